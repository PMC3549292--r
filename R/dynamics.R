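#' Agent parameters: diathesis and adaptation constant
#'
#' @param diathesis positive numeric vulnerability multiplier. It scales
#'   stress into daily activation and simultaneously slows adaptation.
#' @param adaptation_constant non-negative numeric. The fraction of the
#'   previous day's burden cleared each day is `1 / (1 + adaptation_constant
#'   * diathesis)`; zero means the whole burden of the preceding day is
#'   cleared daily.
#' @return a list of class `agent_params`.
#' @export
agent_params <- function(diathesis, adaptation_constant = 3.0) {
  stopifnot(is.numeric(diathesis), length(diathesis) == 1,
            is.numeric(adaptation_constant), length(adaptation_constant) == 1)
  if (!is.finite(diathesis) || diathesis <= 0)
    stop("'diathesis' must be > 0", call. = FALSE)
  if (!is.finite(adaptation_constant) || adaptation_constant < 0)
    stop("'adaptation_constant' must be >= 0", call. = FALSE)
  structure(list(diathesis = diathesis,
                 adaptation_constant = adaptation_constant),
            class = "agent_params")
}

#' One day's stress-burden update
#'
#' Applies activation and adaptation simultaneously from the previous day's
#' burden:
#' \deqn{B_t = B_{t-1} + s_t d - B_{t-1} \frac{1}{1 + c d}}
#' where `d` is the diathesis and `c` the adaptation constant. With `c = 0`
#' the previous burden is cleared entirely and `B_t = s_t d`. Under constant
#' stress `s` the burden converges geometrically to the fixed point
#' `s * d * (1 + c * d)`.
#'
#' @param prev_burden non-negative numeric, burden on day `t - 1`.
#' @param stress_today positive numeric, stress level on day `t`.
#' @param params an [agent_params()] object.
#' @return burden on day `t` (non-negative).
#' @examples
#' p <- agent_params(diathesis = 1.4, adaptation_constant = 3)
#' step_burden(0, 1, p)
#' @export
step_burden <- function(prev_burden, stress_today, params) {
  stopifnot(inherits(params, "agent_params"))
  if (any(prev_burden < 0)) stop("'prev_burden' must be >= 0", call. = FALSE)
  d <- params$diathesis
  # computed as prev * (1 - adaptation fraction) + activation: algebraically
  # identical to adding activation and subtracting adaptation, but exact when
  # the adaptation constant is 0 (burden then equals stress * diathesis) and
  # bitwise identical to the vectorized cohort core
  b <- prev_burden * (1 - 1 / (1 + params$adaptation_constant * d)) +
    stress_today * d
  # the retained fraction is in [0, 1), so b >= 0 already; the floor is a
  # guard against floating-point underflow, not a behaviour change
  pmax(b, 0)
}

#' Simulate one agent's burden and symptom trace
#'
#' Iterates the daily burden update over a stress series starting from zero
#' burden (the day before the simulation begins), then computes depressive
#' symptom levels as the trailing 14-day mean of the burden (the current day
#' and the past 13). Symptoms are undefined (`NA`) on days 1-13.
#'
#' @param params an [agent_params()] object.
#' @param stress a [generate_stress_series()] result or positive numeric
#'   vector of daily stress levels.
#' @return a `symptom_trace`: a data frame with columns `day` (1-based),
#'   `stress`, `burden`, `symptoms`, carrying the parameters as attributes.
#' @examples
#' p <- agent_params(1.4, 3)
#' tr <- run_agent(p, generate_stress_series(0.75, 120, seed = 7))
#' head(tr, 16)
#' @export
run_agent <- function(params, stress) {
  stopifnot(inherits(params, "agent_params"))
  stress <- as.numeric(stress)
  if (length(stress) < 1 || any(!is.finite(stress)) || any(stress < 0))
    stop("'stress' must be a non-empty vector of non-negative finite values",
         call. = FALSE)
  n <- length(stress)
  d <- params$diathesis
  keep <- 1 - 1 / (1 + params$adaptation_constant * d)
  # burden follows the linear recursion B_t = keep * B_{t-1} + d * s_t
  burden <- numeric(n)
  prev <- 0
  for (t in seq_len(n)) {
    prev <- keep * prev + d * stress[t]
    burden[t] <- prev
  }
  symptoms <- as.numeric(stats::filter(burden, rep(1 / 14, 14), sides = 1))
  structure(data.frame(day = seq_len(n), stress = stress,
                       burden = burden, symptoms = symptoms),
            params = params, window_days = 14L,
            class = c("symptom_trace", "data.frame"))
}

#' Equilibrium burden under constant stress
#'
#' Closed-form fixed point of the daily update: `s * d * (1 + c * d)`.
#' Convergence toward it is geometric with daily factor
#' `1 - 1 / (1 + c * d)`.
#'
#' @param stress constant daily stress level.
#' @param params an [agent_params()] object.
#' @return the equilibrium burden.
#' @export
burden_fixed_point <- function(stress, params) {
  stopifnot(inherits(params, "agent_params"))
  stress * params$diathesis *
    (1 + params$adaptation_constant * params$diathesis)
}

#' Export a symptom trace to CSV
#'
#' Columns `day`, `stress`, `burden`, `symptoms`; symptoms are empty for
#' days 1-13 where the 14-day mean is undefined.
#'
#' @param trace a `symptom_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "symptom_trace"))
  utils::write.table(trace, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
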