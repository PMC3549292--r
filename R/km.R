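#' Kaplan-Meier product-limit estimator
#'
#' The estimator used for both onset and recovery analyses, implemented
#' directly since it is the study's analytic instrument. Ties are handled
#' with the standard convention that events precede censorings at equal
#' times (a subject censored at time `t` is still at risk for an event at
#' `t`). Greenwood standard errors are included.
#'
#' @param time positive numeric event or censoring times (days).
#' @param event logical or 0/1; `TRUE` for an observed event, `FALSE` for
#'   censoring.
#' @return an object of class `survival_curve`: a list with `time` (distinct
#'   observed times), `n_risk`, `n_event`, `n_censor`, `surv`
#'   (product-limit survival just after each time), `std_err` (Greenwood),
#'   `n` and the raw `data`.
#' @examples
#' km_fit(c(100, 200, 3652), c(TRUE, TRUE, FALSE))
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  stopifnot(length(time) == length(event))
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]
  if (!length(time)) stop("no observations", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)

  tt <- sort(unique(time))
  n <- length(time)
  pos <- match(time, tt)
  d <- tabulate(pos[event], nbins = length(tt))
  cns <- tabulate(pos[!event], nbins = length(tt))
  removed <- cumsum(d + cns)
  n_risk <- n - c(0L, removed[-length(removed)])
  surv <- cumprod(1 - d / n_risk)
  # Greenwood: var(S) = S^2 * sum d_i / (n_i (n_i - d_i))
  gw <- cumsum(ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0))
  structure(list(time = tt, n_risk = n_risk, n_event = d, n_censor = cns,
                 surv = surv, std_err = surv * sqrt(gw), n = n,
                 data = data.frame(time = time, event = event)),
            class = "survival_curve")
}

#' Evaluate a survival curve at given times
#'
#' Step-function lookup: survival is 1 before the first observed time and
#' constant between observed times.
#'
#' @param curve a `survival_curve`.
#' @param t numeric times.
#' @return survival probabilities at `t`.
#' @export
surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Mean daily event hazard over a time window
#'
#' Events observed in `[from, to]` divided by person-days at risk in the
#' window (a subject contributes a day `t` while `t <= time_i`).
#'
#' @param curve a `survival_curve`.
#' @param from,to window bounds in days, inclusive.
#' @return a list: `events`, `person_days`, `hazard` (events per
#'   person-day; `NaN` when no person-time).
#' @export
interval_hazard <- function(curve, from, to) {
  stopifnot(inherits(curve, "survival_curve"), from <= to)
  time <- curve$data$time
  event <- curve$data$event
  ev <- sum(event & time >= from & time <= to)
  pd <- sum(pmax(0, pmin(time, to) - from + 1))
  list(events = ev, person_days = pd, hazard = ev / pd)
}

#' @export
print.survival_curve <- function(x, ...) {
  ev <- sum(x$n_event)
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, censored = %d\n",
              x$n, ev, x$n - ev))
  last <- length(x$surv)
  cat(sprintf("  survival at last observed time (%g): %.4f\n",
              x$time[last], x$surv[last]))
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.survival_curve <- function(x, xlab = "days", ylab = "survival",
                                ylim = c(0, 1), ...) {
  plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
       xlab = xlab, ylab = ylab, ylim = ylim, ...)
  invisible(x)
}

#' Export a survival curve's points to CSV
#'
#' @param curve a `survival_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.csv(data.frame(time = curve$time, n_risk = curve$n_risk,
                              n_event = curve$n_event,
                              n_censor = curve$n_censor,
                              surv = curve$surv, std_err = curve$std_err),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
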