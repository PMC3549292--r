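#' Diagnostic rule: onset threshold and remission stringency
#'
#' The rule applied to a continuous symptom trace to produce nominal
#' episodes. An agent enters an episode on the first day symptoms *exceed*
#' `threshold`; the episode is over only on the first day symptoms fall
#' *below* `remission_stringency * threshold`. With stringency below 1 this
#' hysteresis keeps an episode alive through dips that stay above the
#' remission cut-point; with stringency exactly 1 the rule degenerates to
#' simple thresholding.
#'
#' @param threshold positive numeric onset cut-point (symptom units).
#' @param remission_stringency numeric in `(0, 1]`; fraction of the
#'   threshold below which symptoms must fall for remission.
#' @return a list of class `diagnostic_rule` with the two parameters and
#'   the derived `remission_cut`.
#' @export
diagnostic_rule <- function(threshold = 15, remission_stringency = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            is.numeric(remission_stringency), length(remission_stringency) == 1)
  if (!is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  if (!is.finite(remission_stringency) ||
      remission_stringency <= 0 || remission_stringency > 1)
    stop("'remission_stringency' must be in (0, 1]", call. = FALSE)
  structure(list(threshold = threshold,
                 remission_stringency = remission_stringency,
                 remission_cut = remission_stringency * threshold),
            class = "diagnostic_rule")
}

#' Segment a symptom trace into diagnostic episodes
#'
#' Runs a two-state (well/ill) machine over the defined part of the trace
#' (day 14 onward). Transitions use strict inequalities: WELL to ILL when
#' `symptoms > threshold`, ILL to WELL when `symptoms < remission_cut`;
#' days of exact equality leave the state unchanged. `end_day` is the first
#' day below the remission cut and `duration_days = end_day - start_day`,
#' i.e. the remission day itself is not counted as an episode day, so the
#' minimal episode lasts one day. An episode still open on the final day is
#' returned with `censored = TRUE` and the partial duration
#' `horizon - start_day + 1`. Agents already above threshold on day 14 are
#' in-episode with `start_day = 14`.
#'
#' @param trace a `symptom_trace` from [run_agent()], or any data frame with
#'   columns `day` and `symptoms`.
#' @param rule a [diagnostic_rule()].
#' @return a data frame of class `episode_set` with one row per episode:
#'   `start_day`, `end_day` (`NA` when censored), `duration_days`,
#'   `censored`. Zero rows when symptoms never exceed the threshold.
#' @examples
#' p <- agent_params(1.4, 3)
#' tr <- run_agent(p, generate_stress_series(0.75, 730, seed = 42))
#' segment_episodes(tr, diagnostic_rule(15, 0.5))
#' @export
segment_episodes <- function(trace, rule) {
  stopifnot(is.data.frame(trace), inherits(rule, "diagnostic_rule"),
            all(c("day", "symptoms") %in% names(trace)))
  sym <- trace$symptoms
  day <- trace$day
  ok <- !is.na(sym)
  sym <- sym[ok]; day <- day[ok]
  thr <- rule$threshold
  rcut <- rule$remission_cut

  starts <- integer(0); ends <- integer(0)
  ill <- FALSE
  cur_start <- NA_integer_
  for (i in seq_along(sym)) {
    if (!ill && sym[i] > thr) {
      ill <- TRUE
      cur_start <- day[i]
    } else if (ill && sym[i] < rcut) {
      ill <- FALSE
      starts <- c(starts, cur_start)
      ends <- c(ends, day[i])
    }
  }
  horizon <- if (length(day)) day[length(day)] else 0L
  censored <- logical(length(starts))
  if (ill) {
    starts <- c(starts, cur_start)
    ends <- c(ends, NA_integer_)
    censored <- c(censored, TRUE)
  }
  duration <- ifelse(censored, horizon - starts + 1L, ends - starts)
  structure(data.frame(start_day = as.integer(starts),
                       end_day = as.integer(ends),
                       duration_days = as.integer(duration),
                       censored = censored),
            rule = rule, horizon = horizon,
            class = c("episode_set", "data.frame"))
}

#' Classify an agent's baseline (day-14) symptom state
#'
#' Baseline is the first day the 14-day symptom mean exists. State is
#' `depressed` when day-14 symptoms exceed the diagnostic threshold (such
#' agents are excluded from onset analyses), `elevated` when above
#' `elevated_cut` but at or below the threshold, and `low` otherwise.
#'
#' @param trace a `symptom_trace` (or data frame with `day`, `symptoms`).
#' @param rule a [diagnostic_rule()].
#' @param elevated_cut positive numeric; sub-threshold cut for "elevated
#'   symptoms" (default 6, roughly half the default threshold of 15).
#' @return one of `"depressed"`, `"elevated"`, `"low"`.
#' @export
baseline_state <- function(trace, rule, elevated_cut = 6) {
  stopifnot(is.data.frame(trace), inherits(rule, "diagnostic_rule"),
            is.numeric(elevated_cut), elevated_cut > 0)
  s14 <- trace$symptoms[trace$day == 14]
  if (length(s14) != 1 || is.na(s14))
    stop("day-14 symptoms are not defined in this trace", call. = FALSE)
  classify_baseline(s14, rule$threshold, elevated_cut)
}

# vectorised kernel shared with the cohort simulator
classify_baseline <- function(s14, threshold, elevated_cut) {
  out <- ifelse(s14 > threshold, "depressed",
                ifelse(s14 > elevated_cut, "elevated", "low"))
  factor(out, levels = c("low", "elevated", "depressed"))
}
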