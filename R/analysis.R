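DAYS_PER_MONTH <- 30.44  # mean calendar month length

cohort_horizon <- function(records, horizon = NULL) {
  if (!is.null(horizon)) return(as.integer(horizon))
  cfg <- attr(records, "config")
  if (!is.null(cfg)) return(cfg$horizon_days)
  stop("horizon not available: pass 'horizon' explicitly for cohorts read from file",
       call. = FALSE)
}

#' Kaplan-Meier curve for first episode onset
#'
#' Time-to-event analysis of the first episode: the event is the first
#' onset day, agents without an onset are censored at the horizon. Agents
#' already depressed at baseline (day-14 symptoms above the threshold) are
#' excluded by default, mirroring how an incidence study would drop
#' prevalent cases.
#'
#' @param records an `agent_cohort` from [simulate_cohort()] or
#'   [read_cohort_csv()].
#' @param exclude_baseline_depressed drop agents depressed at day 14
#'   (default `TRUE`).
#' @param horizon simulation horizon in days; taken from the cohort's
#'   configuration when available.
#' @return a `survival_curve`; `1 - surv_at(curve, horizon)` is the
#'   cumulative incidence.
#' @export
km_onset <- function(records, exclude_baseline_depressed = TRUE,
                     horizon = NULL) {
  stopifnot(is.data.frame(records))
  horizon <- cohort_horizon(records, horizon)
  if (exclude_baseline_depressed)
    records <- records[records$baseline_state != "depressed", , drop = FALSE]
  if (!nrow(records))
    stop("no agents left in the analysis population", call. = FALSE)
  has <- !is.na(records$onset_day)
  curve <- km_fit(time = ifelse(has, records$onset_day, horizon),
                  event = has)
  curve$horizon <- horizon
  curve
}

#' Early versus late onset hazard
#'
#' Compares the mean daily onset hazard in the first analysis year (days
#' 14-365) with the final year (last 365 days of the horizon). A ratio
#' above 1 means incidence declines over the decade; under a constant
#' hazard the ratio is about 1.
#'
#' @param curve a `survival_curve` from [km_onset()].
#' @param horizon horizon in days (taken from the curve when available).
#' @return a list: `hazard_year1`, `hazard_year10`, `ratio`, `declining`
#'   (logical), `flag` (`"ok"`, `"no_events"`, or `"infinite_ratio"`).
#' @export
declining_incidence_stat <- function(curve, horizon = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  horizon <- if (!is.null(horizon)) horizon else curve$horizon
  if (is.null(horizon)) stop("'horizon' required", call. = FALSE)
  if (horizon < 730)
    stop("curve must span at least 2 years", call. = FALSE)
  y1 <- interval_hazard(curve, 14, 365)
  y10 <- interval_hazard(curve, year10_start(horizon), horizon)
  if (sum(curve$n_event) == 0)
    return(list(hazard_year1 = y1$hazard, hazard_year10 = y10$hazard,
                ratio = NA_real_, declining = NA, flag = "no_events"))
  ratio <- y1$hazard / y10$hazard
  flag <- if (y10$hazard == 0 && y1$hazard > 0) "infinite_ratio" else "ok"
  list(hazard_year1 = y1$hazard, hazard_year10 = y10$hazard,
       ratio = ratio, declining = isTRUE(ratio > 1), flag = flag)
}

#' Recurrence in the final year by prior episode history
#'
#' Tabulates the proportion of agents with an episode during year 10
#' against the number of episodes they experienced during years 1-9. Counts
#' above `top_bin` are pooled into a `"top_bin+"` row to avoid sparse
#' cells.
#'
#' @param records an `agent_cohort`.
#' @param top_bin integer; histories of `top_bin` or more are pooled
#'   (default 5).
#' @param year10_var which year-10 outcome to use: `"any"` counts an
#'   episode ongoing or starting during year 10 (default), `"started"`
#'   only one starting in it.
#' @return a `recurrence_table` data frame: `prior_episodes` (factor),
#'   `n_agents`, `n_with_year10_episode`, `proportion`.
#' @export
recurrence_by_history <- function(records, top_bin = 5L,
                                  year10_var = c("any", "started")) {
  stopifnot(is.data.frame(records), top_bin >= 1)
  year10_var <- match.arg(year10_var)
  outcome <- if (year10_var == "any") records$episode_in_year_10
             else records$episode_started_year_10
  prior <- pmin(records$episodes_years_1_9, top_bin)
  labels <- c(as.character(0:(top_bin - 1)), paste0(top_bin, "+"))
  prior <- factor(prior, levels = 0:top_bin, labels = labels)
  n <- as.integer(table(prior))
  ev <- as.integer(tapply(outcome, prior, sum, default = 0L))
  keep <- n > 0L
  structure(data.frame(prior_episodes = factor(labels, levels = labels)[keep],
                       n_agents = n[keep],
                       n_with_year10_episode = ev[keep],
                       proportion = ev[keep] / n[keep]),
            class = c("recurrence_table", "data.frame"))
}

#' Onset curves stratified by baseline symptom level
#'
#' Splits the baseline-non-depressed population at `elevated_cut` (day-14
#' symptoms above the cut versus at or below it) and fits a Kaplan-Meier
#' onset curve in each stratum.
#'
#' @param records an `agent_cohort`.
#' @param elevated_cut baseline cut (default from the cohort configuration,
#'   else 6).
#' @param horizon horizon in days (from the configuration when available).
#' @return a list with elements `elevated` and `low` (each a
#'   `survival_curve`, or `NULL` with a warning when a stratum is empty)
#'   and `elevated_cut`.
#' @export
onset_by_baseline_symptoms <- function(records, elevated_cut = NULL,
                                       horizon = NULL) {
  stopifnot(is.data.frame(records))
  horizon <- cohort_horizon(records, horizon)
  cfg <- attr(records, "config")
  if (is.null(elevated_cut))
    elevated_cut <- if (!is.null(cfg)) cfg$elevated_cut else 6
  records <- records[records$baseline_state != "depressed", , drop = FALSE]
  elev <- records$baseline_symptoms > elevated_cut
  fit_stratum <- function(rows, label) {
    if (!nrow(rows)) {
      warning("empty '", label, "' stratum: curve omitted", call. = FALSE)
      return(NULL)
    }
    has <- !is.na(rows$onset_day)
    km_fit(ifelse(has, rows$onset_day, horizon), has)
  }
  list(elevated = fit_stratum(records[elev, , drop = FALSE], "elevated"),
       low = fit_stratum(records[!elev, , drop = FALSE], "low"),
       elevated_cut = elevated_cut)
}

#' Recovery curve for first episodes
#'
#' Kaplan-Meier estimate of time to remission among first episodes: the
#' event is remission, episodes still open at the horizon contribute
#' censored durations. A monthly summary (30.44-day bins) gives the
#' cumulative probability of recovery at the end of each month.
#'
#' @param records an `agent_cohort` (agents without an episode are
#'   ignored).
#' @param months number of months to tabulate (default 24).
#' @return a list of class `recovery_curve`: `curve` (a `survival_curve`
#'   over episode duration in days), `monthly` (data frame `month`,
#'   `days`, `cum_recovered`, `unrecovered`), and `n_episodes`.
#' @export
recovery_curve <- function(records, months = 24L) {
  stopifnot(is.data.frame(records))
  first <- records[records$episode_count > 0L, , drop = FALSE]
  if (!nrow(first)) stop("no first episodes in this cohort", call. = FALSE)
  curve <- km_fit(first$first_episode_duration_days,
                  !first$first_episode_censored)
  days <- floor(seq_len(months) * DAYS_PER_MONTH)
  monthly <- data.frame(month = seq_len(months), days = days,
                        unrecovered = surv_at(curve, days))
  monthly$cum_recovered <- 1 - monthly$unrecovered
  structure(list(curve = curve,
                 monthly = monthly[, c("month", "days", "cum_recovered",
                                       "unrecovered")],
                 n_episodes = nrow(first)),
            class = "recovery_curve")
}

#' Mean daily remission hazard over a range of episode months
#'
#' @param recovery a `recovery_curve`.
#' @param from_month,to_month inclusive month range (30.44-day months).
#' @return a list as in [interval_hazard()].
#' @export
recovery_hazard <- function(recovery, from_month, to_month) {
  stopifnot(inherits(recovery, "recovery_curve"))
  interval_hazard(recovery$curve,
                  from = floor((from_month - 1) * DAYS_PER_MONTH) + 1,
                  to = floor(to_month * DAYS_PER_MONTH))
}

#' Parameter sweep over simulation configurations
#'
#' Re-runs [simulate_cohort()] over a grid of parameter values and reports
#' cumulative incidence and mean first-episode duration per cell, mirroring
#' a sensitivity analysis of the model parameters. Cell seeds are derived
#' deterministically from the base seed and the cell index. A failing cell
#' is recorded (with its error message) and the sweep continues.
#'
#' @param base a [sim_config()] used for every parameter not in the grid.
#' @param grid named list of value vectors, e.g.
#'   `list(threshold = c(15, 20))`; crossed with [expand.grid()].
#' @param n_agents cohort size per cell (default: `base$n_agents`).
#' @return a data frame with one row per cell: the varied parameters,
#'   `cumulative_incidence`, `mean_first_episode_duration`,
#'   `mean_episode_count_affected`, `seed`, `error`.
#' @export
parameter_sweep <- function(base, grid, n_agents = NULL) {
  stopifnot(inherits(base, "sim_config"), is.list(grid), length(grid) > 0,
            !is.null(names(grid)), all(nzchar(names(grid))))
  bad <- setdiff(names(grid), names(base))
  if (length(bad))
    stop("unknown parameter(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(n_agents)) n_agents <- base$n_agents
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- cells
  res$cumulative_incidence <- NA_real_
  res$mean_first_episode_duration <- NA_real_
  res$mean_episode_count_affected <- NA_real_
  res$seed <- NA_integer_
  res$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    args <- as.list(base)[setdiff(names(base), c("rule"))]
    args[names(grid)] <- lapply(cells[i, , drop = FALSE], identity)
    args$n_agents <- n_agents
    args$seed <- as.integer((as.numeric(base$seed) * 7919 + i) %% 2147483647)
    res$seed[i] <- args$seed
    out <- tryCatch({
      s <- cohort_summary(simulate_cohort(do.call(sim_config, args)))
      res$cumulative_incidence[i] <- s$cumulative_incidence
      res$mean_first_episode_duration[i] <- s$mean_first_episode_duration
      res$mean_episode_count_affected[i] <- s$mean_episode_count_affected
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(out)) res$error[i] <- out
  }
  res
}
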