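#' Simulation configuration
#'
#' Bundles the full parameter set of one simulation experiment. The defaults
#' are the data-producing parameterization: diathesis SD 0.20, stress SD
#' 0.75, adaptation constant 3.0, diagnostic threshold 15, remission
#' stringency 0.5, a 10-year (3652-day) horizon, and an elevated-symptom
#' cut of 6 for baseline stratification.
#'
#' @param n_agents positive integer cohort size.
#' @param horizon_days positive integer simulation length in days.
#' @param diathesis_sd positive numeric; SD of the underlying normal of the
#'   lognormal diathesis distribution (median diathesis is 1).
#' @param stress_sd positive numeric; SD of the underlying normal of the
#'   daily lognormal stress distribution (median stress is 1).
#' @param adaptation_constant non-negative numeric; see [agent_params()].
#' @param threshold positive numeric diagnostic threshold.
#' @param remission_stringency numeric in `(0, 1]`; see [diagnostic_rule()].
#' @param elevated_cut positive numeric baseline cut for elevated symptoms.
#' @param seed integer root seed; every agent's RNG substream is derived
#'   deterministically from it and the agent id.
#' @param max_agent_days resource guard: [simulate_cohort()] refuses runs
#'   with `n_agents * horizon_days` above this cap (default 1e9).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_agents,
                       horizon_days = 3652,
                       diathesis_sd = 0.20,
                       stress_sd = 0.75,
                       adaptation_constant = 3.0,
                       threshold = 15,
                       remission_stringency = 0.5,
                       elevated_cut = 6,
                       seed = 1,
                       max_agent_days = 1e9) {
  stopifnot(length(n_agents) == 1, length(horizon_days) == 1,
            length(seed) == 1)
  if (!is.numeric(n_agents) || is.na(n_agents) || n_agents < 0 ||
      n_agents != floor(n_agents))
    stop("'n_agents' must be a non-negative integer", call. = FALSE)
  if (!is.numeric(horizon_days) || is.na(horizon_days) || horizon_days < 14 ||
      horizon_days != floor(horizon_days))
    stop("'horizon_days' must be an integer >= 14 (symptoms are undefined before day 14)",
         call. = FALSE)
  if (!is.numeric(diathesis_sd) || diathesis_sd <= 0)
    stop("'diathesis_sd' must be > 0", call. = FALSE)
  if (!is.numeric(stress_sd) || stress_sd <= 0)
    stop("'stress_sd' must be > 0", call. = FALSE)
  if (!is.numeric(adaptation_constant) || adaptation_constant < 0)
    stop("'adaptation_constant' must be >= 0", call. = FALSE)
  rule <- diagnostic_rule(threshold, remission_stringency)  # validates both
  if (!is.numeric(elevated_cut) || elevated_cut <= 0)
    stop("'elevated_cut' must be > 0", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 horizon_days = as.integer(horizon_days),
                 diathesis_sd = diathesis_sd,
                 stress_sd = stress_sd,
                 adaptation_constant = adaptation_constant,
                 threshold = threshold,
                 remission_stringency = remission_stringency,
                 elevated_cut = elevated_cut,
                 seed = as.integer(seed),
                 max_agent_days = max_agent_days,
                 rule = rule),
            class = "sim_config")
}

#' Draw diathesis values
#'
#' Diathesis is lognormal with underlying Normal(0, `diathesis_sd`): always
#' positive, median 1, approximately bell-shaped for small SD. The default
#' SD 0.20 puts about 95% of agents between 0.68 and 1.48.
#'
#' @param diathesis_sd positive numeric SD of the underlying normal.
#' @param n number of draws.
#' @return numeric vector of positive diathesis values.
#' @export
draw_diathesis <- function(diathesis_sd, n = 1) {
  if (!is.numeric(diathesis_sd) || length(diathesis_sd) != 1 ||
      !is.finite(diathesis_sd) || diathesis_sd <= 0)
    stop("'diathesis_sd' must be > 0", call. = FALSE)
  stats::rlnorm(n, meanlog = 0, sdlog = diathesis_sd)
}

#' First day of the final analysis year
#'
#' Year 10 is the last 365 days of the horizon (days 3288-3652 at the
#' default 3652-day decade); years 1-9 run from day 14 (first defined
#' symptom day) to the day before.
#' @param horizon_days integer horizon.
#' @return integer day.
#' @keywords internal
year10_start <- function(horizon_days) max(15L, as.integer(horizon_days) - 364L)

#' Simulate a cohort of heterogeneous agents
#'
#' For each agent: draw a diathesis, generate a daily lognormal stress
#' series, iterate the burden dynamics, apply the diagnostic rule, and
#' summarise the result into one record. Every agent uses a private RNG
#' substream derived from `(seed, agent_id)`, so records are reproducible
#' and independent of cohort size or processing order. Agents are processed
#' in chunks with the day loop vectorised across the chunk; the result is
#' identical (to floating point) to the scalar [run_agent()] +
#' [segment_episodes()] path.
#'
#' @param config a [sim_config()].
#' @param chunk_size number of agents simulated per vectorised pass
#'   (memory/speed trade-off; results do not depend on it).
#' @return an `agent_cohort` data frame, one row per agent, with columns:
#' \describe{
#'   \item{agent_id}{1-based agent index.}
#'   \item{diathesis}{the agent's vulnerability multiplier.}
#'   \item{baseline_symptoms}{day-14 symptom level.}
#'   \item{baseline_state}{`low` / `elevated` / `depressed` (see
#'     [baseline_state()]).}
#'   \item{ever_episode}{any episode over the horizon.}
#'   \item{onset_day}{first episode start day (`NA` if none).}
#'   \item{episode_count}{episodes started over the horizon.}
#'   \item{episodes_years_1_9}{episodes started before year 10.}
#'   \item{episode_in_year_10}{any in-episode day during year 10 (an episode
#'     ongoing at the year boundary counts).}
#'   \item{episode_started_year_10}{stricter variant: episode onset during
#'     year 10.}
#'   \item{first_episode_duration_days}{duration of the first episode;
#'     partial (days observed) when censored at the horizon.}
#'   \item{first_episode_censored}{first episode still open at the horizon
#'     (`NA` when no episode).}
#' }
#' The configuration is attached as `attr(, "config")`.
#' @examples
#' cfg <- sim_config(n_agents = 200, horizon_days = 730, seed = 1)
#' rec <- simulate_cohort(cfg)
#' mean(rec$ever_episode)
#' @export
simulate_cohort <- function(config, chunk_size = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_agents
  horizon <- config$horizon_days
  if (as.numeric(n) * horizon > config$max_agent_days)
    stop("run exceeds the resource cap: n_agents * horizon_days > max_agent_days ",
         "(raise 'max_agent_days' in sim_config to override)", call. = FALSE)
  if (n == 0L) return(empty_cohort(config))

  thr <- config$threshold
  rcut <- config$remission_stringency * thr
  c_ad <- config$adaptation_constant
  y10 <- year10_start(horizon)
  out <- vector("list", ceiling(n / chunk_size))

  for (k in seq_along(out)) {
    ids <- (((k - 1L) * chunk_size + 1L)):min(k * chunk_size, n)
    m <- length(ids)

    # per-agent substreams: diathesis first, then the daily stress series
    d <- numeric(m)
    S <- matrix(0, horizon, m)
    seeds <- agent_seed(config$seed, ids)
    for (j in seq_len(m)) {
      set.seed(seeds[j])
      d[j] <- stats::rlnorm(1, 0, config$diathesis_sd)
      S[, j] <- stats::rlnorm(horizon, 0, config$stress_sd)
    }
    St <- t(S)  # agents in rows: contiguous column access in the day loop

    keep <- 1 - 1 / (1 + c_ad * d)
    prev <- numeric(m)
    ring <- matrix(0, m, 14L)   # last 14 burden values per agent
    rollsum <- numeric(m)

    ill <- logical(m)
    ep_count <- integer(m)
    ep_1_9 <- integer(m)
    started_y10 <- logical(m)
    ill_y10 <- logical(m)
    first_start <- rep(NA_integer_, m)
    first_end <- rep(NA_integer_, m)
    base_sym <- rep(NA_real_, m)

    for (t in seq_len(horizon)) {
      prev <- keep * prev + d * St[, t]
      idx <- ((t - 1L) %% 14L) + 1L
      rollsum <- rollsum + prev - ring[, idx]
      ring[, idx] <- prev
      if (t >= 14L) {
        sym <- rollsum / 14
        if (t == 14L) base_sym <- sym
        newly <- !ill & sym > thr
        remit <- ill & sym < rcut
        if (any(newly)) {
          ill[newly] <- TRUE
          ep_count[newly] <- ep_count[newly] + 1L
          if (t < y10) ep_1_9[newly] <- ep_1_9[newly] + 1L
          else started_y10[newly] <- TRUE
          ns <- newly & is.na(first_start)
          first_start[ns] <- t
        }
        if (any(remit)) {
          ill[remit] <- FALSE
          fe <- remit & is.na(first_end) & !is.na(first_start)
          first_end[fe] <- t
        }
        if (t >= y10 && any(ill)) ill_y10 <- ill_y10 | ill
      }
    }

    cens <- !is.na(first_start) & is.na(first_end)
    dur <- ifelse(cens, horizon - first_start + 1L, first_end - first_start)
    out[[k]] <- data.frame(
      agent_id = ids,
      diathesis = d,
      baseline_symptoms = base_sym,
      baseline_state = classify_baseline(base_sym, thr, config$elevated_cut),
      ever_episode = ep_count > 0L,
      onset_day = first_start,
      episode_count = ep_count,
      episodes_years_1_9 = ep_1_9,
      episode_in_year_10 = ill_y10,
      episode_started_year_10 = started_y10,
      first_episode_duration_days = as.integer(dur),
      first_episode_censored = ifelse(ep_count > 0L, cens, NA)
    )
  }

  records <- do.call(rbind, out)
  rownames(records) <- NULL
  structure(records, config = config,
            class = c("agent_cohort", "data.frame"))
}

empty_cohort <- function(config) {
  structure(data.frame(agent_id = integer(0), diathesis = numeric(0),
                       baseline_symptoms = numeric(0),
                       baseline_state = factor(character(0),
                                               levels = c("low", "elevated", "depressed")),
                       ever_episode = logical(0), onset_day = integer(0),
                       episode_count = integer(0),
                       episodes_years_1_9 = integer(0),
                       episode_in_year_10 = logical(0),
                       episode_started_year_10 = logical(0),
                       first_episode_duration_days = integer(0),
                       first_episode_censored = logical(0)),
            config = config, class = c("agent_cohort", "data.frame"))
}

#' Headline summaries of a simulated cohort
#'
#' Cumulative incidence (proportion with any episode), mean episode count
#' among affected agents, and mean first-episode duration. The duration
#' distribution is heavy-tailed and its mean is carried by a small number
#' of very long (often still-ongoing) episodes, so the headline
#' `mean_first_episode_duration` averages over *all* first episodes,
#' counting an episode still open at the horizon at its observed partial
#' length — the statistic a running simulation reports. The mean restricted
#' to episodes that remitted within the horizon is returned alongside as
#' `mean_first_episode_duration_uncensored`, with the censored count.
#'
#' @param records an `agent_cohort` from [simulate_cohort()].
#' @return a list: `n`, `cumulative_incidence`, `mean_episode_count_affected`,
#'   `mean_first_episode_duration`, `mean_first_episode_duration_uncensored`,
#'   `n_first_episodes`, `n_censored_first_episodes`.
#' @export
cohort_summary <- function(records) {
  stopifnot(is.data.frame(records))
  affected <- records$episode_count > 0L
  unc <- affected & !records$first_episode_censored
  list(n = nrow(records),
       cumulative_incidence = mean(records$ever_episode),
       mean_episode_count_affected =
         if (any(affected)) mean(records$episode_count[affected]) else NA_real_,
       mean_first_episode_duration =
         if (any(affected)) mean(records$first_episode_duration_days[affected])
         else NA_real_,
       mean_first_episode_duration_uncensored =
         if (any(unc)) mean(records$first_episode_duration_days[unc]) else NA_real_,
       n_first_episodes = sum(affected),
       n_censored_first_episodes = sum(affected & records$first_episode_censored))
}

cohort_columns <- c("agent_id", "diathesis", "baseline_symptoms",
                    "baseline_state", "ever_episode", "onset_day",
                    "episode_count", "episodes_years_1_9",
                    "episode_in_year_10", "episode_started_year_10",
                    "first_episode_duration_days", "first_episode_censored")

#' Write a cohort to CSV
#'
#' One row per agent, header row, missing/censored fields encoded as empty
#' strings. Doubles are written with 17 significant digits so the file
#' round-trips losslessly through [read_cohort_csv()], and identical
#' configurations produce byte-identical files.
#'
#' @param records an `agent_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records), all(cohort_columns %in% names(records)))
  fmt <- function(v) {
    out <- if (is.double(v)) sprintf("%.17g", v) else as.character(v)
    out[is.na(v)] <- ""
    out
  }
  chr <- vapply(records[cohort_columns], fmt, character(nrow(records)))
  if (nrow(records) == 0L) chr <- matrix(character(0), 0, length(cohort_columns))
  lines <- c(paste(cohort_columns, collapse = ","),
             if (nrow(records)) apply(chr, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#'
#' @param path file path.
#' @return an `agent_cohort` data frame (without the `config` attribute).
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols))
    stop("malformed cohort file: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  conv_num <- function(col, as_int = FALSE) {
    v <- raw[[col]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & v != "")
    if (length(bad))
      stop(sprintf("parse error at line %d, column '%s': %s",
                   bad[1] + 1L, col, v[bad[1]]), call. = FALSE)
    x[v == ""] <- NA
    if (as_int) as.integer(x) else x
  }
  conv_lgl <- function(col) {
    v <- raw[[col]]
    bad <- which(!(v %in% c("TRUE", "FALSE", "")))
    if (length(bad))
      stop(sprintf("parse error at line %d, column '%s': %s",
                   bad[1] + 1L, col, v[bad[1]]), call. = FALSE)
    ifelse(v == "", NA, v == "TRUE")
  }
  out <- data.frame(
    agent_id = conv_num("agent_id", TRUE),
    diathesis = conv_num("diathesis"),
    baseline_symptoms = conv_num("baseline_symptoms"),
    baseline_state = factor(raw$baseline_state,
                            levels = c("low", "elevated", "depressed")),
    ever_episode = conv_lgl("ever_episode"),
    onset_day = conv_num("onset_day", TRUE),
    episode_count = conv_num("episode_count", TRUE),
    episodes_years_1_9 = conv_num("episodes_years_1_9", TRUE),
    episode_in_year_10 = conv_lgl("episode_in_year_10"),
    episode_started_year_10 = conv_lgl("episode_started_year_10"),
    first_episode_duration_days = conv_num("first_episode_duration_days", TRUE),
    first_episode_censored = conv_lgl("first_episode_censored")
  )
  structure(out, class = c("agent_cohort", "data.frame"))
}
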