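# Build a minimal symptom trace from a vector of day-14-onward symptom values.
# Days 1-13 get NA symptoms, as in a real trace.
make_trace <- function(symptoms_from_day14) {
  n <- 13L + length(symptoms_from_day14)
  data.frame(day = seq_len(n),
             symptoms = c(rep(NA_real_, 13), symptoms_from_day14))
}

# Minimal agent-record data frame for analysis-function tests.
make_records <- function(n, onset_day = NA_integer_,
                         baseline_state = "low",
                         baseline_symptoms = 2,
                         episode_count = NULL,
                         episodes_years_1_9 = 0L,
                         episode_in_year_10 = FALSE,
                         episode_started_year_10 = FALSE,
                         first_episode_duration_days = NA_integer_,
                         first_episode_censored = NA) {
  onset_day <- rep_len(onset_day, n)
  if (is.null(episode_count)) episode_count <- as.integer(!is.na(onset_day))
  data.frame(
    agent_id = seq_len(n),
    diathesis = 1,
    baseline_symptoms = rep_len(baseline_symptoms, n),
    baseline_state = factor(rep_len(baseline_state, n),
                            levels = c("low", "elevated", "depressed")),
    ever_episode = !is.na(onset_day),
    onset_day = onset_day,
    episode_count = rep_len(episode_count, n),
    episodes_years_1_9 = rep_len(episodes_years_1_9, n),
    episode_in_year_10 = rep_len(episode_in_year_10, n),
    episode_started_year_10 = rep_len(episode_started_year_10, n),
    first_episode_duration_days = rep_len(first_episode_duration_days, n),
    first_episode_censored = rep_len(first_episode_censored, n)
  )
}

# Random positive symptom series with excursions around a threshold of 15,
# for property-style segmentation tests. Continuous values: ties with the
# threshold have probability zero.
random_symptoms <- function(n) {
  x <- 10 + cumsum(stats::rnorm(n, 0, 2))
  pmax(abs(x), 1e-6)
}

# strip cohort class/config attributes for content-only comparisons
plain_df <- function(d) {
  d <- as.data.frame(d)
  attr(d, "config") <- NULL
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}
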