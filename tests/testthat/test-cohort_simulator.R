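test_that("sim_config validates parameters and applies the default parameterization", {
  cfg <- sim_config(n_agents = 10)
  expect_equal(cfg$horizon_days, 3652L)
  expect_equal(cfg$diathesis_sd, 0.20)
  expect_equal(cfg$stress_sd, 0.75)
  expect_equal(cfg$adaptation_constant, 3.0)
  expect_equal(cfg$threshold, 15)
  expect_equal(cfg$remission_stringency, 0.5)
  expect_error(sim_config(-1), "n_agents")
  expect_error(sim_config(10, horizon_days = 10), "horizon_days")
  expect_error(sim_config(10, diathesis_sd = 0), "diathesis_sd")
  expect_error(sim_config(10, remission_stringency = 1.5), "remission_stringency")
})

test_that("draw_diathesis is positive with median near 1", {
  expect_error(draw_diathesis(0), "diathesis_sd")
  set.seed(9)
  d <- draw_diathesis(0.20, 1e5)
  expect_true(all(d > 0))
  expect_lt(abs(median(d) - 1), 0.01)
})

test_that("identical configurations give identical cohorts and byte-identical CSVs", {
  cfg <- sim_config(n_agents = 150, horizon_days = 600, seed = 42)
  r1 <- simulate_cohort(cfg)
  r2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(r1, p1); write_cohort_csv(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("agent records are independent of cohort size and chunking", {
  big <- simulate_cohort(sim_config(n_agents = 80, horizon_days = 500, seed = 7))
  small <- simulate_cohort(sim_config(n_agents = 40, horizon_days = 500, seed = 7))
  expect_identical(plain_df(big[1:40, ]), plain_df(small))
  rechunk <- simulate_cohort(sim_config(n_agents = 80, horizon_days = 500, seed = 7),
                             chunk_size = 17L)
  expect_identical(plain_df(big), plain_df(rechunk))
})

test_that("vectorized cohort core matches the scalar per-agent reference path", {
  cfg <- sim_config(n_agents = 10, horizon_days = 500, seed = 13)
  rec <- simulate_cohort(cfg)
  rule <- diagnostic_rule(cfg$threshold, cfg$remission_stringency)
  y10 <- diathesim:::year10_start(cfg$horizon_days)
  for (i in seq_len(10)) {
    set.seed(diathesim:::agent_seed(cfg$seed, i))
    d <- rlnorm(1, 0, cfg$diathesis_sd)
    stress <- rlnorm(cfg$horizon_days, 0, cfg$stress_sd)
    tr <- run_agent(agent_params(d, cfg$adaptation_constant), stress)
    eps <- segment_episodes(tr, rule)
    expect_equal(rec$diathesis[i], d)
    expect_equal(rec$baseline_symptoms[i], tr$symptoms[14], tolerance = 1e-9)
    expect_equal(rec$episode_count[i], nrow(eps))
    if (nrow(eps)) {
      expect_equal(rec$onset_day[i], eps$start_day[1])
      expect_equal(rec$first_episode_duration_days[i], eps$duration_days[1])
      expect_equal(rec$first_episode_censored[i], eps$censored[1])
      expect_equal(rec$episodes_years_1_9[i], sum(eps$start_day < y10))
      expect_equal(rec$episode_started_year_10[i], any(eps$start_day >= y10))
      # in-episode days are start..end-1 (or start..horizon when censored)
      last_day <- ifelse(eps$censored, cfg$horizon_days, eps$end_day - 1L)
      expect_equal(rec$episode_in_year_10[i], any(last_day >= y10))
    } else {
      expect_true(is.na(rec$onset_day[i]))
      expect_false(rec$ever_episode[i])
    }
  }
})

test_that("record invariants hold on a simulated cohort", {
  rec <- simulate_cohort(sim_config(n_agents = 500, horizon_days = 1500, seed = 3))
  expect_true(all(rec$episode_count >= rec$episodes_years_1_9))
  expect_identical(rec$ever_episode, rec$episode_count >= 1L)
  expect_true(all(rec$onset_day[!is.na(rec$onset_day)] >= 14))
  expect_true(all(rec$episode_in_year_10[rec$episode_started_year_10]))
  cens <- which(!is.na(rec$first_episode_censored) & rec$first_episode_censored)
  expect_true(all(rec$episode_count[cens] == 1L))
  expect_true(all(is.na(rec$first_episode_censored) == (rec$episode_count == 0L)))
  dep <- rec$baseline_state == "depressed"
  expect_true(all(rec$onset_day[dep] == 14L))
})

test_that("incidence responds monotonically to threshold and diathesis spread", {
  base <- cohort_summary(simulate_cohort(sim_config(n_agents = 5000, seed = 21)))
  hi_thr <- cohort_summary(simulate_cohort(sim_config(n_agents = 5000, seed = 21,
                                                      threshold = 20)))
  hi_dsd <- cohort_summary(simulate_cohort(sim_config(n_agents = 5000, seed = 21,
                                                      diathesis_sd = 0.30)))
  expect_lt(hi_thr$cumulative_incidence, base$cumulative_incidence)
  expect_gt(hi_dsd$cumulative_incidence, base$cumulative_incidence)
})

test_that("the resource cap guards oversized runs", {
  cfg <- sim_config(n_agents = 1e6, horizon_days = 3652, max_agent_days = 1e9)
  expect_error(simulate_cohort(cfg), "resource cap")
})

test_that("cohort CSV round-trips losslessly, including an empty cohort", {
  rec <- simulate_cohort(sim_config(n_agents = 60, horizon_days = 700, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  back <- read_cohort_csv(path)
  expect_identical(plain_df(rec), plain_df(back))

  empty <- simulate_cohort(sim_config(n_agents = 0))
  expect_equal(nrow(empty), 0)
  write_cohort_csv(empty, path)
  expect_length(readLines(path), 1L)       # header only
  expect_equal(nrow(read_cohort_csv(path)), 0)
})

test_that("malformed cohort files fail with line and column in the message", {
  rec <- simulate_cohort(sim_config(n_agents = 5, horizon_days = 400, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  lines <- readLines(path)
  parts <- strsplit(lines[4], ",")[[1]]
  parts[2] <- "not-a-number"                # diathesis of the 3rd agent
  lines[4] <- paste(parts, collapse = ",")
  writeLines(lines, path)
  expect_error(read_cohort_csv(path), "line 4, column 'diathesis'")
})
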