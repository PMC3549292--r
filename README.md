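# diathesim

An agent-based diathesis-stress simulator of depressive symptom dynamics,
with threshold-based diagnostic classification and the epidemiologic
analyses needed to study what that thresholding does to an inherently
continuous process.

## The scientific problem

Viewed through the standard incidence-prevalence-duration disease model,
major depression epidemiology is complicated: incidence declines over
time, recurrence risk rises steeply with the number of past episodes,
sub-threshold symptoms at baseline predict later onset, and the
probability of recovery falls as an episode drags on. `diathesim` is for
psychiatric epidemiologists and disease modelers who want to ask a
sharper question: how much of that complexity is real disease dynamics,
and how much is an artifact of forcing a continuous phenomenon through a
nominal diagnostic cut-point?

The model is deliberately minimal. Agent *i* has a fixed vulnerability
(**diathesis**) `d ~ Lognormal(0, 0.20)` and sees i.i.d. daily stress
`s_t ~ Lognormal(0, 0.75)`. An internal stress burden updates daily as

    B_t = B_{t-1} + s_t * d  -  B_{t-1} / (1 + c * d)

(activation minus adaptation; `c` is the adaptation constant, default 3).
Symptom level `Y_t` is the trailing 14-day mean of `B`. A diagnostic rule
with hysteresis segments `Y` into episodes: onset when `Y > 15`,
remission only when `Y < 0.5 * 15`. Under constant stress the burden has
the closed-form equilibrium `s * d * (1 + c * d)`.

From 100,000 simulated agents over ten years (3652 days) the default
parameterization produces roughly 15% cumulative incidence, ~2.8 episodes
per affected agent, a ~314-day mean first-episode duration, ~13% of first
episodes unrecovered at one year — and all four "complex" epidemiologic
patterns emerge from a process that contains none of them explicitly.

## Worked example

```r
library(diathesim)

cfg <- sim_config(n_agents = 20000, seed = 42)   # defaults: the reference calibration
cohort <- simulate_cohort(cfg)                   # ~15 s, one row per agent
s <- cohort_summary(cohort)

onset <- km_onset(cohort)                        # first-onset Kaplan-Meier,
declining_incidence_stat(onset)                  #   baseline-depressed excluded
recurrence_by_history(cohort, top_bin = 3)
rc <- recovery_curve(cohort)
surv_at(rc$curve, 365)
```

Output (as printed by this code):

```
cumulative incidence: 14.1%
mean episodes among affected: 2.80
mean first-episode duration: 317 days (136 of 2822 censored)
$hazard_year1
[1] 0.0001463166
$hazard_year10
[1] 1.701535e-05
$ratio
[1] 8.599092
  prior_episodes n_agents n_with_year10_episode  proportion
1              0    17285                   107 0.006190338
2              1     1206                   229 0.189883914
3              2      450                   142 0.315555556
4             3+     1059                   658 0.621340888
unrecovered at 12 months: 13.9%
```

Reading it: one agent in seven crosses the diagnostic threshold within
ten years; the daily onset hazard in year 1 is ~8.6 times the year-10
hazard (incidence "declines" although no agent's parameters change);
year-10 episode risk climbs from 0.6% with no prior episodes to 62% with
three or more (apparent kindling); and 13.9% of first episodes have not
remitted after a year. All of this is produced by thresholding a
stationary continuous process across a heterogeneous population.

A command-line interface is included (`inst/scripts/diathesim`, or
`run_cli()` from R) with subcommands `simulate`, `analyze`, `sweep` and
`reproduce`.

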