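# raslkit

Analysis toolkit for studies of **reciprocal regulation between two
RNA-binding proteins (RBPs)** based on targeted isoform counting
(RASL-seq-style assays). When two RBPs — say, two splicing factors with
overlapping binding preferences — each regulate the other's expression,
depleting either one perturbs a heavily overlapping set of splicing
events. Disentangling *shared* targets from *factor-specific* ones, and
expression-level cross-regulation (transcription, mRNA decay,
translation) from direct splicing regulation, requires a consistent set
of quantitative procedures. `raslkit` packages those procedures, each
testable against a synthetic-data generator with known ground truth.

## What it computes

**Splicing quantification.** For each alternative event with long- and
short-isoform read counts, percent spliced in is

    PSI = 100 · long / (long + short),

undefined when the total is zero. Events are kept when their mean total
read count across all samples is strictly above 10. For a knockdown
versus control comparison,

    ΔPSI = mean PSI(knockdown) − mean PSI(control)   (percentage points),

and an event is called significant when |ΔPSI| > 10 **and** the
two-sided, pooled-variance (Student's) t-test on per-replicate PSI gives
p < 0.05. Raw p-values are used deliberately, matching standard practice
for targeted assays; every threshold is a function argument.

**Cross-regulation statistics.** The overlap of the two knockdowns'
significant-event sets within the common testable universe is tested
with a two-tailed hypergeometric test (doubled smaller tail, capped at
1; a min-likelihood variant is available). Shared events are regressed
(OLS, ΔPSI_B on ΔPSI_A) to estimate the slope and R² of the common
response; events are classified as `shared`, `A_specific`,
`B_specific`, `A_trend_in_B`, `B_trend_in_A`, `discordant` or
`nonresponsive`. Rescue experiments (re-expressing one factor in cells
depleted of the other) are summarized by the rescue fraction
`(PSI_rescue − PSI_kd)/(PSI_wt − PSI_kd)` and mapped onto antagonistic /
saturated-single / cooperative regulatory models.

**Expression dynamics.** Reference-gene-normalized fold changes; mRNA
half-life from transcription-shutoff time courses by log-linear OLS
(`t½ = ln 2 / k`); induction time-course comparison with a
loss-of-induction flag.

**Polysome profiling.** Sucrose-gradient fraction signals are divided by
an exogenous spike-in RNA measured in the same fraction (cancelling
recovery differences exactly), normalized to a distribution, and
summarized as the mass proportion in polysome fractions. A transcript is
classified `efficient_elongation` when cycloheximide (CHX) increases its
polysomal proportion by more than 0.15, and `impaired_elongation` when
its polysome association is CHX-independent — the classic run-off
signature of poor elongation.

**Synthetic data.** `simulate_count_table()` generates a full
two-knockdown screen (negative-binomial depth, binomial isoform split,
truncated-normal PSI jitter) with per-event ground-truth classes and
effect sizes; companions simulate exponential decay series and spike-in
polysome profiles. All generators are deterministic given a seed.

## Worked example

```r
library(raslkit)

cfg <- simulation_config(n_events = 5000, seed = 20)  # two knockdowns, 3v3 replicates
sim <- simulate_count_table(cfg)

tab <- filter_events(sim$table, min_mean_reads = 10)
psi <- compute_psi(tab)
calls_A <- compare_conditions(psi, "kdA", "control")
calls_B <- compare_conditions(psi, "kdB", "control")

overlap_stats(calls_A, calls_B)
#> overlap_stats: universe 5000, |A| 351, |B| 334, shared 111
#>   shared = 31.6% of A, 33.2% of B; two-tailed hypergeometric p = 1.69e-50

cls <- classify_events(calls_A, calls_B)
table(cls$class)
#>    A_specific  A_trend_in_B    B_specific  B_trend_in_A    discordant
#>           117           123           104           119             1
#> nonresponsive        shared
#>          4426           110

shared <- cls[cls$class == "shared", ]
shared_event_regression(shared$delta_psi_A, shared$delta_psi_B)
#> regression_fit: slope 0.810, intercept 1.75, R^2 0.850 (n = 110)
```

The overlap is far beyond chance (p ≈ 1.7e-50) and shared events shift
by nearly the same amount in both knockdowns (slope ≈ 0.81, R² 0.85) —
the signature of co-regulated targets. Expression dynamics and
translation work the same way:

```r
estimate_half_life(simulate_decay_series(half_life = 3,
  timepoints = c(0, 1, 2, 4, 8), noise_cv = 0.05, seed = 2))
#> half_life_estimate: k = 0.2320 /h, t1/2 = 2.99 h, R^2 = 0.995 (n = 5, excluded 0)

classify_translation(
  simulate_polysome_profiles(10, "impaired", "plus",  seed = 5),
  simulate_polysome_profiles(10, "impaired", "minus", seed = 6))
#> translation_call: polysomal mass +CHX 0.83, -CHX 0.83, shift -0.00 -> impaired_elongation
```

A thin command-line wrapper with subcommands `simulate`, `quantify`,
`overlap`, `classify`, `rescue`, `decay`, `induction` and `polysome` is
installed at `system.file("scripts", "raslkit.R", package = "raslkit")`.

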