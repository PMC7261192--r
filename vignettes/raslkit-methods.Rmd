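---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raslkit)
```

`raslkit` implements the quantitative backbone of a reciprocal-regulation
study of two RNA-binding proteins: splicing quantification from targeted
isoform counts, cross-knockdown overlap and classification statistics,
rescue-experiment interpretation, mRNA decay kinetics, and
spike-in-normalized polysome analysis. This vignette records the models,
the parameters that matter, and the design decisions taken where the
field's conventions leave room.

## Splicing quantification

For an event with `long` and `short` isoform read counts in a sample,

$$\mathrm{PSI} = 100 \cdot \frac{\text{long}}{\text{long} + \text{short}},$$

in percent. A cell with zero total reads has no defined PSI; it is
recorded as missing and excluded from group means and tests. Imputing
zero would fabricate a strong exon-skipping signal out of a dropout, so
exclusion is the only defensible default; an event needs at least two
defined replicates per group to be testable at all, and untestable
events are reported by ID rather than silently dropped.

Events are pre-filtered on sequencing depth: the mean of the per-sample
totals across **all** samples must be **strictly** greater than
`min_mean_reads` (default 10 reads). The strict inequality is
deliberate and tested — an event averaging exactly 10 reads is removed.
The same strictness applies to the effect-size threshold below, so
boundary cases resolve the same way everywhere.

The group comparison is

$$\Delta\mathrm{PSI} = \overline{\mathrm{PSI}}_{kd} - \overline{\mathrm{PSI}}_{ctrl}
\quad \text{(percentage points)},$$

with a two-sided, unpaired, pooled-variance (Student's) t-test on the
per-replicate PSI values. Significance requires both
$|\Delta\mathrm{PSI}| > 10$ and $p < 0.05$; the magnitude filter means
the realized false-call rate on null data sits well below the nominal
t-test level (the type-I simulation in the test suite measures it). A
Welch test is available behind `var_equal = FALSE` for designs with
visibly unequal replicate variance, but the equal-variance test is the
default for three-versus-three designs. **No multiple-testing
correction is applied by default**: targeted panels of a few thousand
pre-selected events are conventionally analysed on raw p-values with
the magnitude filter doing most of the work, and the `p_value` column
is exposed so `stats::p.adjust()` can be applied when genome-scale
stringency is wanted. Degenerate inputs are resolved explicitly: when
both groups have zero variance the p-value is 1 if the means agree and
0 otherwise.

RT-PCR validation of a call requires the orthogonal measurement to
agree in direction and to clear the same thresholds
($|\Delta\mathrm{PSI}| > 10$, $p < 0.05$) on its own replicates;
fewer than two replicates per condition gives `untestable`, which is
deliberately distinct from `not_validated`.

## Overlap, regression, classification, rescue

**Universe.** Overlap statistics are computed on the intersection of
events testable in *both* comparisons. The universe size is carried in
every `overlap_stats` result so the sensitivity of the p-value to this
choice can be checked directly.

**Two-tailed hypergeometric test.** With universe $N$, set sizes $n_A$
and $n_B$ and overlap $k$, $X \sim \mathrm{Hypergeom}(N, n_A, n_B)$;
the enrichment tail is $P[X \ge k]$ and the depletion tail
$P[X \le k]$. The two-tailed p-value is twice the smaller tail, capped
at 1 — the conventional, conservative construction. The alternative
"min-likelihood" definition (sum of all outcomes no more likely than
the observed, with a $1+10^{-7}$ relative tolerance on the equality
comparison to absorb floating-point ties) is available via
`method = "minlike"`. The test suite checks the implementation against
exhaustive subset enumeration for every parameter tuple with
$N \le 12$, and checks super-uniformity of the p-value under random
independent sets.

**Shared-event regression** is ordinary least squares of
$\Delta\mathrm{PSI}_B$ on $\Delta\mathrm{PSI}_A$. The orientation (A on
the x-axis) is a convention; `both_orientations = TRUE` reports the
reverse fit too. The fit requires at least three points and a
non-degenerate x; R² is the squared correlation, defined as 1 for an
exactly flat (perfectly fitted) response.

**Classification** partitions the universe with one tunable,
`trend_threshold` (default 5 percentage points): significant in both
with the same sign is `shared`; significant in one with a
same-direction, sub-significance response above the trend threshold in
the other is a *trend*; significant in one with the other response at
or below threshold (or opposite in sign) is *truly specific*;
significant in both with opposite signs is surfaced as `discordant`
rather than folded into another class, because such calls historically
fail orthogonal validation and deserve individual scrutiny. The trend
threshold is a sensitivity parameter, not doctrine — the boundary
between "specific" and "trending" is genuinely soft, and the
classification table exposes both effect sizes so any other cut can be
applied downstream.

**Rescue experiments.** The rescue fraction
$(\overline{\mathrm{PSI}}_{rescue} - \overline{\mathrm{PSI}}_{kd}) /
(\overline{\mathrm{PSI}}_{wt} - \overline{\mathrm{PSI}}_{kd})$ is only
defined when the knockdown moved the event by more than 10 percentage
points; otherwise the outcome is `untestable`. Calls use a configurable
band (default: below 0.25 `no_rescue`, above 0.75 `full_rescue`,
`partial_rescue` between) — re-expression experiments are inherently
semi-quantitative, so the band is configuration, not doctrine. The
mapping to regulatory models follows the logic of a factor pair (A, B)
where depleting either factor also depletes the other: no rescue of a
B-specific event by re-expressing the partner indicates direct
antagonism (the partner is already active); no rescue of an A-specific
event indicates a single saturating regulator; partial rescue by either
factor on a both-sensitive event indicates cooperative regulation. The
rescue fraction is invariant to exchanging the long/short isoform roles
(PSI → 100 − PSI), which the suite tests.

## Expression dynamics

Reference normalization divides the target by the reference gene at the
same timepoint and rescales so $t = 0$ equals 1; normalization happens
*before* the log transform of the decay fit, because the reference
corrects multiplicative measurement effects that would otherwise enter
the fitted intercept. Each condition is normalized to its own $t = 0$
(the natural choice when conditions are profiled as separate time
courses); comparisons across conditions are then ratios of fold
changes. Below-detection measurements are encoded as missing — never
zero, which would be $-\infty$ on the log scale — and the number of
exclusions is reported with every fit.

Half-life estimation assumes single-exponential decay
$y(t) = y_0 e^{-kt}$ and fits $\ln y$ on $t$ by OLS, the simplest
standard estimator for shutoff time courses; $t_{1/2} = \ln 2 / k$. At
least three positive points are required. A fitted $k \le 0$ (no
measurable decay) yields an undefined half-life rather than a negative
number. The estimator is scale-invariant and, when forced onto exactly
two points, equals the closed-form two-point solution — both are
tested. Recovery simulations use six timepoints spaced relative to the
true half-life ($\{0, 0.5, 1, 2, 4, 8\} \times t_{1/2}$), the package's
stance on sampling design: an experimenter matches the sampling window
to the expected decay, and a fixed absolute grid would push fast decays
below detection.

Induction comparison reports per-timepoint fold induction in each
condition, their ratio, and flags `induction_lost` when the knockdown's
maximal induction is below `loss_threshold` (default 0.5) of the
wildtype's.

## Polysome profiling

Fractions are ordered light → heavy. Each fraction's target signal is
divided by the spike-in signal from the same fraction — because the
spike-in was added in known, equal amounts before RNA isolation, the
ratio cancels fraction-specific recovery exactly — and the result is
normalized to a distribution. The polysome boundary (first fraction
counted as polysomal) defaults to $\lceil 0.5F \rceil + 1$ for $F$
fractions, i.e. the heavy half of the gradient; gradients differ, so
the boundary is an explicit parameter and every result records the
value used. The classifier uses a single statistic — the CHX-induced
change in polysomal mass proportion — rather than per-fraction testing,
matching how the readout is interpreted: a shift above
`shift_threshold` (default 0.15) means CHX-dependent polysome
association (`efficient_elongation`); CHX-independent association means
`impaired_elongation`. Control transcripts are handled as ordinary
profiles side by side, not hard-coded.

## The synthetic-data generator

The generator emulates a targeted splicing screen of two knockdowns (A
and B) against a common control — by default 5000 events, three
replicates per condition, mean depth 200 reads/event/sample with
negative-binomial overdispersion 0.1, the scale of a stimulated T-cell
RASL screen. Per event: total reads are negative-binomial, long-isoform
reads binomial given a replicate-level true PSI equal to baseline
(uniform 15–85) plus the class effect plus truncated-normal jitter,
clamped to [0, 100]. The count model (NB total, binomial split) is the
simplest one consistent with overdispersed targeted sequencing;
replicate jitter acts on the PSI scale, in percentage points, so
configured effect sizes are in the same units as the thresholds.

Event classes and defaults: `shared` (71/5000) with
$\Delta\mathrm{PSI}_B = 0.83 \cdot \Delta\mathrm{PSI}_A + \varepsilon$,
$\varepsilon \sim N(0, 2^2)$ pp; `A_specific` (45/5000) and
`B_specific` (37/5000) with an effect in one knockdown only; `A_trend`
and `B_trend` (150/5000 each) with a significant-scale effect in one
knockdown and a same-sign sub-threshold effect (3–9 pp) in the other;
the rest null. Effect magnitudes are uniform on 12–40 pp, and the
*direction* of a large effect is chosen so the true shifted mean stays
inside [0, 100] when both directions do not fit (an exon at PSI 15
cannot lose 40 points) — the realistic behaviour, and it keeps the
clamp from biasing effect sizes. `psi_noise_sd` defaults to 5 pp, a
replicate reproducibility chosen so that the stated thresholds
($|\Delta\mathrm{PSI}| > 10$, $p < 0.05$, $n = 3$) give high power at
30-pp effects while keeping null calls below the nominal rate; both
properties are measured in the test suite rather than asserted here.
One seed drives a single RNG stream for everything, restored on exit,
so equal configs are bit-for-bit reproducible.

Decay series are $e^{-t \ln 2 / t_{1/2}}$ with multiplicative lognormal
noise of a given CV (mean-one parameterization) and a constant
reference track. Polysome profiles are built from heavy- or
light-weighted archetype shapes (quadratic ramps) with lognormal shape
jitter (sd 0.2), then distorted by per-fraction lognormal recovery
factors (sd 0.5) carried identically by the spike-in channel — so
spike normalization must recover the pre-distortion distribution
exactly, which the suite checks against the generator's internal truth.

**What the generator does not emulate:** correlated events (each event
is independent), probe-specific biases and cross-hybridization,
batch effects, partial knockdown gradients, read-level errors, or
binding footprints. Passing tests therefore demonstrate that the
statistics recover the truth of *this* generative model at realistic
noise, not that any biological screen satisfies the model; on real
data the universe definition, the equal-variance assumption and the
absence of FDR control are the assumptions to revisit first.

## Problem sizes and numerics

The test suite and the acceptance script run on one CPU in well under a
minute: enumeration oracle to $N \le 12$; 2000-event null and
slope-recovery screens; 200 decay simulations per half-life in
$\{0.5, 1, 2, 5, 10\}$ h; 200 polysome simulations per class. These
sizes give Monte-Carlo error comfortably inside the asserted bounds
(binomial SE ≈ 0.5% on a 2000-event call rate). Exact identities are
asserted to 1e-12; the doubled-tail cap, degenerate-variance p-values,
zero-total PSI cells, flat decay series and out-of-range boundaries
all have explicit, tested behaviour rather than relying on downstream
NaN propagation.
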