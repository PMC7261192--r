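#' Configuration for the synthetic splicing-screen generator
#'
#' Describes a targeted splicing screen of two knockdowns (A and B, e.g.
#' two RNA-binding proteins) against a common control, with known ground
#' truth. Events fall into six classes: `shared` (respond to both
#' knockdowns, with `delta_psi_B = shared_slope * delta_psi_A` plus
#' noise), `A_specific` / `B_specific` (respond to one knockdown only),
#' `A_trend` / `B_trend` (significant response to one knockdown plus a
#' same-direction sub-threshold response to the other), and `null`.
#'
#' Defaults emulate a screen of ~5000 known alternative exons with three
#' knockdown and three control replicates, a shared-response slope of
#' 0.83, effect sizes of 12-40 percentage points, trends of 3-9, and a
#' replicate-level PSI jitter of 5 percentage points.
#'
#' @param n_events number of splicing events.
#' @param n_replicates_per_group replicates per condition (default 3).
#' @param mean_depth expected total reads per event per sample
#'   (default 200).
#' @param depth_dispersion negative-binomial overdispersion of the total
#'   reads (variance = mu + dispersion * mu^2; 0 gives Poisson depth).
#' @param frac_shared,frac_A_specific,frac_B_specific,frac_trending
#'   proportions of event classes; `frac_trending` is split evenly
#'   between `A_trend` and `B_trend`; the remainder is null. Must be
#'   non-negative and sum to at most 1.
#' @param shared_slope scale factor relating the knockdown-B effect to
#'   the knockdown-A effect for shared events (default 0.83).
#' @param shared_slope_noise_sd sd (percentage points) of the noise
#'   around the shared-slope relation (default 2).
#' @param delta_psi_magnitude_range interval (percentage points) for true
#'   effect magnitudes (default `c(12, 40)`).
#' @param trend_magnitude_range sub-threshold interval for trending
#'   responses (default `c(3, 9)`).
#' @param psi_noise_sd replicate-level PSI jitter, percentage points
#'   (default 5).
#' @param seed random seed; fixes all outputs bit-for-bit.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_events = 5000,
                              n_replicates_per_group = 3,
                              mean_depth = 200,
                              depth_dispersion = 0.1,
                              frac_shared = 71 / 5000,
                              frac_A_specific = 45 / 5000,
                              frac_B_specific = 37 / 5000,
                              frac_trending = 300 / 5000,
                              shared_slope = 0.83,
                              shared_slope_noise_sd = 2,
                              delta_psi_magnitude_range = c(12, 40),
                              trend_magnitude_range = c(3, 9),
                              psi_noise_sd = 5,
                              seed = 1L) {
  n_events <- assert_count(n_events, "n_events", min = 1L)
  n_replicates_per_group <- assert_count(n_replicates_per_group,
                                         "n_replicates_per_group", min = 1L)
  assert_scalar_number(mean_depth, "mean_depth", positive = TRUE)
  assert_scalar_number(depth_dispersion, "depth_dispersion")
  if (depth_dispersion < 0) stop_("`depth_dispersion` must be >= 0")
  fr <- c(frac_shared = frac_shared, frac_A_specific = frac_A_specific,
          frac_B_specific = frac_B_specific, frac_trending = frac_trending)
  for (nm in names(fr)) assert_scalar_number(fr[[nm]], nm)
  if (any(fr < 0)) stop_("class proportions must be >= 0")
  if (sum(fr) > 1) stop_("class proportions sum to %.3f > 1", sum(fr))
  assert_scalar_number(shared_slope, "shared_slope")
  assert_scalar_number(shared_slope_noise_sd, "shared_slope_noise_sd")
  if (shared_slope_noise_sd < 0) stop_("`shared_slope_noise_sd` must be >= 0")
  assert_range(delta_psi_magnitude_range, "delta_psi_magnitude_range")
  assert_range(trend_magnitude_range, "trend_magnitude_range")
  assert_scalar_number(psi_noise_sd, "psi_noise_sd")
  if (psi_noise_sd < 0) stop_("`psi_noise_sd` must be >= 0")
  seed <- assert_count(seed, "seed")
  structure(list(n_events = n_events,
                 n_replicates_per_group = n_replicates_per_group,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 frac_shared = frac_shared,
                 frac_A_specific = frac_A_specific,
                 frac_B_specific = frac_B_specific,
                 frac_trending = frac_trending,
                 shared_slope = shared_slope,
                 shared_slope_noise_sd = shared_slope_noise_sd,
                 delta_psi_magnitude_range = delta_psi_magnitude_range,
                 trend_magnitude_range = trend_magnitude_range,
                 psi_noise_sd = psi_noise_sd,
                 seed = seed),
            class = "simulation_config")
}

#' Read a simulation configuration from a YAML key-value file
#'
#' Keys match the arguments of [simulation_config()]; absent keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_("the `yaml` package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

# Signed effect magnitudes that avoid saturating PSI outside [0, 100]:
# an event near the low end of the PSI scale can only gain inclusion and
# vice versa; the sign is random when both directions fit.
draw_signed_effect <- function(baseline, range) {
  n <- length(baseline)
  mag <- stats::runif(n, range[1], range[2])
  must_up <- baseline - mag < 0
  must_down <- baseline + mag > 100
  sgn <- ifelse(must_up, 1, ifelse(must_down, -1,
                sample(c(-1, 1), n, replace = TRUE)))
  sgn * mag
}

#' Simulate a targeted isoform count table with known ground truth
#'
#' Generates a full two-knockdown screen: per sample, each event's total
#' read count is drawn from a negative binomial with the configured mean
#' and overdispersion, and its long-isoform count binomially from a
#' replicate-level true PSI (class-dependent baseline shift plus
#' truncated-normal jitter, clamped to `[0, 100]`). All randomness flows
#' from the single seed in the config.
#'
#' @param config a [simulation_config()].
#' @return A list with `table`, an [event_count_table()] with conditions
#'   `control`, `kdA`, `kdB`, and `truth`, a data.frame (`event_id`,
#'   `class`, `baseline_psi`, `delta_psi_A`, `delta_psi_B`) emitting the
#'   ground truth alongside the data.
#' @examples
#' sim <- simulate_count_table(simulation_config(n_events = 50, seed = 1))
#' sim$table
#' head(sim$truth)
#' @export
simulate_count_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_events
    counts_per_class <- c(
      shared = round(config$frac_shared * n),
      A_specific = round(config$frac_A_specific * n),
      B_specific = round(config$frac_B_specific * n),
      A_trend = round(config$frac_trending * n / 2),
      B_trend = round(config$frac_trending * n / 2))
    if (sum(counts_per_class) > n)
      counts_per_class <- pmin(counts_per_class, n)  # rounding guard
    classes <- c(rep(names(counts_per_class), counts_per_class),
                 rep("null", n - sum(counts_per_class)))
    classes <- sample(classes)

    event_id <- sprintf("ev%05d", seq_len(n))
    baseline <- stats::runif(n, 15, 85)
    dA <- dB <- numeric(n)
    rng_main <- config$delta_psi_magnitude_range
    rng_trend <- config$trend_magnitude_range

    i <- classes == "shared"
    if (any(i)) {
      dA[i] <- draw_signed_effect(baseline[i], rng_main)
      dB[i] <- config$shared_slope * dA[i] +
        stats::rnorm(sum(i), 0, config$shared_slope_noise_sd)
    }
    i <- classes == "A_specific"
    if (any(i)) dA[i] <- draw_signed_effect(baseline[i], rng_main)
    i <- classes == "B_specific"
    if (any(i)) dB[i] <- draw_signed_effect(baseline[i], rng_main)
    i <- classes == "A_trend"
    if (any(i)) {
      dA[i] <- draw_signed_effect(baseline[i], rng_main)
      dB[i] <- sign(dA[i]) * stats::runif(sum(i), rng_trend[1], rng_trend[2])
    }
    i <- classes == "B_trend"
    if (any(i)) {
      dB[i] <- draw_signed_effect(baseline[i], rng_main)
      dA[i] <- sign(dB[i]) * stats::runif(sum(i), rng_trend[1], rng_trend[2])
    }

    reps <- config$n_replicates_per_group
    conditions <- c("control", "kdA", "kdB")
    samples <- data.frame(
      sample_id = paste0(rep(conditions, each = reps), "_", seq_len(reps)),
      condition = rep(conditions, each = reps),
      replicate = rep(seq_len(reps), times = length(conditions)),
      stimulation = "stimulated",
      stringsAsFactors = FALSE)

    shift_of <- c(control = 0, kdA = 1, kdB = 2)  # index into cbind(0, dA, dB)
    shifts <- cbind(0, dA, dB)
    counts_list <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      true_psi <- clamp(baseline + shifts[, shift_of[samples$condition[s]] + 1] +
                          stats::rnorm(n, 0, config$psi_noise_sd), 0, 100)
      total <- if (config$depth_dispersion > 0)
        stats::rnbinom(n, mu = config$mean_depth,
                       size = 1 / config$depth_dispersion)
      else stats::rpois(n, config$mean_depth)
      long <- stats::rbinom(n, total, true_psi / 100)
      counts_list[[s]] <- data.frame(
        event_id = event_id, sample_id = samples$sample_id[s],
        long_count = long, short_count = total - long,
        stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, counts_list)

    truth <- data.frame(event_id = event_id, class = classes,
                        baseline_psi = baseline,
                        delta_psi_A = dA, delta_psi_B = dB,
                        stringsAsFactors = FALSE)
    list(table = event_count_table(counts, samples), truth = truth)
  })
}

#' Simulate a transcription-shutoff decay time course
#'
#' Target abundance follows single-exponential decay,
#' `exp(-ln(2) * t / half_life)`, with multiplicative lognormal noise of
#' the given coefficient of variation; a constant reference-gene track
#' is emitted alongside.
#'
#' @param half_life true half-life in hours (> 0).
#' @param timepoints sampling times in hours; must include 0.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 gives the noiseless closed form).
#' @param seed random seed.
#' @return A data.frame `time`, `target`, `reference` usable directly by
#'   [estimate_half_life()]; the noiseless curve is attached as
#'   `attr(, "true_abundance")`.
#' @export
simulate_decay_series <- function(half_life, timepoints, noise_cv = 0.05,
                                  seed = 1L) {
  assert_scalar_number(half_life, "half_life", positive = TRUE)
  if (!0 %in% timepoints) stop_("timepoints must include 0")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop_("timepoints must be strictly increasing")
  assert_scalar_number(noise_cv, "noise_cv")
  if (noise_cv < 0) stop_("`noise_cv` must be >= 0")
  with_seed(seed, {
    true_ab <- exp(-log(2) * timepoints / half_life)
    sdlog <- sqrt(log1p(noise_cv^2))
    noise <- if (noise_cv > 0)
      stats::rlnorm(length(timepoints), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, length(timepoints))
    out <- data.frame(time = timepoints, target = true_ab * noise,
                      reference = 1)
    attr(out, "true_abundance") <- true_ab
    out
  })
}

#' Simulate a spike-in polysome gradient profile
#'
#' Builds a fraction-wise transcript distribution from an archetype shape
#' — heavy-weighted (polysomal) or light-weighted (mRNP/monosomal) — with
#' lognormal shape jitter, then distorts each fraction by a random
#' recovery factor carried identically by the spike-in channel, so
#' [spike_normalize()] can undo it exactly.
#'
#' Class semantics follow the cycloheximide run-off logic: an
#' `efficient` transcript is polysomal with CHX but light without it; an
#' `impaired` transcript stays polysomal regardless of CHX.
#'
#' @param n_fractions number of gradient fractions (>= 6).
#' @param shift_class ground-truth class, `"efficient"` or `"impaired"`.
#' @param chx `"plus"` or `"minus"`.
#' @param seed random seed.
#' @param shape_jitter_sd lognormal sd of the fraction-wise shape jitter
#'   (default 0.2).
#' @param recovery_sd lognormal sd of the fraction-specific recovery
#'   factors (default 0.5).
#' @param genotype optional condition label carried on the profile.
#' @return A [polysome_profile()] with attributes `true_distribution`
#'   (the pre-distortion distribution) and `true_class`.
#' @export
simulate_polysome_profiles <- function(n_fractions = 10,
                                       shift_class = c("efficient", "impaired"),
                                       chx = c("plus", "minus"),
                                       seed = 1L,
                                       shape_jitter_sd = 0.2,
                                       recovery_sd = 0.5,
                                       genotype = NA_character_) {
  shift_class <- match.arg(shift_class)
  chx <- match.arg(chx)
  n_fractions <- assert_count(n_fractions, "n_fractions", min = 6L)
  with_seed(seed, {
    f <- seq_len(n_fractions)
    heavy <- shift_class == "impaired" || chx == "plus"
    weights <- if (heavy) f^2 else (n_fractions + 1 - f)^2
    weights <- weights * stats::rlnorm(n_fractions, 0, shape_jitter_sd)
    true_dist <- weights / sum(weights)
    recovery <- stats::rlnorm(n_fractions, 0, recovery_sd)
    target <- 1000 * true_dist * recovery
    spikein <- 100 * recovery
    prof <- polysome_profile(target, spikein, chx = chx, genotype = genotype)
    attr(prof, "true_distribution") <- true_dist
    attr(prof, "true_class") <- shift_class
    prof
  })
}

#' Write simulated ground truth to a TSV file
#'
#' @param truth the `truth` data.frame from [simulate_count_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) write_tsv_(truth, path)
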