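#' Normalize an expression time course to a reference gene
#'
#' Each timepoint's target abundance is divided by the reference-gene
#' abundance at the same timepoint (canceling input and efficiency
#' differences), then the series is rescaled so the t = 0 value is 1.
#' Missing target measurements (below detection) are kept as `NA` and
#' counted, never treated as zero.
#'
#' @param series data.frame with columns `time` (hours, strictly
#'   increasing, containing 0), `target` and `reference` (abundances,
#'   arbitrary units; reference must be positive everywhere).
#' @return A data.frame `time`, `normalized` with
#'   `attr(, "n_excluded")` counting missing target values.
#' @export
normalize_to_reference <- function(series) {
  series <- as.data.frame(series)
  req <- c("time", "target", "reference")
  missing <- setdiff(req, names(series))
  if (length(missing))
    stop_("series is missing column(s): %s", paste(missing, collapse = ", "))
  if (is.unsorted(series$time, strictly = TRUE))
    stop_("timepoints must be strictly increasing")
  if (!0 %in% series$time) stop_("series must include timepoint 0")
  bad <- which(!is.finite(series$reference) | series$reference <= 0)
  if (length(bad))
    stop_("reference is zero, negative or missing at timepoint(s): %s",
          paste(series$time[bad], collapse = ", "))
  ratio <- series$target / series$reference
  at0 <- ratio[series$time == 0]
  if (!is.finite(at0) || at0 <= 0)
    stop_("target at timepoint 0 must be positive to anchor the series")
  out <- data.frame(time = series$time, normalized = ratio / at0)
  attr(out, "n_excluded") <- sum(!is.finite(ratio))
  out
}

# Log-linear exponential-decay fit; no minimum-point check so the
# two-point closed form can be exercised directly.
fit_log_linear <- function(time, value) {
  fit <- stats::lm(log(value) ~ time)
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (stats::var(log(value)) == 0) 1 else stats::cor(time, log(value))^2
  list(k = -slope, r_squared = r2, n_points = length(time))
}

#' Estimate mRNA half-life from a transcription-shutoff time course
#'
#' Fits a single-exponential decay model by ordinary least squares of
#' log(normalized abundance) on time, after reference-gene normalization
#' (normalization precedes the log transform). The decay rate is minus
#' the slope and the half-life is `ln(2) / k`. When the fitted rate is
#' non-positive (no measurable decay, e.g. a flat series), the half-life
#' is reported as undefined (`NA`) rather than a negative number.
#'
#' @param series a decay series: data.frame with `time`, `target`,
#'   `reference` as in [normalize_to_reference()].
#' @return An object of class `half_life_estimate`: list with `k`
#'   (1/hour), `half_life` (hours or `NA`), `r_squared`, `n_points`,
#'   `n_excluded` (non-positive or missing values dropped before the
#'   fit).
#' @examples
#' s <- simulate_decay_series(half_life = 2, timepoints = c(0, 1, 2, 4),
#'                            noise_cv = 0, seed = 1)
#' estimate_half_life(s)
#' @export
estimate_half_life <- function(series) {
  norm <- normalize_to_reference(series)
  ok <- is.finite(norm$normalized) & norm$normalized > 0
  n_excluded <- sum(!ok)
  if (sum(ok) < 3)
    stop_("half-life fit requires >= 3 positive, defined timepoints (got %d)",
          sum(ok))
  fit <- fit_log_linear(norm$time[ok], norm$normalized[ok])
  structure(list(k = fit$k,
                 half_life = if (fit$k > 0) log(2) / fit$k else NA_real_,
                 r_squared = fit$r_squared,
                 n_points = fit$n_points,
                 n_excluded = n_excluded),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  hl <- if (is.na(x$half_life)) "undefined (no measurable decay)"
        else sprintf("%.2f h", x$half_life)
  cat(sprintf("half_life_estimate: k = %.4f /h, t1/2 = %s, R^2 = %.3f (n = %d, excluded %d)\n",
              x$k, hl, x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Reference-normalized fold change between two measurements
#'
#' Computes `(measure_b / reference_b) / (measure_a / reference_a)`: the
#' change in target abundance from condition a to condition b after
#' normalizing each to its loading/reference control.
#'
#' @param measure_a,measure_b target signals in the two conditions.
#' @param reference_a,reference_b matching reference signals.
#' @return The fold change (dimensionless). All inputs must be positive.
#' @export
fold_change <- function(measure_a, measure_b, reference_a, reference_b) {
  vals <- c(measure_a = measure_a, measure_b = measure_b,
            reference_a = reference_a, reference_b = reference_b)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop_("non-positive or missing input(s): %s", paste(bad, collapse = ", "))
  (measure_b / reference_b) / (measure_a / reference_a)
}

#' Compare induction time courses between two conditions
#'
#' Each condition's series is reference-normalized and expressed as fold
#' induction relative to its own t = 0. The per-timepoint ratio
#' (knockdown / wildtype) and the maximal fold induction per condition
#' are reported; induction is flagged as lost when the knockdown's
#' maximal induction falls below `loss_threshold` times the wildtype's.
#'
#' @param series_wt,series_kd data.frames with `time`, `target`,
#'   `reference`; timepoints must match exactly.
#' @param loss_threshold fraction of wildtype maximal induction below
#'   which the knockdown is flagged (default 0.5).
#' @return An object of class `induction_comparison`: list with
#'   `by_time` (data.frame `time`, `fold_wt`, `fold_kd`, `ratio`),
#'   `max_induction_wt`, `max_induction_kd`, `induction_lost`,
#'   `loss_threshold`.
#' @export
compare_induction <- function(series_wt, series_kd, loss_threshold = 0.5) {
  assert_scalar_number(loss_threshold, "loss_threshold", positive = TRUE)
  if (!isTRUE(all.equal(series_wt$time, series_kd$time)))
    stop_("timepoints of the two series do not match")
  wt <- normalize_to_reference(series_wt)
  kd <- normalize_to_reference(series_kd)
  by_time <- data.frame(time = wt$time, fold_wt = wt$normalized,
                        fold_kd = kd$normalized,
                        ratio = kd$normalized / wt$normalized)
  max_wt <- max(wt$normalized, na.rm = TRUE)
  max_kd <- max(kd$normalized, na.rm = TRUE)
  structure(list(by_time = by_time,
                 max_induction_wt = max_wt,
                 max_induction_kd = max_kd,
                 induction_lost = max_kd < loss_threshold * max_wt,
                 loss_threshold = loss_threshold),
            class = "induction_comparison")
}

#' @export
print.induction_comparison <- function(x, ...) {
  cat(sprintf("induction_comparison: max fold induction wt %.2f, kd %.2f -> %s\n",
              x$max_induction_wt, x$max_induction_kd,
              if (x$induction_lost) "induction LOST" else "induction retained"))
  invisible(x)
}
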