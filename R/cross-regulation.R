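#' Two-tailed hypergeometric overlap test
#'
#' Tests whether the intersection of two subsets of a common universe is
#' larger or smaller than expected under random, independent draws without
#' replacement. With `X ~ Hypergeometric(n_universe, n_A, n_B)`, the
#' enrichment tail is `P[X >= n_shared]` and the depletion tail is
#' `P[X <= n_shared]`.
#'
#' Two constructions of the two-tailed p-value are offered:
#' \describe{
#'   \item{`"double"`}{twice the smaller tail, capped at 1 (default).}
#'   \item{`"minlike"`}{the sum of probabilities of all outcomes no more
#'     likely than the observed one.}
#' }
#' The two agree for symmetric distributions and differ slightly for
#' skewed ones; the doubled-tail form is the default because it is the
#' standard, conservative choice.
#'
#' @param n_universe number of events in the common universe.
#' @param n_A,n_B sizes of the two subsets.
#' @param n_shared observed intersection size.
#' @param method `"double"` or `"minlike"`.
#' @return The two-tailed p-value, in (0, 1].
#' @examples
#' hypergeom_two_tailed(5000, 309, 215, 71)
#' @export
hypergeom_two_tailed <- function(n_universe, n_A, n_B, n_shared,
                                 method = c("double", "minlike")) {
  method <- match.arg(method)
  n_universe <- assert_count(n_universe, "n_universe")
  n_A <- assert_count(n_A, "n_A")
  n_B <- assert_count(n_B, "n_B")
  n_shared <- assert_count(n_shared, "n_shared")
  if (n_A > n_universe || n_B > n_universe)
    stop_("n_A and n_B cannot exceed n_universe")
  if (n_shared > min(n_A, n_B))
    stop_("n_shared cannot exceed min(n_A, n_B)")
  if (n_shared < max(0L, n_A + n_B - n_universe))
    stop_("n_shared is below the minimum possible overlap %d",
          max(0L, n_A + n_B - n_universe))

  m <- n_A; n <- n_universe - n_A; k <- n_B
  upper <- stats::phyper(n_shared - 1, m, n, k, lower.tail = FALSE)
  lower <- stats::phyper(n_shared, m, n, k, lower.tail = TRUE)
  if (method == "double") {
    min(1, 2 * min(upper, lower))
  } else {
    support <- max(0L, k - n):min(m, k)
    d <- stats::dhyper(support, m, n, k)
    d_obs <- stats::dhyper(n_shared, m, n, k)
    sum(d[d <= d_obs * (1 + 1e-7)])
  }
}

#' Overlap statistics between two knockdowns' significant-event sets
#'
#' The universe is the intersection of the events testable in both
#' comparisons; within it, significant-event sets for each knockdown are
#' intersected and the overlap is tested with [hypergeom_two_tailed()].
#' The universe size is always reported so its sensitivity can be
#' checked.
#'
#' @param calls_A,calls_B `event_calls` from [compare_conditions()] for
#'   knockdowns A and B against their controls.
#' @param method tail construction, see [hypergeom_two_tailed()].
#' @return An object of class `overlap_stats`: list with `n_universe`,
#'   `n_A`, `n_B`, `n_shared`, `p_two_tailed`, and `pct_of_A`,
#'   `pct_of_B` (the shared set as a percentage of each knockdown's
#'   responsive set, on the 0-100 scale).
#' @export
overlap_stats <- function(calls_A, calls_B, method = c("double", "minlike")) {
  method <- match.arg(method)
  universe <- intersect(calls_A$event_id, calls_B$event_id)
  if (length(universe) == 0) stop_("empty universe: the call sets share no events")
  sig_A <- calls_A$event_id[calls_A$significant]
  sig_B <- calls_B$event_id[calls_B$significant]
  sig_A <- intersect(sig_A, universe)
  sig_B <- intersect(sig_B, universe)
  shared <- intersect(sig_A, sig_B)
  out <- list(
    n_universe = length(universe),
    n_A = length(sig_A),
    n_B = length(sig_B),
    n_shared = length(shared),
    p_two_tailed = hypergeom_two_tailed(length(universe), length(sig_A),
                                        length(sig_B), length(shared),
                                        method = method),
    pct_of_A = if (length(sig_A)) 100 * length(shared) / length(sig_A) else NA_real_,
    pct_of_B = if (length(sig_B)) 100 * length(shared) / length(sig_B) else NA_real_,
    shared_ids = shared
  )
  structure(out, class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap_stats: universe %d, |A| %d, |B| %d, shared %d\n",
              x$n_universe, x$n_A, x$n_B, x$n_shared))
  cat(sprintf("  shared = %.1f%% of A, %.1f%% of B; two-tailed hypergeometric p = %.3g\n",
              x$pct_of_A, x$pct_of_B, x$p_two_tailed))
  invisible(x)
}

#' Ordinary least-squares regression of shared-event effect sizes
#'
#' For events responsive to both knockdowns, regresses delta-PSI in
#' knockdown B (y) on delta-PSI in knockdown A (x). A slope near 1 with
#' high R-squared indicates that both depletions shift the same events in
#' the same direction by a similar amount.
#'
#' @param delta_psi_A,delta_psi_B numeric vectors of delta-PSI values
#'   (percentage points) for the shared events; equal length, >= 3 points.
#' @param both_orientations also fit the reverse regression (A on B) and
#'   return it as `$reverse`.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points` (and optionally `reverse`).
#' @export
shared_event_regression <- function(delta_psi_A, delta_psi_B,
                                    both_orientations = FALSE) {
  if (length(delta_psi_A) != length(delta_psi_B))
    stop_("delta_psi_A and delta_psi_B must have equal length")
  ok <- is.finite(delta_psi_A) & is.finite(delta_psi_B)
  x <- delta_psi_A[ok]; y <- delta_psi_B[ok]
  if (length(x) < 3) stop_("regression requires >= 3 shared events")
  if (stats::var(x) == 0) stop_("delta_psi_A has zero variance; slope undefined")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  out <- structure(list(slope = unname(stats::coef(fit)[2]),
                        intercept = unname(stats::coef(fit)[1]),
                        r_squared = r2, n_points = length(x)),
                   class = "regression_fit")
  if (both_orientations)
    out$reverse <- shared_event_regression(delta_psi_B, delta_psi_A)
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: slope %.3f, intercept %.2f, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Classify events by their response pattern across two knockdowns
#'
#' Partitions the common universe of testable events into mutually
#' exclusive classes:
#' \describe{
#'   \item{shared}{significant in both knockdowns, same direction.}
#'   \item{A_specific / B_specific}{significant only in one knockdown,
#'     with the other knockdown's delta-PSI either at or below
#'     `trend_threshold` in magnitude or of opposite sign — "truly
#'     specific" events.}
#'   \item{A_trend_in_B / B_trend_in_A}{significant only in one
#'     knockdown, but the other knockdown shows a same-direction,
#'     sub-significance delta-PSI exceeding `trend_threshold` — events
#'     that trend in the same direction.}
#'   \item{discordant}{significant in both with opposite directions —
#'     surfaced as an anomaly class worth individual validation.}
#'   \item{nonresponsive}{significant in neither.}
#' }
#'
#' @param calls_A,calls_B `event_calls` for the two knockdowns.
#' @param trend_threshold percentage points of same-direction delta-PSI
#'   above which a non-significant response counts as a trend (default 5;
#'   a sensitivity parameter, not doctrine).
#' @return A data.frame of class `event_classes` with columns `event_id`,
#'   `class`, `delta_psi_A`, `delta_psi_B`, `sig_A`, `sig_B`, `p_A`,
#'   `p_B`.
#' @export
classify_events <- function(calls_A, calls_B, trend_threshold = 5) {
  assert_scalar_number(trend_threshold, "trend_threshold")
  m <- merge(
    data.frame(event_id = calls_A$event_id, delta_psi_A = calls_A$delta_psi,
               sig_A = calls_A$significant, p_A = calls_A$p_value,
               stringsAsFactors = FALSE),
    data.frame(event_id = calls_B$event_id, delta_psi_B = calls_B$delta_psi,
               sig_B = calls_B$significant, p_B = calls_B$p_value,
               stringsAsFactors = FALSE),
    by = "event_id")
  if (nrow(m) == 0) stop_("empty universe: the call sets share no events")

  same_dir <- m$delta_psi_A * m$delta_psi_B > 0
  cls <- character(nrow(m))
  cls[m$sig_A & m$sig_B & same_dir] <- "shared"
  cls[m$sig_A & m$sig_B & !same_dir] <- "discordant"
  a_only <- m$sig_A & !m$sig_B
  b_only <- m$sig_B & !m$sig_A
  trend_B <- same_dir & abs(m$delta_psi_B) > trend_threshold
  trend_A <- same_dir & abs(m$delta_psi_A) > trend_threshold
  cls[a_only & trend_B] <- "A_trend_in_B"
  cls[a_only & !trend_B] <- "A_specific"
  cls[b_only & trend_A] <- "B_trend_in_A"
  cls[b_only & !trend_A] <- "B_specific"
  cls[!m$sig_A & !m$sig_B] <- "nonresponsive"

  out <- data.frame(event_id = m$event_id, class = cls,
                    delta_psi_A = m$delta_psi_A, delta_psi_B = m$delta_psi_B,
                    sig_A = m$sig_A, sig_B = m$sig_B,
                    p_A = m$p_A, p_B = m$p_B, stringsAsFactors = FALSE)
  class(out) <- c("event_classes", "data.frame")
  out
}

#' Interpret a rescue (re-expression) experiment
#'
#' In a rescue experiment one factor is re-expressed from cDNA in cells
#' depleted of a factor, asking how much of the knockdown's splicing
#' effect is reverted. The rescue fraction is
#' `(mean PSI_rescue - mean PSI_kd) / (mean PSI_wt - mean PSI_kd)`:
#' 0 means no reversion, 1 full reversion. It requires a measurable
#' knockdown effect (`|mean PSI_wt - mean PSI_kd| > 10` percentage
#' points); otherwise the outcome is untestable.
#'
#' When the event's sensitivity class is supplied, the outcome is mapped
#' to a regulatory model for a factor pair (A, B):
#' \describe{
#'   \item{antagonistic_direct}{no rescue of a B-specific event — the
#'     re-expressed partner already acts at capacity, consistent with
#'     direct antagonism in which depleting only B tips the balance.}
#'   \item{saturated_single}{no rescue of an A-specific event — the
#'     effect reflects a single saturating regulator, so partial
#'     depletion from the other hairpin never crossed threshold.}
#'   \item{cooperative}{partial (or full) rescue of a both-sensitive
#'     event — each factor contributes, and joint loss has the maximal
#'     effect.}
#' }
#'
#' @param psi_wt,psi_kd,psi_rescue numeric vectors of replicate PSI values
#'   (percent) for wildtype, knockdown, and knockdown + re-expression.
#' @param partial_band rescue-fraction interval called "partial"
#'   (default `c(0.25, 0.75)`): below the band is `no_rescue`, above it
#'   `full_rescue`. Qualitative thresholds exposed as configuration.
#' @param sensitivity optional event class: `"A_specific"`,
#'   `"B_specific"` or `"shared"`, used for the model mapping.
#' @return An object of class `rescue_outcome`: list with group means,
#'   `rescue_fraction`, `call` (`no_rescue` / `partial_rescue` /
#'   `full_rescue` / `untestable`) and `model` (or `NA`).
#' @export
classify_rescue <- function(psi_wt, psi_kd, psi_rescue,
                            partial_band = c(0.25, 0.75),
                            sensitivity = NULL) {
  assert_range(partial_band, "partial_band")
  m_wt <- mean(psi_wt); m_kd <- mean(psi_kd); m_res <- mean(psi_rescue)
  out <- list(mean_psi_wt = m_wt, mean_psi_kd = m_kd, mean_psi_rescue = m_res,
              partial_band = partial_band,
              rescue_fraction = NA_real_, call = "untestable",
              model = NA_character_)
  if (abs(m_wt - m_kd) > 10) {
    rf <- (m_res - m_kd) / (m_wt - m_kd)
    out$rescue_fraction <- rf
    out$call <- if (rf < partial_band[1]) "no_rescue"
      else if (rf > partial_band[2]) "full_rescue"
      else "partial_rescue"
    if (!is.null(sensitivity)) {
      sensitivity <- match.arg(sensitivity, c("A_specific", "B_specific", "shared"))
      out$model <- if (out$call == "no_rescue" && sensitivity == "B_specific")
        "antagonistic_direct"
      else if (out$call == "no_rescue" && sensitivity == "A_specific")
        "saturated_single"
      else if (out$call != "no_rescue" && sensitivity == "shared")
        "cooperative"
      else NA_character_
    }
  }
  structure(out, class = "rescue_outcome")
}

#' @export
print.rescue_outcome <- function(x, ...) {
  cat(sprintf("rescue_outcome: wt %.1f, kd %.1f, rescue %.1f -> fraction %s, %s\n",
              x$mean_psi_wt, x$mean_psi_kd, x$mean_psi_rescue,
              if (is.na(x$rescue_fraction)) "NA" else sprintf("%.2f", x$rescue_fraction),
              x$call))
  if (!is.na(x$model)) cat("  inferred model:", x$model, "\n")
  invisible(x)
}
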