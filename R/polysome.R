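#' Construct a polysome gradient profile
#'
#' A polysome profile records a target transcript's signal across sucrose
#' gradient fractions ordered light (free mRNPs/monosomes) to heavy
#' (polysomes), alongside the signal of an exogenous spike-in RNA added
#' to each fraction before RNA isolation. Dividing by the spike-in
#' cancels fraction-specific recovery differences.
#'
#' @param target_signal numeric vector of target signals, fraction 1..F
#'   (light to heavy), F >= 6.
#' @param spikein_signal matching spike-in signals, strictly positive.
#' @param chx cycloheximide status, `"plus"` or `"minus"`.
#' @param genotype optional condition label (e.g. "WT", "shRNA").
#' @param polysome_boundary first fraction index counted as polysomal
#'   (default `ceiling(0.5 * F) + 1`; the gradient midpoint is a
#'   convention, not a claim — every result records the boundary used).
#' @return An object of class `polysome_profile`.
#' @export
polysome_profile <- function(target_signal, spikein_signal,
                             chx = c("plus", "minus"), genotype = NA_character_,
                             polysome_boundary = NULL) {
  chx <- match.arg(chx)
  n <- length(target_signal)
  if (n < 6) stop_("a polysome profile needs >= 6 fractions (got %d)", n)
  if (length(spikein_signal) != n)
    stop_("target and spike-in signals must cover the same fractions")
  if (any(!is.finite(target_signal) | target_signal < 0))
    stop_("target signal must be non-negative and finite")
  bad <- which(!is.finite(spikein_signal) | spikein_signal <= 0)
  if (length(bad))
    stop_("spike-in signal is non-positive at fraction(s): %s",
          paste(bad, collapse = ", "))
  polysome_boundary <- polysome_boundary %||% (ceiling(0.5 * n) + 1)
  polysome_boundary <- assert_count(polysome_boundary, "polysome_boundary", min = 2L)
  if (polysome_boundary > n)
    stop_("polysome_boundary must be <= the number of fractions")
  structure(list(fraction = seq_len(n),
                 target_signal = as.numeric(target_signal),
                 spikein_signal = as.numeric(spikein_signal),
                 chx = chx, genotype = genotype,
                 polysome_boundary = polysome_boundary),
            class = "polysome_profile")
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat(sprintf("polysome_profile: %d fractions, %sCHX, boundary %d%s\n",
              length(x$fraction), if (x$chx == "plus") "+" else "-",
              x$polysome_boundary,
              if (is.na(x$genotype)) "" else paste0(", ", x$genotype)))
  invisible(x)
}

#' Spike-in-normalize a polysome profile
#'
#' Divides each fraction's target signal by its spike-in signal, then
#' rescales to a distribution summing to 1 over fractions. Because the
#' same known amount of spike-in RNA is present in every fraction, the
#' ratio removes fraction-specific recovery losses exactly.
#'
#' @param profile a [polysome_profile()].
#' @return A numeric vector (length F) summing to 1: the fraction-wise
#'   distribution of the transcript.
#' @export
spike_normalize <- function(profile) {
  stopifnot(inherits(profile, "polysome_profile"))
  ratio <- profile$target_signal / profile$spikein_signal
  total <- sum(ratio)
  if (total <= 0) stop_("profile has zero total signal after normalization")
  ratio / total
}

#' Proportion of a transcript's mass in polysome fractions
#'
#' @param distribution a normalized fraction-wise distribution (from
#'   [spike_normalize()]), summing to 1.
#' @param polysome_boundary first fraction index counted as polysomal;
#'   must lie in `2..length(distribution)`.
#' @return Sum of the distribution over fractions `>= polysome_boundary`,
#'   in `[0, 1]`.
#' @export
polysome_proportion <- function(distribution, polysome_boundary) {
  polysome_boundary <- assert_count(polysome_boundary, "polysome_boundary", min = 2L)
  if (polysome_boundary > length(distribution))
    stop_("polysome_boundary out of range (1 < boundary <= %d)",
          length(distribution))
  sum(distribution[seq_along(distribution) >= polysome_boundary])
}

#' Classify translation elongation from a +/- cycloheximide profile pair
#'
#' Cycloheximide (CHX) freezes elongating ribosomes, so an efficiently
#' translated mRNA is polysome-associated with CHX but runs off (shifts
#' to light fractions) without it. CHX-independent polysome association
#' — little difference between the two profiles — indicates poor
#' translation-elongation efficiency. The classifier computes the
#' polysomal mass proportion in each profile and calls
#' `efficient_elongation` when
#' `proportion(+CHX) - proportion(-CHX) > shift_threshold`, otherwise
#' `impaired_elongation`.
#'
#' @param profile_plus_chx,profile_minus_chx matched
#'   [polysome_profile()]s (+CHX and -CHX) with the same fraction count
#'   and polysome boundary.
#' @param shift_threshold minimum CHX-dependent shift of polysomal mass
#'   proportion calling elongation efficient (default 0.15).
#' @return An object of class `translation_call`: list with
#'   `proportion_plus`, `proportion_minus`, `chx_shift`, `call`,
#'   `shift_threshold`, `polysome_boundary`.
#' @export
classify_translation <- function(profile_plus_chx, profile_minus_chx,
                                 shift_threshold = 0.15) {
  stopifnot(inherits(profile_plus_chx, "polysome_profile"),
            inherits(profile_minus_chx, "polysome_profile"))
  assert_scalar_number(shift_threshold, "shift_threshold")
  if (length(profile_plus_chx$fraction) != length(profile_minus_chx$fraction))
    stop_("profiles have different fraction counts")
  if (profile_plus_chx$polysome_boundary != profile_minus_chx$polysome_boundary)
    stop_("profiles have different polysome boundaries")
  b <- profile_plus_chx$polysome_boundary
  p_plus <- polysome_proportion(spike_normalize(profile_plus_chx), b)
  p_minus <- polysome_proportion(spike_normalize(profile_minus_chx), b)
  shift <- p_plus - p_minus
  structure(list(proportion_plus = p_plus, proportion_minus = p_minus,
                 chx_shift = shift,
                 call = if (shift > shift_threshold) "efficient_elongation"
                        else "impaired_elongation",
                 shift_threshold = shift_threshold,
                 polysome_boundary = b),
            class = "translation_call")
}

#' @export
print.translation_call <- function(x, ...) {
  cat(sprintf("translation_call: polysomal mass +CHX %.2f, -CHX %.2f, shift %.2f -> %s\n",
              x$proportion_plus, x$proportion_minus, x$chx_shift, x$call))
  invisible(x)
}

#' Read polysome profiles from a TSV file
#'
#' Expects columns `fraction`, `target_signal`, `spikein_signal`,
#' `genotype`, `chx` (values `plus`/`minus`); one profile per
#' (genotype, chx) combination, fractions in order.
#'
#' @param path input TSV path.
#' @param polysome_boundary optional boundary applied to every profile.
#' @return A named list of [polysome_profile()]s, names
#'   `"<genotype>.<chx>"`.
#' @export
read_polysome_table <- function(path, polysome_boundary = NULL) {
  df <- read_tsv_(path, c("fraction", "target_signal", "spikein_signal",
                          "genotype", "chx"))
  out <- list()
  for (g in unique(df$genotype)) for (cx in unique(df$chx[df$genotype == g])) {
    sub <- df[df$genotype == g & df$chx == cx, ]
    sub <- sub[order(sub$fraction), ]
    out[[paste(g, cx, sep = ".")]] <- polysome_profile(
      sub$target_signal, sub$spikein_signal, chx = cx, genotype = g,
      polysome_boundary = polysome_boundary)
  }
  out
}
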