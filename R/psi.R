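#' Compute percent-spliced-in (PSI) values
#'
#' PSI for an event in a sample is 100 times the ratio of reads supporting
#' the long isoform to total reads (long + short). Cells with zero total
#' reads are undefined (`NA`) and are excluded from all downstream group
#' means and tests rather than imputed.
#'
#' @param x an [event_count_table()], normally after [filter_events()].
#' @return An object of class `psi_matrix`: a list with `psi`, an
#'   event-by-sample numeric matrix in percent (0-100, `NA` where
#'   undefined), and `samples`, the sample sheet.
#' @export
compute_psi <- function(x) {
  stopifnot(inherits(x, "event_count_table"))
  events <- unique(x$counts$event_id)
  sample_ids <- x$samples$sample_id
  psi <- matrix(NA_real_, nrow = length(events), ncol = length(sample_ids),
                dimnames = list(events, sample_ids))
  total <- x$counts$long_count + x$counts$short_count
  val <- ifelse(total > 0, 100 * x$counts$long_count / total, NA_real_)
  psi[cbind(match(x$counts$event_id, events),
            match(x$counts$sample_id, sample_ids))] <- val
  structure(list(psi = psi, samples = x$samples), class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("psi_matrix: %d events x %d samples, %d undefined cell(s)\n",
              nrow(x$psi), ncol(x$psi), sum(is.na(x$psi))))
  invisible(x)
}

# Vectorized two-sample t-test across the rows of two matrices.
# Pooled-variance (Student) by default; Welch optional. Rows where either
# group has < 2 defined values get NA. Degenerate rows with zero variance
# in both groups get p = 1 when the means agree and p = 0 otherwise.
row_t_test <- function(kd, ctrl, var_equal = TRUE) {
  n1 <- rowSums(!is.na(kd))
  n2 <- rowSums(!is.na(ctrl))
  m1 <- rowMeans(kd, na.rm = TRUE)
  m2 <- rowMeans(ctrl, na.rm = TRUE)
  v1 <- apply(kd, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(ctrl, 1L, stats::var, na.rm = TRUE)
  delta <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(delta / se), df)
  degen <- is.finite(delta) & !is.na(se) & se == 0
  p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  testable <- n1 >= 2 & n2 >= 2
  p[!testable] <- NA_real_
  list(delta = delta, p = p, mean_kd = m1, mean_ctrl = m2, testable = testable)
}

#' Compare two conditions event-wise: delta-PSI and significance calls
#'
#' For every event, computes the difference between the mean PSI of the
#' knockdown group and the mean PSI of the control group (delta-PSI, in
#' percentage points) and a two-sided unpaired Student's t-test on the
#' per-replicate PSI values. An event is called significant when
#' `|delta_psi| > dpsi_threshold` *and* `p_value < alpha` — both criteria
#' are required. Events with fewer than two defined PSI replicates in
#' either group are untestable and reported separately.
#'
#' @param psi a `psi_matrix` from [compute_psi()].
#' @param group_kd condition label of the knockdown group.
#' @param group_ctrl condition label of the control group.
#' @param dpsi_threshold minimum absolute delta-PSI, percentage points
#'   (default 10); strict inequality.
#' @param alpha significance level for the t-test p-value (default 0.05);
#'   strict inequality. No multiple-testing correction is applied: calls
#'   are made on raw p-values, faithfully reproducing the conventional
#'   targeted-assay analysis. Apply [stats::p.adjust()] to the `p_value`
#'   column if FDR control is wanted.
#' @param var_equal use the pooled-variance Student's t-test (default
#'   `TRUE`); set `FALSE` for Welch's unequal-variance test.
#' @return A data.frame of class `event_calls` with one row per testable
#'   event: `event_id`, `mean_psi_ctrl`, `mean_psi_kd`, `delta_psi`,
#'   `p_value`, `significant`, `direction` ("up"/"down"/"none"). IDs of
#'   untestable events are attached as `attr(, "untestable")`.
#' @export
compare_conditions <- function(psi, group_kd, group_ctrl,
                               dpsi_threshold = 10, alpha = 0.05,
                               var_equal = TRUE) {
  stopifnot(inherits(psi, "psi_matrix"))
  for (g in c(group_kd, group_ctrl))
    if (!g %in% psi$samples$condition)
      stop_("condition `%s` is not present in the sample sheet", g)
  kd_ids <- psi$samples$sample_id[psi$samples$condition == group_kd]
  ctrl_ids <- psi$samples$sample_id[psi$samples$condition == group_ctrl]
  tt <- row_t_test(psi$psi[, kd_ids, drop = FALSE],
                   psi$psi[, ctrl_ids, drop = FALSE], var_equal = var_equal)
  events <- rownames(psi$psi)
  calls <- data.frame(
    event_id = events[tt$testable],
    mean_psi_ctrl = tt$mean_ctrl[tt$testable],
    mean_psi_kd = tt$mean_kd[tt$testable],
    delta_psi = tt$delta[tt$testable],
    p_value = tt$p[tt$testable],
    stringsAsFactors = FALSE
  )
  calls$significant <- abs(calls$delta_psi) > dpsi_threshold & calls$p_value < alpha
  calls$direction <- ifelse(calls$delta_psi > 0, "up",
                            ifelse(calls$delta_psi < 0, "down", "none"))
  rownames(calls) <- NULL
  attr(calls, "untestable") <- events[!tt$testable]
  attr(calls, "groups") <- c(kd = group_kd, ctrl = group_ctrl)
  attr(calls, "dpsi_threshold") <- dpsi_threshold
  attr(calls, "alpha") <- alpha
  class(calls) <- c("event_calls", "data.frame")
  calls
}

#' Write event calls to a TSV file
#'
#' @param calls an `event_calls` data.frame from [compare_conditions()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_event_calls <- function(calls, path) {
  write_tsv_(as.data.frame(calls), path)
}

#' Read event calls from a TSV file
#'
#' @param path a TSV written by [write_event_calls()].
#' @return An `event_calls` data.frame.
#' @export
read_event_calls <- function(path) {
  calls <- read_tsv_(path, c("event_id", "mean_psi_ctrl", "mean_psi_kd",
                             "delta_psi", "p_value", "significant", "direction"))
  calls$event_id <- as.character(calls$event_id)
  calls$significant <- as.logical(calls$significant)
  class(calls) <- c("event_calls", "data.frame")
  calls
}

#' Check RT-PCR validation of a targeted-assay splicing call
#'
#' A call is validated when independent RT-PCR measurements show a
#' splicing change in the same direction as the original call, with
#' RT-PCR |delta-PSI| > `dpsi_threshold` and RT-PCR t-test
#' p < `alpha`.
#'
#' @param rasl_delta_psi delta-PSI of the original call (percentage
#'   points); only its sign is used.
#' @param rtpcr_kd,rtpcr_ctrl numeric vectors of replicate RT-PCR PSI
#'   values (percent) for the knockdown and control conditions.
#' @param dpsi_threshold,alpha validation thresholds (defaults 10 and
#'   0.05, strict inequalities).
#' @return `"validated"`, `"not_validated"`, or `"untestable"` when either
#'   condition has fewer than two replicates.
#' @export
validate_concordance <- function(rasl_delta_psi, rtpcr_kd, rtpcr_ctrl,
                                 dpsi_threshold = 10, alpha = 0.05) {
  assert_scalar_number(rasl_delta_psi, "rasl_delta_psi")
  if (length(rtpcr_kd) < 2 || length(rtpcr_ctrl) < 2) return("untestable")
  delta <- mean(rtpcr_kd) - mean(rtpcr_ctrl)
  p <- tryCatch(stats::t.test(rtpcr_kd, rtpcr_ctrl, var.equal = TRUE)$p.value,
                error = function(e) if (delta == 0) 1 else 0)
  ok <- sign(delta) == sign(rasl_delta_psi) &&
    abs(delta) > dpsi_threshold && p < alpha
  if (ok) "validated" else "not_validated"
}
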