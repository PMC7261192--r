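#' Construct a validated event count table
#'
#' An event count table holds, for every alternative-splicing event and
#' sample, the number of reads supporting the long (exon-included) and
#' short (exon-skipped) isoform, together with a sample sheet describing
#' the experimental design. It is the substrate for PSI quantification.
#'
#' @param counts data.frame with columns `event_id`, `sample_id`,
#'   `long_count`, `short_count`. Counts must be non-negative integers and
#'   every (event, sample) pair may appear at most once.
#' @param samples sample sheet data.frame with columns `sample_id`,
#'   `condition`, `replicate` and optionally `stimulation`. Every sample
#'   referenced in `counts` must appear here.
#' @return An object of class `event_count_table`: a list with elements
#'   `counts` and `samples`.
#' @examples
#' counts <- data.frame(
#'   event_id = c("ev1", "ev1"), sample_id = c("s1", "s2"),
#'   long_count = c(30L, 10L), short_count = c(10L, 30L))
#' samples <- data.frame(sample_id = c("s1", "s2"),
#'                       condition = c("control", "kd"), replicate = c(1L, 1L))
#' event_count_table(counts, samples)
#' @export
event_count_table <- function(counts, samples) {
  req <- c("event_id", "sample_id", "long_count", "short_count")
  missing <- setdiff(req, names(counts))
  if (length(missing))
    stop_("counts is missing column(s): %s", paste(missing, collapse = ", "))
  req_s <- c("sample_id", "condition", "replicate")
  missing <- setdiff(req_s, names(samples))
  if (length(missing))
    stop_("sample sheet is missing column(s): %s", paste(missing, collapse = ", "))

  counts$event_id <- as.character(counts$event_id)
  counts$sample_id <- as.character(counts$sample_id)
  samples$sample_id <- as.character(samples$sample_id)

  for (col in c("long_count", "short_count")) {
    x <- counts[[col]]
    if (!is.numeric(x)) stop_("column `%s` must be numeric", col)
    bad <- which(!is.finite(x) | x < 0 | x != floor(x))
    if (length(bad))
      stop_("column `%s` has negative or non-integer values at row(s): %s",
            col, paste(utils::head(bad, 5), collapse = ", "))
    counts[[col]] <- as.integer(x)
  }

  key <- paste(counts$event_id, counts$sample_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_("duplicate (event, sample) pair(s) at row(s): %s",
          paste(utils::head(dup, 5), collapse = ", "))

  if (anyDuplicated(samples$sample_id))
    stop_("sample sheet has duplicated sample_id values")
  unknown <- setdiff(unique(counts$sample_id), samples$sample_id)
  if (length(unknown))
    stop_("sample(s) present in counts but absent from the sample sheet: %s",
          paste(unknown, collapse = ", "))

  structure(list(counts = counts, samples = samples),
            class = "event_count_table")
}

#' Read an event count table and its sample sheet from TSV files
#'
#' @param path path to a tab-delimited file with columns `event_id`,
#'   `sample_id`, `long_count`, `short_count`.
#' @param sample_sheet_path path to a tab-delimited sample sheet with
#'   columns `sample_id`, `condition`, `replicate` (and optionally
#'   `stimulation`).
#' @return A validated [event_count_table()]. Malformed input (negative
#'   counts, duplicate pairs, unknown samples) is a hard error naming the
#'   offending rows.
#' @export
read_count_table <- function(path, sample_sheet_path) {
  counts <- read_tsv_(path, c("event_id", "sample_id", "long_count", "short_count"))
  samples <- read_tsv_(sample_sheet_path, c("sample_id", "condition", "replicate"))
  event_count_table(counts, samples)
}

#' Write an event count table and sample sheet to TSV files
#'
#' @param x an [event_count_table()].
#' @param path output path for the counts TSV.
#' @param sample_sheet_path output path for the sample sheet TSV.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(x, path, sample_sheet_path) {
  stopifnot(inherits(x, "event_count_table"))
  write_tsv_(x$counts, path)
  write_tsv_(x$samples, sample_sheet_path)
  invisible(path)
}

#' Filter events by mean read depth
#'
#' Retains exactly those events whose mean total read count
#' (long + short) across *all* samples in the sample sheet is strictly
#' greater than `min_mean_reads`. The strict inequality means events
#' sitting exactly at the threshold are removed. A sample with no row for
#' an event contributes zero reads to the mean.
#'
#' @param x an [event_count_table()].
#' @param min_mean_reads minimum mean total reads per event (default 10,
#'   the conventional depth filter for targeted isoform counting).
#' @return A filtered `event_count_table`.
#' @export
filter_events <- function(x, min_mean_reads = 10) {
  stopifnot(inherits(x, "event_count_table"))
  assert_scalar_number(min_mean_reads, "min_mean_reads")
  n_samples <- nrow(x$samples)
  totals <- x$counts$long_count + x$counts$short_count
  by_event <- tapply(totals, x$counts$event_id, sum)
  keep_ids <- names(by_event)[by_event / n_samples > min_mean_reads]
  x$counts <- x$counts[x$counts$event_id %in% keep_ids, , drop = FALSE]
  rownames(x$counts) <- NULL
  x
}

#' @export
print.event_count_table <- function(x, ...) {
  cat(sprintf("event_count_table: %d events x %d samples (%d count rows)\n",
              length(unique(x$counts$event_id)), nrow(x$samples), nrow(x$counts)))
  cond <- table(x$samples$condition)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(cond), cond), collapse = ", "), "\n")
  invisible(x)
}
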