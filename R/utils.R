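# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulations do not perturb the session stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_("`%s` must be > 0", name)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min)
    stop_("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop_("`%s` must be a numeric vector of length 2", name)
  if (x[1] > x[2]) stop_("`%s` has lower bound greater than upper bound", name)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path, required_cols) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_("%s is missing required column(s): %s", path, paste(missing, collapse = ", "))
  df
}
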