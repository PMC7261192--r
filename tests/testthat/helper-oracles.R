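# Independent oracles and small fixture builders used across the suite.

# Brute-force overlap distribution: fix set A = {1..nA} (valid by
# exchangeability of labels) and enumerate every size-nB subset of
# {1..N}, counting its overlap with A. Independent of phyper/dhyper.
overlap_counts_by_enumeration <- function(N, nA, nB) {
  if (nB == 0) {
    counts <- 1
    names(counts) <- "0"
    return(counts)
  }
  combs <- utils::combn(N, nB)
  if (is.null(dim(combs))) combs <- matrix(combs, nrow = nB)
  overlaps <- colSums(combs <= nA)
  tab <- table(factor(overlaps, levels = 0:min(nA, nB)))
  tab[tab > 0]
}

two_tailed_from_counts <- function(counts, k) {
  ks <- as.integer(names(counts))
  tot <- sum(counts)
  upper <- sum(counts[ks >= k]) / tot
  lower <- sum(counts[ks <= k]) / tot
  min(1, 2 * min(upper, lower))
}

# Textbook pooled-variance two-sample t-test, written from the formula.
pooled_t_p_value <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t_stat), n1 + n2 - 2)
}

# Tiny count-table builder: psi_by_group is a named list of per-sample
# PSI vectors; every event gets the same PSI pattern scaled to `total`.
make_table <- function(psi_values, conditions, total = 100L,
                       event_ids = "ev1") {
  samples <- data.frame(
    sample_id = paste0("s", seq_along(conditions)),
    condition = conditions,
    replicate = ave(seq_along(conditions), conditions, FUN = seq_along),
    stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(event_ids, function(ev) {
    data.frame(event_id = ev, sample_id = samples$sample_id,
               long_count = as.integer(round(total * psi_values / 100)),
               short_count = as.integer(total - round(total * psi_values / 100)),
               stringsAsFactors = FALSE)
  }))
  event_count_table(counts, samples)
}

# Minimal event_calls data.frame for classification tests.
make_calls <- function(event_id, delta_psi, p_value,
                       dpsi_threshold = 10, alpha = 0.05) {
  df <- data.frame(event_id = event_id,
                   mean_psi_ctrl = 50, mean_psi_kd = 50 + delta_psi,
                   delta_psi = delta_psi, p_value = p_value,
                   significant = abs(delta_psi) > dpsi_threshold & p_value < alpha,
                   direction = ifelse(delta_psi > 0, "up",
                                      ifelse(delta_psi < 0, "down", "none")),
                   stringsAsFactors = FALSE)
  class(df) <- c("event_calls", "data.frame")
  df
}
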