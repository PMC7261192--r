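test_that("count-table validation rejects malformed input", {
  counts <- data.frame(event_id = "ev1", sample_id = "s1",
                       long_count = 5L, short_count = 5L)
  samples <- data.frame(sample_id = "s1", condition = "control", replicate = 1L)
  expect_s3_class(event_count_table(counts, samples), "event_count_table")

  bad <- counts; bad$long_count <- -1L
  expect_error(event_count_table(bad, samples), "row\\(s\\): 1")

  dup <- rbind(counts, counts)
  expect_error(event_count_table(dup, samples), "duplicate")

  orphan <- counts; orphan$sample_id <- "s9"
  expect_error(event_count_table(orphan, samples), "s9")

  frac <- counts; frac$short_count <- 2.5
  expect_error(event_count_table(frac, samples), "non-integer")
})

test_that("read_count_table parses a well-formed fixture and flags bad rows", {
  d <- withr::local_tempdir()
  writeLines(c("event_id\tsample_id\tlong_count\tshort_count",
               "ev1\ts1\t30\t10", "ev2\ts1\t0\t50"),
             file.path(d, "counts.tsv"))
  writeLines(c("sample_id\tcondition\treplicate", "s1\tcontrol\t1"),
             file.path(d, "samples.tsv"))
  tab <- read_count_table(file.path(d, "counts.tsv"), file.path(d, "samples.tsv"))
  expect_equal(length(unique(tab$counts$event_id)), 2)

  writeLines(c("event_id\tsample_id\tlong_count\tshort_count",
               "ev1\ts1\t-1\t10"), file.path(d, "neg.tsv"))
  expect_error(read_count_table(file.path(d, "neg.tsv"),
                                file.path(d, "samples.tsv")),
               "row\\(s\\): 1")
  writeLines(c("event_id\tsample_id\tlong_count\tshort_count",
               "ev1\tsX\t1\t10"), file.path(d, "orphan.tsv"))
  expect_error(read_count_table(file.path(d, "orphan.tsv"),
                                file.path(d, "samples.tsv")),
               "sX")
})

test_that("read filter keeps events with mean total strictly above threshold", {
  # three events with mean totals 5, 10, 12 across two samples
  counts <- data.frame(
    event_id = rep(c("a", "b", "c"), each = 2),
    sample_id = rep(c("s1", "s2"), 3),
    long_count = c(2L, 3L, 5L, 5L, 6L, 6L),
    short_count = c(3L, 2L, 5L, 5L, 6L, 6L))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        condition = "control", replicate = 1:2)
  tab <- event_count_table(counts, samples)
  kept <- filter_events(tab, min_mean_reads = 10)
  expect_equal(unique(kept$counts$event_id), "c")  # 10 is not > 10
  # threshold 0 with all totals positive is the identity
  expect_equal(filter_events(tab, 0)$counts, tab$counts)
})

test_that("lowering the read-filter threshold never removes a retained event", {
  sim <- simulate_count_table(simulation_config(n_events = 300, mean_depth = 15,
                                                depth_dispersion = 0.6, seed = 21))
  thresholds <- c(30, 20, 10, 5, 0)
  prev <- character(0)
  for (th in thresholds) {
    kept <- unique(filter_events(sim$table, th)$counts$event_id)
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("PSI is the long/total ratio in percent with zero-total cells undefined", {
  counts <- data.frame(event_id = c("a", "b", "c"), sample_id = "s1",
                       long_count = c(30L, 0L, 0L),
                       short_count = c(10L, 50L, 0L))
  samples <- data.frame(sample_id = "s1", condition = "control", replicate = 1L)
  psi <- compute_psi(event_count_table(counts, samples))
  expect_equal(psi$psi["a", "s1"], 75)
  expect_equal(psi$psi["b", "s1"], 0)
  expect_true(is.na(psi$psi["c", "s1"]))
})

test_that("PSI identity and bounds hold on random tables", {
  sim <- simulate_count_table(simulation_config(n_events = 200, seed = 31))
  psi <- compute_psi(sim$table)
  expect_true(all(psi$psi >= 0 & psi$psi <= 100, na.rm = TRUE))
  long <- with(sim$table$counts, tapply(long_count, list(event_id, sample_id), sum))
  tot <- with(sim$table$counts,
              tapply(long_count + short_count, list(event_id, sample_id), sum))
  manual <- 100 * long / tot
  expect_equal(psi$psi[rownames(manual), colnames(manual)],
               manual, tolerance = 1e-12)
})

test_that("identical groups give delta 0 and p = 1", {
  tab <- make_table(c(10, 20, 30, 10, 20, 30),
                    rep(c("control", "kd"), each = 3), total = 1000L)
  calls <- compare_conditions(compute_psi(tab), "kd", "control")
  expect_equal(calls$delta_psi, 0)
  expect_equal(calls$p_value, 1)
  expect_false(calls$significant)
})

test_that("t-test matches the textbook pooled-variance value", {
  kd <- c(80, 82, 84); ctrl <- c(50, 52, 54)
  tab <- make_table(c(ctrl, kd), rep(c("control", "kd"), each = 3),
                    total = 1000L)
  calls <- compare_conditions(compute_psi(tab), "kd", "control")
  psi_kd <- 100 * round(1000 * kd / 100) / 1000    # realized PSI after rounding
  psi_ctrl <- 100 * round(1000 * ctrl / 100) / 1000
  expect_equal(calls$delta_psi, mean(psi_kd) - mean(psi_ctrl), tolerance = 1e-12)
  expect_equal(calls$p_value, pooled_t_p_value(psi_kd, psi_ctrl),
               tolerance = 1e-12)
  expect_equal(calls$p_value,
               t.test(psi_kd, psi_ctrl, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_true(calls$significant)
  expect_equal(calls$direction, "up")
})

test_that("significance requires both the delta-PSI and p-value criteria", {
  # large delta but noisy: p too big
  tab <- make_table(c(40, 60, 50, 55, 75, 61),
                    rep(c("control", "kd"), each = 3), total = 1000L)
  calls <- compare_conditions(compute_psi(tab), "kd", "control")
  expect_gt(abs(calls$delta_psi), 10)
  expect_gt(calls$p_value, 0.05)
  expect_false(calls$significant)
  # tight but small delta: p tiny, |delta| <= 10 -> still not significant
  tab2 <- make_table(c(50, 50.3, 49.7, 55, 55.3, 54.7),
                     rep(c("control", "kd"), each = 3), total = 10000L)
  calls2 <- compare_conditions(compute_psi(tab2), "kd", "control")
  expect_lt(calls2$p_value, 0.05)
  expect_false(calls2$significant)
  # boundary: delta exactly 10 fails the strict inequality
  tab3 <- make_table(c(50, 50, 50, 60, 60, 60),
                     rep(c("control", "kd"), each = 3), total = 1000L)
  calls3 <- compare_conditions(compute_psi(tab3), "kd", "control")
  expect_equal(calls3$delta_psi, 10)
  expect_false(calls3$significant)
})

test_that("Welch option changes the test but not the effect estimate", {
  tab <- make_table(c(40, 50, 60, 70, 71, 90),
                    rep(c("control", "kd"), each = 3), total = 1000L)
  psi <- compute_psi(tab)
  student <- compare_conditions(psi, "kd", "control")
  welch <- compare_conditions(psi, "kd", "control", var_equal = FALSE)
  expect_equal(student$delta_psi, welch$delta_psi)
  x <- psi$psi[1, 4:6]; y <- psi$psi[1, 1:3]
  expect_equal(welch$p_value, t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("events with undefined replicates are untestable, not guessed", {
  counts <- data.frame(
    event_id = rep(c("ok", "thin"), each = 6),
    sample_id = rep(paste0("s", 1:6), 2),
    long_count = c(rep(30L, 6), 30L, 0L, 0L, 30L, 0L, 0L),
    short_count = c(rep(70L, 6), 70L, 0L, 0L, 70L, 0L, 0L))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        condition = rep(c("control", "kd"), each = 3),
                        replicate = rep(1:3, 2))
  calls <- compare_conditions(compute_psi(event_count_table(counts, samples)),
                              "kd", "control")
  expect_equal(calls$event_id, "ok")
  expect_equal(attr(calls, "untestable"), "thin")
  expect_error(compare_conditions(compute_psi(event_count_table(counts, samples)),
                                  "kd", "missing_group"),
               "not present")
})

test_that("calls are invariant to sample ordering", {
  sim <- simulate_count_table(simulation_config(n_events = 100, seed = 41))
  psi1 <- compute_psi(sim$table)
  shuf <- sim$table
  set.seed(1)
  shuf$counts <- shuf$counts[sample(nrow(shuf$counts)), ]
  shuf$samples <- shuf$samples[sample(nrow(shuf$samples)), ]
  psi2 <- compute_psi(event_count_table(shuf$counts, shuf$samples))
  c1 <- compare_conditions(psi1, "kdA", "control")
  c2 <- compare_conditions(psi2, "kdA", "control")
  ord <- order(c1$event_id)
  ord2 <- order(c2$event_id)
  expect_equal(c1$delta_psi[ord], c2$delta_psi[ord2], tolerance = 1e-12)
  expect_equal(c1$p_value[ord], c2$p_value[ord2], tolerance = 1e-12)
})

test_that("power to call a 30-point shift at 5-point jitter is high", {
  cfg <- simulation_config(n_events = 1000, frac_shared = 0,
                           frac_A_specific = 1, frac_B_specific = 0,
                           frac_trending = 0,
                           delta_psi_magnitude_range = c(30, 30),
                           psi_noise_sd = 5, seed = 42)
  sim <- simulate_count_table(cfg)
  calls <- compare_conditions(compute_psi(filter_events(sim$table)),
                              "kdA", "control")
  expect_gte(mean(calls$significant), 0.90)
})

test_that("RT-PCR concordance follows direction, magnitude and significance", {
  up_good <- c(65, 66, 64); up_weak <- c(58, 59, 57)
  down <- c(38, 37, 39); ctrl <- c(50, 51, 49)
  expect_equal(validate_concordance(20, up_good, ctrl), "validated")
  expect_equal(validate_concordance(20, down, ctrl), "not_validated")
  expect_equal(validate_concordance(20, up_weak, ctrl), "not_validated")
  expect_equal(validate_concordance(-20, down, ctrl), "validated")
  expect_equal(validate_concordance(20, c(65), ctrl), "untestable")
})

test_that("event calls round-trip through TSV", {
  sim <- simulate_count_table(simulation_config(n_events = 50, seed = 51))
  calls <- compare_conditions(compute_psi(filter_events(sim$table)),
                              "kdA", "control")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_calls(calls, path)
  back <- read_event_calls(path)
  expect_equal(back$event_id, calls$event_id)
  expect_equal(back$delta_psi, calls$delta_psi, tolerance = 1e-9)
  expect_equal(back$significant, calls$significant)
})
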