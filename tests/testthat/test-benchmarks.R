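bench <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(cas = r[[1]], benchmark_type = r[[2]],
               value_ugL = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}
pb_analyte <- function() {
  data.frame(cas = "7439-92-1", units = "ug/L", reporting_limit = 0.1)
}

test_that("MCLG-zero substitution uses the override for lead, the reporting limit otherwise", {
  # Pb: MCLG = 0 with the shipped override -> 1 ug/L
  r <- resolve_benchmark("7439-92-1", bench(list("7439-92-1", "MCLG", 0)),
                         pb_analyte())
  expect_equal(r$value_ugL, 1)
  expect_true(r$substituted)
  expect_identical(r$substitution_origin, "fixed_value")

  # no override -> reporting limit (converted to ug/L)
  r2 <- resolve_benchmark("71-43-2", bench(list("71-43-2", "MCLG", 0)),
                          data.frame(cas = "71-43-2", units = "ug/L",
                                     reporting_limit = 0.1),
                          overrides = NULL)
  expect_equal(r2$value_ugL, 0.1)
  expect_true(r2$substituted)
  expect_identical(r2$substitution_origin, "reporting_limit")

  # reporting limit carried in mg/L converts
  r3 <- resolve_benchmark("71-43-2", bench(list("71-43-2", "MCLG", 0)),
                          data.frame(cas = "71-43-2", units = "mg/L",
                                     reporting_limit = 0.01),
                          overrides = NULL)
  expect_equal(r3$value_ugL, 10)

  # missing reporting limit is a configuration error
  expect_error(resolve_benchmark(
    "71-43-2", bench(list("71-43-2", "MCLG", 0)),
    data.frame(cas = "71-43-2", units = "ug/L",
               reporting_limit = NA_real_), overrides = NULL),
    "reporting_limit")
})

test_that("resolution picks the minimum health benchmark with provenance", {
  # nitrate: 10 mg/L MCLG beats the WHO guideline value
  r <- resolve_benchmark("14797-55-8",
                         bench(list("14797-55-8", "MCLG", 10000),
                               list("14797-55-8", "WHO_GV", 50000)),
                         NULL)
  expect_equal(r$value_ugL, 10000)
  expect_identical(r$source_type, "MCLG")
  expect_false(r$substituted)

  # enforceable SOQ never enters the resolution
  entries <- bench(list("7440-38-2", "SOQ", 5),
                   list("7440-38-2", "WHO_GV", 10))
  entries$enforceable <- c(TRUE, FALSE)
  r2 <- resolve_benchmark("7440-38-2", entries, NULL)
  expect_identical(r2$source_type, "WHO_GV")
  expect_equal(r2$value_ugL, 10)

  # no health benchmark at all -> NULL
  only_soq <- bench(list("7440-66-6", "SOQ", 5000))
  expect_null(resolve_benchmark("7440-66-6", only_soq, NULL))

  # ties break by the fixed type precedence
  r3 <- resolve_benchmark("67-66-3", bench(list("67-66-3", "HBSL", 70),
                                           list("67-66-3", "MCLG", 70)),
                          NULL)
  expect_identical(r3$source_type, "MCLG")
})

test_that("resolution is minimal, positive, and order-invariant", {
  set.seed(21)
  types <- c("MCLG", "WHO_GV", "WHO_pGV", "HBSL", "STATE_MCL", "DWHA")
  for (i in 1:40) {
    k <- sample(2:6, 1)
    ty <- sample(types, k)
    vals <- round(runif(k, 0.5, 100), 2)
    if ("MCLG" %in% ty && runif(1) < 0.4) vals[ty == "MCLG"] <- 0
    entries <- data.frame(cas = "67-66-3", benchmark_type = ty,
                          value_ugL = vals, stringsAsFactors = FALSE)
    an <- data.frame(cas = "67-66-3", units = "ug/L", reporting_limit = 0.1)
    r <- resolve_benchmark("67-66-3", entries, an, overrides = NULL)
    # oracle: exhaustive min over the post-substitution candidate set
    post <- ifelse(entries$benchmark_type == "MCLG" & entries$value_ugL == 0,
                   0.1, entries$value_ugL)
    expect_equal(r$value_ugL, min(post))
    expect_gt(r$value_ugL, 0)
    # order invariance
    perm <- sample(nrow(entries))
    r2 <- resolve_benchmark("67-66-3", entries[perm, ], an, overrides = NULL)
    expect_equal(r2, r)
    expect_identical(r$substituted, any(entries$benchmark_type == "MCLG" &
                                          entries$value_ugL == 0))
  }
})

test_that("TQ is the concentration-to-benchmark ratio", {
  expect_equal(compute_tq(0.5, 0.5), 1)
  expect_equal(compute_tq(1.1, 1), 1.1)  # max Pb over the 1 ug/L benchmark
  expect_equal(compute_tq(0.05, 0.5), 0.1)
  expect_error(compute_tq(1, 0), "> 0")
})

test_that("sigma-TQ is additive with sorted contributions and threshold flags", {
  panel <- tiny_panel()
  # benchmarks chosen to give TQs 0.6 and 0.5 in one sample
  resolved <- data.frame(cas = c("67-66-3", "7439-92-1"),
                         value_ugL = c(10, 1), source_type = "MCLG",
                         substituted = FALSE,
                         substitution_origin = NA_character_)
  recs <- data.frame(sample_id = "S01", cas = c("67-66-3", "7439-92-1"),
                     concentration = c(6, 0.5))
  study <- bw_study(tiny_samples(1), panel, recs)
  tq <- sum_tq(study, resolved)
  expect_equal(tq$totals$sigma_tq, 1.1)
  expect_true(tq$totals$exceeds_0p1 && tq$totals$exceeds_1)
  expect_false(tq$totals$any_single_tq_gt_1)
  expect_equal(tq$contributions$tq, c(0.6, 0.5))  # descending

  # no benchmarked detections -> 0, no flags
  tq0 <- sum_tq(study, resolved[0, ])
  expect_equal(tq0$totals$sigma_tq, 0)
  expect_false(tq0$totals$exceeds_0p1)
  expect_setequal(tq0$uncovered, c("67-66-3", "7439-92-1"))

  # a single contaminant alone above TQ = 1 is flagged
  recs2 <- data.frame(sample_id = "S01", cas = "7439-92-1",
                      concentration = 1.5)
  tq2 <- sum_tq(bw_study(tiny_samples(1), panel, recs2), resolved)
  expect_true(tq2$totals$any_single_tq_gt_1)
})

test_that("sigma-TQ is permutation-invariant and monotone under record removal", {
  fx <- default_fixtures()
  study <- generate_study(synthetic_config(seed = 5))
  resolved <- resolve_benchmarks(study$analytes, fx$benchmarks)
  tq <- sum_tq(study, resolved)
  shuffled <- study
  set.seed(9)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  tq_sh <- sum_tq(shuffled, resolved)
  expect_equal(tq_sh$totals$sigma_tq, tq$totals$sigma_tq)

  # dropping any detection never increases sigma-TQ
  det_idx <- which(study$records$status %in%
                     c("semiquantitative", "quantitative"))
  for (i in sample(det_idx, 5)) {
    less <- study
    less$records <- less$records[-i, ]
    tq_less <- sum_tq(less, resolved)
    expect_true(all(tq_less$totals$sigma_tq <= tq$totals$sigma_tq + 1e-12))
  }
})
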