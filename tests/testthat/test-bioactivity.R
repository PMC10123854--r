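acc_row <- function(cas, ep, value, units = "ug/L", family = "misc",
                    nonspecific = FALSE, baseline = FALSE,
                    unreliable = FALSE) {
  data.frame(cas = cas, assay_endpoint_id = ep, acc_value = value,
             acc_units = units, flag_nonspecific = nonspecific,
             flag_baseline = baseline, flag_unreliable = unreliable,
             endpoint_family = family, stringsAsFactors = FALSE)
}

test_that("ACC matching is exact-CAS with coverage and flag exclusion", {
  analytes <- data.frame(cas = sprintf("%d-00-0", 1:5), name = letters[1:5],
                         molecular_weight = NA_real_)
  acc <- rbind(acc_row(analytes$cas[1], "E1", 10),
               acc_row(analytes$cas[2], "E2", 20),
               acc_row(analytes$cas[3], "E3", 5, baseline = TRUE),
               acc_row("99-99-9", "E4", 7))  # not in panel
  m <- match_acc(analytes, acc)
  expect_equal(m$coverage$n_matched, 3)
  expect_equal(m$coverage$n_total, 5)
  expect_equal(m$coverage$pct, 60)
  # all-flagged chemical is matched but unusable
  expect_identical(m$matched_no_usable, analytes$cas[3])
  expect_setequal(unique(m$usable$cas), analytes$cas[1:2])

  # empty ACC table: zero coverage, no usable endpoints
  m0 <- match_acc(analytes, acc[0, ])
  expect_equal(m0$coverage$n_matched, 0)
  expect_equal(nrow(m0$usable), 0)
})

test_that("the 26-of-45 coverage arithmetic reports 58 percent", {
  analytes <- data.frame(cas = sprintf("%d-00-0", 1:45),
                         molecular_weight = NA_real_)
  acc <- do.call(rbind, lapply(1:26, function(i)
    acc_row(analytes$cas[i], paste0("E", i), 10)))
  m <- match_acc(analytes, acc)
  expect_equal(m$coverage$pct, 58)
})

test_that("ACC unit harmonization: uM converts via molecular weight", {
  # dimensional oracle: 1 uM of 1-butanol (74.12 g/mol) = 74.12 ug/L
  expect_equal(acc_to_ugL(1.0, "uM", 74.12), 74.12)
  expect_equal(acc_to_ugL(5.0, "ug/L", 999), 5.0)  # passthrough
  expect_equal(acc_to_ugL(c(1, 2), c("uM", "ug/L"), c(100, NA)), c(100, 2))
  expect_error(acc_to_ugL(0, "uM", 74.12), "positive")
  expect_error(acc_to_ugL(1, "uM", NA, cas = "71-36-3"), "71-36-3")
  expect_error(acc_to_ugL(1, "parsecs", 1), "unknown")
})

test_that("EAR is the detection-to-ACC ratio, one row per endpoint", {
  panel <- tiny_panel()
  recs <- data.frame(sample_id = "S01",
                     cas = c("67-66-3", "141-78-6"),
                     concentration = c(10, 0.5))
  study <- bw_study(tiny_samples(1), panel, recs)
  acc <- rbind(acc_row("67-66-3", "E1", 10),       # EAR = 1
               acc_row("67-66-3", "E2", 10000),    # EAR = 0.001
               acc_row("141-78-6", "E1", 1000))
  ear <- compute_ear(study, match_acc(detected_organics(study), acc))
  expect_equal(nrow(ear), 3)
  e <- ear[ear$cas == "67-66-3", ]
  expect_equal(sort(e$ear), c(0.001, 1))

  # recover printed-range EARs by inverting the ratio: acc = conc / ear
  target_ears <- c(1.35, 6.74)
  conc <- 6.0
  acc_inv <- do.call(rbind, lapply(seq_along(target_ears), function(i)
    acc_row("71-36-3", paste0("B", i), conc / target_ears[i])))
  butanol <- data.frame(cas = "71-36-3", name = "1-butanol",
                        analyte_class = "VOC", units = "ug/L", mdl = 0.2,
                        loq = 0.5, reporting_limit = 0.5,
                        molecular_weight = 74.12)
  st2 <- bw_study(tiny_samples(1), butanol,
                  data.frame(sample_id = "S01", cas = "71-36-3",
                             concentration = conc))
  ear2 <- compute_ear(st2, match_acc(st2$analytes, acc_inv))
  expect_equal(sort(ear2$ear), sort(target_ears), tolerance = 1e-12)
})

test_that("aggregation policies follow their definitions", {
  ear <- data.frame(
    sample_id = "S01",
    cas = c("a", "a", "b"),
    assay_endpoint_id = c("E1", "E2", "E2"),
    endpoint_family = c("f1", "f2", "f2"),
    conc_ugL = 1, acc_ugL = 1,
    ear = c(0.2, 0.5, 0.7), stringsAsFactors = FALSE)
  expect_equal(aggregate_ear(ear, "sum_of_chem_max")$totals$sigma_ear, 1.2)
  pe <- aggregate_ear(ear, "per_endpoint_sum_max")
  expect_equal(pe$totals$sigma_ear, 1.2)  # E2: 0.5 + 0.7
  expect_identical(pe$totals$top_endpoint, "E2")
  expect_identical(pe$totals$top_family, "f2")
  expect_equal(aggregate_ear(ear, "grand_sum")$totals$sigma_ear, 1.4)

  one_chem <- ear[ear$cas == "a", ]
  expect_equal(aggregate_ear(one_chem, "sum_of_chem_max")$totals$sigma_ear, 0.5)
  expect_equal(aggregate_ear(one_chem, "grand_sum")$totals$sigma_ear, 0.7)

  # sample with no matched chemicals: 0 under every policy
  for (pol in c("sum_of_chem_max", "per_endpoint_sum_max", "grand_sum")) {
    z <- aggregate_ear(ear[0, ], pol, sample_ids = "S09")
    expect_equal(z$totals$sigma_ear, 0)
    expect_false(z$totals$exceeds_0p001)
  }
  expect_error(aggregate_ear(ear, "mystery_policy"), "unknown")
})

test_that("grand sum dominates both other policies; sigma-EAR is monotone", {
  fx <- default_fixtures()
  for (seed in 1:10) {
    study <- generate_study(synthetic_config(seed = seed))
    ear <- compute_ear(study, fx$acc)
    ids <- study$samples$sample_id
    g <- aggregate_ear(ear, "grand_sum", ids)$totals$sigma_ear
    cm <- aggregate_ear(ear, "sum_of_chem_max", ids)$totals$sigma_ear
    pe <- aggregate_ear(ear, "per_endpoint_sum_max", ids)$totals$sigma_ear
    expect_true(all(g >= cm - 1e-12))
    expect_true(all(g >= pe - 1e-12))

    # raising any concentration never lowers any sigma-EAR
    up <- study
    det <- which(up$records$status %in% c("semiquantitative", "quantitative"))
    up$records$concentration[det] <- up$records$concentration[det] * 1.5
    up$records$status[det] <- "quantitative"
    ear_up <- compute_ear(up, fx$acc)
    for (pol in c("grand_sum", "sum_of_chem_max", "per_endpoint_sum_max")) {
      expect_true(all(aggregate_ear(ear_up, pol, ids)$totals$sigma_ear >=
                        aggregate_ear(ear, pol, ids)$totals$sigma_ear - 1e-12))
    }
  }
})

test_that("excluding a flagged assay never increases any EAR quantity", {
  panel <- tiny_panel()
  recs <- data.frame(sample_id = "S01", cas = "67-66-3", concentration = 10)
  study <- bw_study(tiny_samples(1), panel, recs)
  acc_clean <- rbind(acc_row("67-66-3", "E1", 100),
                     acc_row("67-66-3", "E2", 5))
  acc_flagged <- acc_clean
  acc_flagged$flag_unreliable[2] <- TRUE
  for (pol in c("grand_sum", "sum_of_chem_max", "per_endpoint_sum_max")) {
    with_flag <- aggregate_ear(compute_ear(study, acc_flagged), pol,
                               "S01")$totals$sigma_ear
    without <- aggregate_ear(compute_ear(study, acc_clean), pol,
                             "S01")$totals$sigma_ear
    expect_lte(with_flag, without)
  }
})

test_that("screening thresholds TQ = 0.1 and EAR = 0.001 coincide when ACC = 100 x benchmark", {
  # contaminant-specific equivalency of the two screening levels holds
  # exactly when the bioactivity cutoff sits two orders of magnitude
  # above the (margin-of-safety) health benchmark
  benchmark <- 50
  acc_val <- 100 * benchmark
  panel <- data.frame(cas = "71-43-2", name = "benzene",
                      analyte_class = "VOC", units = "ug/L",
                      mdl = 0.01, loq = 0.02, reporting_limit = 0.02,
                      molecular_weight = 78.11)
  conc <- 0.1 * benchmark  # TQ exactly 0.1
  study <- bw_study(tiny_samples(1), panel,
                    data.frame(sample_id = "S01", cas = "71-43-2",
                               concentration = conc))
  resolved <- data.frame(cas = "71-43-2", value_ugL = benchmark,
                         source_type = "WHO_GV", substituted = FALSE,
                         substitution_origin = NA_character_)
  tq <- sum_tq(study, resolved)
  ear <- aggregate_ear(compute_ear(study, acc_row("71-43-2", "E1", acc_val)),
                       "grand_sum", "S01")
  expect_identical(tq$totals$sigma_tq, 0.1)
  expect_identical(ear$totals$sigma_ear, 0.001)
  # and the equivalence is concentration-free: EAR / TQ = benchmark / ACC
  expect_identical(ear$totals$sigma_ear / tq$totals$sigma_tq, 0.01)
})
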