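test_that("the generator honors its configuration contract", {
  cfg <- synthetic_config(seed = 101)
  study <- generate_study(cfg)
  expect_equal(nrow(study$samples), 30)
  expect_equal(sum(study$samples$source_type == "purified_TW"), 7)
  expect_equal(sum(study$samples$origin == "imported"), 7)
  expect_equal(nrow(study$records), 30 * nrow(cfg$panel))

  # arsenic never appears in purified-TW samples (detection probability 0)
  pur <- study$samples$sample_id[study$samples$source_type == "purified_TW"]
  as_det <- study$records[study$records$cas == "7440-38-2" &
                            study$records$sample_id %in% pur, ]
  expect_true(all(as_det$status == "nondetect"))

  # determinism: the same seed reproduces the study exactly
  expect_identical(generate_study(cfg), generate_study(cfg))
  # a different seed does not
  other <- generate_study(synthetic_config(seed = 102))
  expect_false(identical(study$records$concentration,
                         other$records$concentration))
})

test_that("certain detection with a high median yields all-quantitative records", {
  panel <- tiny_panel()[3, ]
  cfg <- synthetic_config(
    n_purified_tw = 5, n_spring_domestic = 5, n_spring_imported = 0,
    panel = panel,
    detect_prob = data.frame(cas = panel$cas,
                             source_type = c("purified_TW", "spring"),
                             p = 1),
    conc_model = data.frame(cas = panel$cas, median = 50, gsd = 1.5),
    cooccur = data.frame(cas1 = character(), cas2 = character(),
                         source_type = character(), p_both = numeric()),
    blank_model = data.frame(cas = character(), p = numeric(),
                             median = numeric(), gsd = numeric()),
    seed = 7)
  study <- generate_study(cfg)
  expect_true(all(study$records$status == "quantitative"))
})

test_that("generated concentrations always respect their status invariants", {
  for (seed in c(3, 33, 333)) {
    study <- generate_study(synthetic_config(seed = seed))
    idx <- match(study$records$cas, study$analytes$cas)
    mdl <- study$analytes$mdl[idx]
    loq <- study$analytes$loq[idx]
    conc <- study$records$concentration
    st <- study$records$status
    expect_true(all(is.na(conc[st == "nondetect"])))
    expect_true(all(conc[st == "semiquantitative"] >= mdl[st == "semiquantitative"] &
                      conc[st == "semiquantitative"] < loq[st == "semiquantitative"]))
    expect_true(all(conc[st == "quantitative"] >= loq[st == "quantitative"]))
    # blanks obey the same classification
    bidx <- match(study$blanks$cas, study$analytes$cas)
    expect_identical(study$blanks$status,
                     classify_detection(study$blanks$concentration,
                                        study$analytes$mdl[bidx],
                                        study$analytes$loq[bidx]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(detect_prob = data.frame(
    cas = "67-66-3", source_type = "spring", p = 1.2)), "\\[0, 1\\]")
  cm <- default_conc_model()
  cm$gsd[1] <- 0.9
  expect_error(synthetic_config(conc_model = cm), "> 1")
  # co-occurrence outside the Frechet bounds of its marginals
  expect_error(synthetic_config(cooccur = data.frame(
    cas1 = "7440-38-2", cas2 = "7440-61-1", source_type = "spring",
    p_both = 0.99)), "Frechet")
})

test_that("calibration sets expected subgroup frequencies exactly", {
  cfg <- synthetic_config(seed = 1)
  cal <- calibrate_to_frequencies(cfg, data.frame(
    cas = c("7439-92-1", "7440-38-2", "122-34-9", "1912-24-9"),
    subgroup = c("overall", "purified_TW", "overall", "spring"),
    frac = c(5 / 30, 0, 0, 1)))
  dp <- cal$detect_prob
  p_of <- function(cas, st) dp$p[dp$cas == cas & dp$source_type == st]
  expect_equal(p_of("7439-92-1", "purified_TW"), 5 / 30)
  expect_equal(p_of("7439-92-1", "spring"), 5 / 30)
  expect_equal(p_of("7440-38-2", "purified_TW"), 0)
  expect_equal(p_of("122-34-9", "spring"), 0)
  expect_equal(p_of("1912-24-9", "spring"), 1)
  ec <- attr(cal, "expected_counts")
  expect_equal(ec$expected_count[1], 5)
  # target 1 -> detected in every spring sample
  study <- generate_study(cal)
  spring <- study$samples$sample_id[study$samples$source_type == "spring"]
  atrazine <- study$records[study$records$cas == "1912-24-9" &
                              study$records$sample_id %in% spring, ]
  expect_true(all(atrazine$status %in% c("semiquantitative", "quantitative")))

  expect_error(calibrate_to_frequencies(
    synthetic_config(n_purified_tw = 0, seed = 1),
    data.frame(cas = "67-66-3", subgroup = "purified_TW", frac = 0.5)),
    "subgroup size 0")
})

test_that("detection frequencies converge to configured probabilities", {
  # law of large numbers over replicate studies for a few tracked analytes
  n_rep <- 60
  hits <- c(pb = 0, as_spring = 0, u_spring = 0)
  n_pb <- 0; n_spring <- 0
  for (r in seq_len(n_rep)) {
    study <- generate_study(synthetic_config(seed = 5000 + r))
    det <- study$records[study$records$status %in%
                           c("semiquantitative", "quantitative"), ]
    spring <- study$samples$sample_id[study$samples$source_type == "spring"]
    hits["pb"] <- hits["pb"] +
      length(unique(det$sample_id[det$cas == "7439-92-1"]))
    hits["as_spring"] <- hits["as_spring"] +
      length(unique(det$sample_id[det$cas == "7440-38-2" &
                                    det$sample_id %in% spring]))
    hits["u_spring"] <- hits["u_spring"] +
      length(unique(det$sample_id[det$cas == "7440-61-1" &
                                    det$sample_id %in% spring]))
    n_pb <- n_pb + 30
    n_spring <- n_spring + length(spring)
  }
  ci_contains <- function(k, n, p) {
    ci <- binom.test(k, n)$conf.int
    p >= ci[1] && p <= ci[2]
  }
  expect_true(ci_contains(hits[["pb"]], n_pb, 5 / 30))
  expect_true(ci_contains(hits[["as_spring"]], n_spring, 20 / 23))
  expect_true(ci_contains(hits[["u_spring"]], n_spring, 17 / 23))
})

test_that("fixture tables embed the study's regulatory facts", {
  fx <- default_fixtures()
  b <- fx$benchmarks
  mclg0 <- b$cas[b$benchmark_type == "MCLG" & b$value_ugL == 0]
  # the six MCLG-zero organics plus As, U, Pb
  expect_true(all(c("75-27-4", "75-25-2", "75-09-2",   # DBP
                    "127-18-4", "71-43-2", "79-01-6",  # VOC
                    "7440-38-2", "7440-61-1", "7439-92-1") %in% mclg0))
  expect_equal(b$value_ugL[b$cas == "14797-55-8" &
                             b$benchmark_type == "MCLG"], 10000)
  expect_equal(fx$annotations$value_ugL[fx$annotations$cas == "16984-48-8"],
               700)
  # ACC fixture covers roughly 58 % of the organic panel
  panel <- default_panel()
  organics <- panel[panel$analyte_class != "inorganic", ]
  cov <- detection_percent(length(intersect(unique(fx$acc$cas),
                                            organics$cas)),
                           nrow(organics))
  expect_gte(cov, 50)
  expect_lte(cov, 65)
  expect_true(all(cas_is_valid(b$cas)))
  expect_true(all(cas_is_valid(fx$acc$cas)))
})
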