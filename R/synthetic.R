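#' Default synthetic analyte panel
#'
#' A 28-analyte panel spanning the analyte classes of a bottled-water
#' survey: trace inorganics (As, U, Pb), major ions carried in mg/L
#' (nitrate-N, fluoride, bromide, sulfate), trihalomethane disinfection
#' byproducts, volatile organics, and pesticides, each with
#' plausible-scale method detection limits and limits of quantitation.
#' CAS numbers are real registry numbers; detection limits, molecular
#' weights and downstream fixture values are synthetic study parameters,
#' not laboratory data.
#'
#' @return Analyte panel data frame (see [bw_study()]).
#' @export
default_panel <- function() {
  p <- function(cas, name, cls, units, mdl, loq, mw = NA_real_) {
    data.frame(cas = cas, name = name, analyte_class = cls, units = units,
               mdl = mdl, loq = loq, reporting_limit = loq,
               molecular_weight = mw, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("7440-38-2", "arsenic", "inorganic", "ug/L", 0.04, 0.1),
    p("7440-61-1", "uranium", "inorganic", "ug/L", 0.04, 0.1),
    p("7439-92-1", "lead", "inorganic", "ug/L", 0.04, 0.1),
    p("14797-55-8", "nitrate-N", "inorganic", "mg/L", 0.01, 0.04),
    p("16984-48-8", "fluoride", "inorganic", "mg/L", 0.01, 0.02),
    p("24959-67-9", "bromide", "inorganic", "mg/L", 0.01, 0.03),
    p("14808-79-8", "sulfate", "inorganic", "mg/L", 0.02, 0.09),
    p("7440-66-6", "zinc", "inorganic", "ug/L", 0.5, 2),
    p("7440-39-3", "barium", "inorganic", "ug/L", 0.1, 0.25),
    p("7440-24-6", "strontium", "inorganic", "ug/L", 0.2, 0.5),
    p("67-66-3", "trichloromethane", "DBP", "ug/L", 0.05, 0.1, 119.38),
    p("75-27-4", "bromodichloromethane", "DBP", "ug/L", 0.05, 0.1, 163.82),
    p("75-25-2", "tribromomethane", "DBP", "ug/L", 0.05, 0.1, 252.73),
    p("124-48-1", "dibromochloromethane", "DBP", "ug/L", 0.05, 0.1, 208.28),
    p("75-09-2", "dichloromethane", "DBP", "ug/L", 0.05, 0.1, 84.93),
    p("127-18-4", "tetrachloroethene", "VOC", "ug/L", 0.05, 0.1, 165.83),
    p("71-43-2", "benzene", "VOC", "ug/L", 0.05, 0.1, 78.11),
    p("79-01-6", "trichloroethene", "VOC", "ug/L", 0.05, 0.1, 131.39),
    p("108-88-3", "toluene", "VOC", "ug/L", 0.05, 0.1, 92.14),
    p("71-36-3", "1-butanol", "VOC", "ug/L", 0.2, 0.5, 74.12),
    p("141-78-6", "ethyl acetate", "VOC", "ug/L", 0.02, 0.05, 88.11),
    p("75-05-8", "acetonitrile", "VOC", "ug/L", 0.1, 0.3, 41.05),
    p("110-62-3", "n-pentanal", "VOC", "ug/L", 0.005, 0.01, 86.13),
    p("75-37-6", "1,1-difluoroethane", "VOC", "ug/L", 0.005, 0.01, 66.05),
    p("75-45-6", "chlorodifluoromethane", "VOC", "ug/L", 0.005, 0.01, 86.47),
    p("1912-24-9", "atrazine", "pesticide", "ug/L", 0.03, 0.06, 215.68),
    p("122-34-9", "simazine", "pesticide", "ug/L", 0.03, 0.06, 201.66),
    p("51218-45-2", "metolachlor", "pesticide", "ug/L", 0.03, 0.06, 283.79)
  ))
}

# Default per-analyte detection probabilities by source type, reflecting
# the survey's qualitative structure: geogenic trace elements (As, U)
# confined to spring-sourced samples, chlorination byproducts enriched in
# purified-tapwater samples, pesticides sporadic in spring samples.
default_detect_prob <- function(panel = default_panel()) {
  d <- function(cas, p_purified, p_spring) {
    data.frame(cas = cas,
               source_type = c("purified_TW", "spring"),
               p = c(p_purified, p_spring), stringsAsFactors = FALSE)
  }
  probs <- do.call(rbind, list(
    d("7440-38-2", 0, 20 / 23),
    d("7440-61-1", 0, 17 / 23),
    d("7439-92-1", 1 / 7, 4 / 23),
    d("14797-55-8", 0.85, 0.9),
    d("16984-48-8", 0.8, 0.8),
    d("24959-67-9", 0.3, 0.5),
    d("14808-79-8", 0.95, 0.95),
    d("7440-66-6", 0.4, 0.4),
    d("7440-39-3", 0.3, 0.85),
    d("7440-24-6", 0.4, 0.95),
    d("67-66-3", 6 / 7, 4 / 23),
    d("75-27-4", 6 / 7, 2 / 23),
    d("75-25-2", 0, 5 / 23),
    d("124-48-1", 3 / 7, 1 / 23),
    d("75-09-2", 2 / 7, 2 / 23),
    d("127-18-4", 1 / 7, 4 / 23),
    d("71-43-2", 1 / 7, 2 / 23),
    d("79-01-6", 0, 1 / 23),
    d("108-88-3", 1 / 7, 3 / 23),
    d("71-36-3", 0, 3 / 23),
    d("141-78-6", 1 / 7, 2 / 23),
    d("75-05-8", 5 / 7, 3 / 23),
    d("110-62-3", 1 / 7, 2 / 23),
    d("75-37-6", 1 / 7, 2 / 23),
    d("75-45-6", 1 / 7, 2 / 23),
    d("1912-24-9", 0, 2 / 23),
    d("122-34-9", 0, 1 / 23),
    d("51218-45-2", 0, 2 / 23)
  ))
  probs[probs$cas %in% panel$cas, , drop = FALSE]
}

# Log-normal concentration model for detected results, in each analyte's
# native units: geometric median and geometric standard deviation,
# truncated below at the MDL at draw time.
default_conc_model <- function(panel = default_panel()) {
  m <- function(cas, median, gsd) {
    data.frame(cas = cas, median = median, gsd = gsd,
               stringsAsFactors = FALSE)
  }
  mods <- do.call(rbind, list(
    m("7440-38-2", 0.8, 3), m("7440-61-1", 0.9, 3), m("7439-92-1", 0.2, 2),
    m("14797-55-8", 0.35, 3.5), m("16984-48-8", 0.1, 2.2),
    m("24959-67-9", 0.05, 2.5), m("14808-79-8", 5, 3),
    m("7440-66-6", 5, 3), m("7440-39-3", 30, 3), m("7440-24-6", 200, 3),
    m("67-66-3", 8, 3), m("75-27-4", 2, 3), m("75-25-2", 2, 3),
    m("124-48-1", 1, 3), m("75-09-2", 0.3, 2.5),
    m("127-18-4", 0.3, 2.5), m("71-43-2", 0.15, 2), m("79-01-6", 0.15, 2),
    m("108-88-3", 0.2, 2), m("71-36-3", 6, 2), m("141-78-6", 0.3, 2.5),
    m("75-05-8", 0.5, 2.5), m("110-62-3", 0.2, 2), m("75-37-6", 0.1, 2),
    m("75-45-6", 0.1, 2),
    m("1912-24-9", 0.03, 2), m("122-34-9", 0.03, 2), m("51218-45-2", 0.03, 2)
  ))
  mods[mods$cas %in% panel$cas, , drop = FALSE]
}

# Correlated detection for geogenic co-occurrence: exact joint 2x2 cell
# probabilities per sample for listed pairs (marginals stay at the
# configured per-analyte detection probabilities).
default_cooccur <- function() {
  data.frame(cas1 = "7440-38-2", cas2 = "7440-61-1",
             source_type = "spring", p_both = 16 / 23,
             stringsAsFactors = FALSE)
}

# Sporadic low-level blank contamination: major ions at trace levels and
# four volatile organics with single-detection-scale levels.
default_blank_model <- function(panel = default_panel()) {
  b <- function(cas, p, median, gsd) {
    data.frame(cas = cas, p = p, median = median, gsd = gsd,
               stringsAsFactors = FALSE)
  }
  mods <- do.call(rbind, list(
    b("24959-67-9", 0.4, 0.02, 1.5),
    b("14808-79-8", 0.4, 0.05, 1.5),
    b("7440-66-6", 0.4, 1.0, 1.5),
    b("75-45-6", 1 / 3, 0.02, 1.2),
    b("75-37-6", 1 / 3, 0.01, 1.2),
    b("141-78-6", 1 / 3, 0.09, 1.2),
    b("110-62-3", 1 / 3, 0.011, 1.2)
  ))
  mods[mods$cas %in% panel$cas, , drop = FALSE]
}

#' Synthetic bottled-water study configuration
#'
#' Parameterizes the synthetic study generator. The defaults emulate the
#' structure of a 30-sample bottled-water survey: 7 purified-tapwater
#' (domestic), 16 spring domestic and 7 spring imported samples, the
#' [default_panel()] analyte panel, per-analyte x source-type Bernoulli
#' detection probabilities, log-normal detected concentrations truncated
#' below at the MDL, an exactly calibrated As-U co-occurrence joint for
#' spring samples, and sporadic low-level blank contamination across
#' three blanks.
#'
#' @param n_purified_tw,n_spring_domestic,n_spring_imported Group sizes.
#' @param panel Analyte panel data frame.
#' @param detect_prob Data frame `cas`, `source_type`, `p`.
#' @param conc_model Data frame `cas`, `median`, `gsd` (native units).
#' @param cooccur Data frame `cas1`, `cas2`, `source_type`, `p_both` of
#'   exactly calibrated pairwise joint detection probabilities.
#' @param blank_model Data frame `cas`, `p`, `median`, `gsd`.
#' @param n_blanks Number of blank samples.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_purified_tw = 7, n_spring_domestic = 16,
                             n_spring_imported = 7,
                             panel = default_panel(),
                             detect_prob = default_detect_prob(panel),
                             conc_model = default_conc_model(panel),
                             cooccur = default_cooccur(),
                             blank_model = default_blank_model(panel),
                             n_blanks = 3, seed = 1L) {
  stopifnot(n_purified_tw >= 0, n_spring_domestic >= 0,
            n_spring_imported >= 0)
  if (any(detect_prob$p < 0 | detect_prob$p > 1)) {
    stop("detection probabilities must be in [0, 1]")
  }
  if (any(conc_model$gsd <= 1)) stop("geometric standard deviations must be > 1")
  if (nrow(cooccur)) check_cooccur(cooccur, detect_prob)
  structure(list(n_purified_tw = n_purified_tw,
                 n_spring_domestic = n_spring_domestic,
                 n_spring_imported = n_spring_imported,
                 panel = panel, detect_prob = detect_prob,
                 conc_model = conc_model, cooccur = cooccur,
                 blank_model = blank_model, n_blanks = n_blanks,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

check_cooccur <- function(cooccur, detect_prob) {
  for (i in seq_len(nrow(cooccur))) {
    p1 <- prob_for(detect_prob, cooccur$cas1[i], cooccur$source_type[i])
    p2 <- prob_for(detect_prob, cooccur$cas2[i], cooccur$source_type[i])
    p11 <- cooccur$p_both[i]
    lo <- max(0, p1 + p2 - 1)
    hi <- min(p1, p2)
    if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
      stop(sprintf(
        "co-occurrence p_both=%.4g for (%s, %s) is outside the Frechet bounds [%.4g, %.4g] of the marginals",
        p11, cooccur$cas1[i], cooccur$cas2[i], lo, hi))
    }
  }
  invisible(TRUE)
}

prob_for <- function(detect_prob, cas, source_type) {
  hit <- detect_prob$cas == cas & detect_prob$source_type == source_type
  if (!any(hit)) 0 else detect_prob$p[hit][1]
}

# Log-normal truncated below at `lower` via inverse-CDF sampling.
rlnorm_trunc <- function(n, median, gsd, lower) {
  meanlog <- log(median)
  sdlog <- log(gsd)
  plo <- stats::plnorm(lower, meanlog, sdlog)
  u <- stats::runif(n, plo, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic bottled-water study
#'
#' Draws a full [bw_study()] from a [synthetic_config()]: per sample and
#' analyte a Bernoulli detection (exact joint cells for configured
#' co-occurring pairs), a truncated log-normal concentration for
#' detections, a detection status via [classify_detection()], and blank
#' records from the blank contamination model. Fully reproducible from
#' the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return A `bw_study`.
#' @examples
#' study <- generate_study(synthetic_config(seed = 42))
#' study
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_purified_tw + config$n_spring_domestic +
    config$n_spring_imported
  samples <- data.frame(
    sample_id = sprintf("BW%02d", seq_len(n)),
    source_type = c(rep("purified_TW", config$n_purified_tw),
                    rep("spring", config$n_spring_domestic),
                    rep("spring", config$n_spring_imported)),
    origin = c(rep("domestic", config$n_purified_tw),
               rep("domestic", config$n_spring_domestic),
               rep("imported", config$n_spring_imported)),
    stringsAsFactors = FALSE)
  samples$treatment <- ifelse(
    samples$source_type == "purified_TW", "reverse_osmosis",
    sample(c("none_listed", "ozonation", "uv"), n, replace = TRUE,
           prob = c(0.6, 0.25, 0.15)))
  samples$packaging <- sample(c("plastic", "glass", "aluminum", "carton"),
                              n, replace = TRUE,
                              prob = c(0.6, 0.2, 0.1, 0.1))

  panel <- config$panel
  cm <- config$conc_model
  pair_cas <- unique(c(config$cooccur$cas1, config$cooccur$cas2))

  records <- vector("list", n)
  for (si in seq_len(n)) {
    st <- samples$source_type[si]
    detected <- logical(nrow(panel))
    names(detected) <- panel$cas
    # exactly calibrated joint cells for co-occurring pairs
    handled <- character()
    cc <- config$cooccur
    if (nrow(cc)) {
      for (k in seq_len(nrow(cc))) {
        c1 <- cc$cas1[k]; c2 <- cc$cas2[k]
        if (cc$source_type[k] == st && c1 %in% panel$cas &&
            c2 %in% panel$cas) {
          p1 <- prob_for(config$detect_prob, c1, st)
          p2 <- prob_for(config$detect_prob, c2, st)
          p11 <- cc$p_both[k]
          u <- stats::runif(1)
          # cells in fixed order: both, first only, second only, neither
          p10 <- p1 - p11; p01 <- p2 - p11
          if (u < p11) { detected[c1] <- TRUE; detected[c2] <- TRUE }
          else if (u < p11 + p10) detected[c1] <- TRUE
          else if (u < p11 + p10 + p01) detected[c2] <- TRUE
          handled <- c(handled, c1, c2)
        }
      }
    }
    for (ai in seq_len(nrow(panel))) {
      cas <- panel$cas[ai]
      if (cas %in% handled) next
      detected[cas] <- stats::runif(1) < prob_for(config$detect_prob, cas, st)
    }
    conc <- rep(NA_real_, nrow(panel))
    for (ai in seq_len(nrow(panel))) {
      if (!detected[ai]) next
      mi <- match(panel$cas[ai], cm$cas)
      if (is.na(mi)) stop("no concentration model for ", panel$cas[ai])
      conc[ai] <- rlnorm_trunc(1, cm$median[mi], cm$gsd[mi], panel$mdl[ai])
    }
    records[[si]] <- data.frame(
      sample_id = samples$sample_id[si], cas = panel$cas,
      concentration = conc, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)

  bm <- config$blank_model
  blanks <- list()
  for (bi in seq_len(config$n_blanks)) {
    bid <- sprintf("BLK%02d", bi)
    for (k in seq_len(nrow(bm))) {
      if (!bm$cas[k] %in% panel$cas) next
      if (stats::runif(1) < bm$p[k]) {
        ai <- match(bm$cas[k], panel$cas)
        conc <- rlnorm_trunc(1, bm$median[k], bm$gsd[k], panel$mdl[ai])
        blanks[[length(blanks) + 1]] <- data.frame(
          sample_id = bid, cas = bm$cas[k], concentration = conc,
          stringsAsFactors = FALSE)
      }
    }
  }
  blanks <- if (length(blanks)) do.call(rbind, blanks) else empty_records()

  bw_study(samples = samples, analytes = panel, records = records,
           blanks = blanks)
}

#' Calibrate detection probabilities to target frequencies
#'
#' Sets per-analyte Bernoulli detection probabilities so the expected
#' subgroup detection frequencies equal the supplied targets — the bridge
#' from a survey's printed detection counts (e.g. 5 of 30 samples) to a
#' generator configuration that recovers them in expectation.
#'
#' @param config A [synthetic_config()] to modify.
#' @param targets Data frame with columns `cas`, `subgroup` (one of
#'   `"purified_TW"`, `"spring"`, `"overall"`), and `frac` in `[0, 1]`.
#' @return The updated configuration; attribute `expected_counts`
#'   documents the implied expected subgroup detection counts.
#' @export
calibrate_to_frequencies <- function(config, targets) {
  stopifnot(inherits(config, "synthetic_config"))
  req(targets, c("cas", "subgroup", "frac"), "targets")
  if (any(targets$frac < 0 | targets$frac > 1)) {
    stop("target fractions must be in [0, 1]")
  }
  n_p <- config$n_purified_tw
  n_s <- config$n_spring_domestic + config$n_spring_imported
  dp <- config$detect_prob
  set_p <- function(dp, cas, source_type, p) {
    hit <- dp$cas == cas & dp$source_type == source_type
    if (any(hit)) dp$p[hit] <- p
    else dp <- rbind(dp, data.frame(cas = cas, source_type = source_type,
                                    p = p, stringsAsFactors = FALSE))
    dp
  }
  expected <- list()
  for (i in seq_len(nrow(targets))) {
    cas <- targets$cas[i]; sub <- targets$subgroup[i]
    frac <- targets$frac[i]
    if (sub == "overall") {
      if (n_p + n_s == 0 && frac > 0) stop("subgroup size 0 with nonzero target")
      dp <- set_p(dp, cas, "purified_TW", frac)
      dp <- set_p(dp, cas, "spring", frac)
      expected[[i]] <- data.frame(cas = cas, subgroup = sub,
                                  n = n_p + n_s,
                                  expected_count = frac * (n_p + n_s))
    } else {
      n_sub <- if (sub == "purified_TW") n_p else n_s
      if (n_sub == 0 && frac > 0) stop("subgroup size 0 with nonzero target")
      dp <- set_p(dp, cas, sub, frac)
      expected[[i]] <- data.frame(cas = cas, subgroup = sub, n = n_sub,
                                  expected_count = frac * n_sub)
    }
  }
  config$detect_prob <- dp
  if (nrow(config$cooccur)) check_cooccur(config$cooccur, dp)
  attr(config, "expected_counts") <- do.call(rbind, expected)
  config
}

#' Default benchmark, bioactivity, and censoring-policy fixtures
#'
#' Ships the fixture tables that accompany the default synthetic panel:
#' a benchmark registry embedding the survey's regulatory facts (MCLG of
#' zero for As, U, Pb and for bromodichloromethane, tribromomethane,
#' dichloromethane, tetrachloroethene, benzene and trichloroethene; the
#' 10 mg/L nitrate-N MCLG; enforceable standards of quality), a
#' synthetic plausible-scale ACC bioactivity table covering roughly
#' 58 percent of the organic panel with DNA-binding and other endpoint
#' families plus flagged records, a fluoride 0.7 mg/L reference value
#' carried as a non-benchmark annotation, and the blank censoring policy
#' (doubled rule for the four blank-detected volatiles,
#' chlorodifluoromethane removed).
#'
#' @return List with elements `benchmarks` (data frame), `acc` (data
#'   frame), `censor_policy` (a [censor_policy()]), and `annotations`
#'   (non-benchmark reference values).
#' @export
default_fixtures <- function() {
  b <- function(cas, type, value, enforceable = FALSE) {
    data.frame(cas = cas, benchmark_type = type, value_ugL = value,
               enforceable = enforceable, stringsAsFactors = FALSE)
  }
  benchmarks <- do.call(rbind, list(
    b("7440-38-2", "SOQ", 10, TRUE), b("7440-38-2", "MCLG", 0),
    b("7440-38-2", "WHO_GV", 10), b("7440-38-2", "STATE_MCL", 5, TRUE),
    b("7440-61-1", "SOQ", 30, TRUE), b("7440-61-1", "MCLG", 0),
    b("7440-61-1", "WHO_GV", 30),
    b("7439-92-1", "SOQ", 5, TRUE), b("7439-92-1", "MCLG", 0),
    b("14797-55-8", "SOQ", 10000, TRUE), b("14797-55-8", "MCLG", 10000),
    b("14797-55-8", "WHO_GV", 50000),
    b("16984-48-8", "SOQ", 2400, TRUE), b("16984-48-8", "MCLG", 4000),
    b("16984-48-8", "WHO_GV", 1500),
    b("14808-79-8", "SOQ", 250000, TRUE),
    b("7440-66-6", "SOQ", 5000, TRUE), b("7440-66-6", "HBSL", 2000),
    b("7440-39-3", "SOQ", 2000, TRUE), b("7440-39-3", "MCLG", 2000),
    b("7440-24-6", "HBSL", 4000),
    b("67-66-3", "MCLG", 70), b("67-66-3", "WHO_GV", 300),
    b("75-27-4", "MCLG", 0), b("75-27-4", "WHO_GV", 60),
    b("75-25-2", "MCLG", 0), b("75-25-2", "WHO_GV", 100),
    b("124-48-1", "MCLG", 60), b("124-48-1", "WHO_GV", 100),
    b("75-09-2", "MCLG", 0), b("75-09-2", "WHO_GV", 20),
    b("127-18-4", "MCLG", 0), b("127-18-4", "WHO_GV", 40),
    b("71-43-2", "MCLG", 0), b("71-43-2", "WHO_GV", 10),
    b("79-01-6", "MCLG", 0), b("79-01-6", "WHO_pGV", 8),
    b("108-88-3", "MCLG", 1000), b("108-88-3", "WHO_GV", 700),
    b("1912-24-9", "SOQ", 3, TRUE), b("1912-24-9", "MCLG", 3),
    b("1912-24-9", "WHO_GV", 100),
    b("122-34-9", "SOQ", 4, TRUE), b("122-34-9", "MCLG", 4),
    b("51218-45-2", "HBSL", 300)
  ))

  a <- function(cas, ep, value, units, family,
                nonspecific = FALSE, baseline = FALSE, unreliable = FALSE) {
    data.frame(cas = cas, assay_endpoint_id = ep, acc_value = value,
               acc_units = units, flag_nonspecific = nonspecific,
               flag_baseline = baseline, flag_unreliable = unreliable,
               endpoint_family = family, stringsAsFactors = FALSE)
  }
  acc <- do.call(rbind, list(
    a("67-66-3", "SYN_DNA_1", 1000, "ug/L", "DNA binding"),
    a("67-66-3", "SYN_CYP_2", 5000, "ug/L", "CYP"),
    a("67-66-3", "SYN_BG_3", 200, "ug/L", "background", baseline = TRUE),
    a("75-27-4", "SYN_DNA_1", 800, "ug/L", "DNA binding"),
    a("75-27-4", "SYN_NR_4", 12, "uM", "nuclear receptor"),
    a("75-25-2", "SYN_DNA_1", 1200, "ug/L", "DNA binding"),
    a("124-48-1", "SYN_DNA_1", 900, "ug/L", "DNA binding"),
    a("127-18-4", "SYN_CYP_2", 2000, "ug/L", "CYP"),
    a("127-18-4", "SYN_STRESS_5", 3000, "ug/L", "cell stress"),
    a("71-43-2", "SYN_DNA_1", 1500, "ug/L", "DNA binding"),
    a("71-43-2", "SYN_STRESS_5", 30, "uM", "cell stress"),
    a("108-88-3", "SYN_STRESS_5", 4000, "ug/L", "cell stress"),
    a("71-36-3", "SYN_DNA_1", 2.0, "ug/L", "DNA binding"),
    a("71-36-3", "SYN_STRESS_5", 8.0, "ug/L", "cell stress"),
    a("71-36-3", "SYN_BAD_6", 1.0, "ug/L", "cell stress", unreliable = TRUE),
    a("1912-24-9", "SYN_NR_4", 50, "ug/L", "nuclear receptor"),
    a("1912-24-9", "SYN_DNA_1", 300, "ug/L", "DNA binding"),
    a("51218-45-2", "SYN_NR_4", 80, "ug/L", "nuclear receptor")
  ))

  policy <- censor_policy(
    doubled_rule = c("75-37-6", "141-78-6", "110-62-3", "75-45-6"),
    removal = "75-45-6")

  annotations <- data.frame(
    cas = "16984-48-8", label = "fluoride dental-health reference",
    value_ugL = 700, stringsAsFactors = FALSE)

  list(benchmarks = benchmarks, acc = acc, censor_policy = policy,
       annotations = annotations)
}

#' Write the synthetic study and fixture tables to CSV/YAML
#'
#' @param study A [bw_study()].
#' @param dir Output directory.
#' @param fixtures Fixture list from [default_fixtures()] (or `NULL` to
#'   skip fixture files).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(study, dir, fixtures = default_fixtures()) {
  paths <- write_study(study, dir)
  if (!is.null(fixtures)) {
    bp <- file.path(dir, "benchmarks.csv")
    ap <- file.path(dir, "acc.csv")
    cp <- file.path(dir, "censor_policy.yaml")
    utils::write.csv(fixtures$benchmarks, bp, row.names = FALSE)
    utils::write.csv(fixtures$acc, ap, row.names = FALSE)
    yaml::write_yaml(list(doubled_rule = as.list(fixtures$censor_policy$doubled_rule),
                          removal = as.list(fixtures$censor_policy$removal)),
                     cp)
    paths <- c(paths, benchmarks = bp, acc = ap, censor_policy = cp)
  }
  invisible(paths)
}
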