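#' Regulatory and health-based exceedance report
#'
#' Three-tier per-sample exceedance report for a censored study:
#' * tier 1 — enforceable exceedances: detected concentration strictly
#'   greater than the lowest enforceable SOQ/MCL ("shall not contain in
#'   excess of", hence strict comparison; state MCLs stay in the
#'   health-benchmark resolution, not here);
#' * tier 2 — de facto exceedances: any detection of an analyte whose
#'   MCLG is zero (no known safe level of exposure), regardless of
#'   concentration;
#' * tier 3 — near-benchmark detections: concentration above a
#'   configurable fraction of the lowest enforceable standard (default
#'   0.5) without exceeding it.
#'
#' @param study A censored [bw_study()].
#' @param benchmarks Benchmark table including enforceable entries.
#' @param near_fraction Tier-3 fraction of the enforceable value.
#' @return Data frame `sample_id`, `cas`, `name`, `tier`, `conc_ugL`,
#'   `threshold_ugL`.
#' @export
exceedance_report <- function(study, benchmarks, near_fraction = 0.5) {
  stopifnot(inherits(study, "bw_study"))
  benchmarks <- validate_benchmarks(benchmarks)
  det <- detections_ugL(study)
  if (!nrow(det)) {
    return(data.frame(sample_id = character(), cas = character(),
                      name = character(), tier = integer(),
                      conc_ugL = numeric(), threshold_ugL = numeric(),
                      stringsAsFactors = FALSE))
  }
  enf <- benchmarks[benchmarks$enforceable &
                      benchmarks$benchmark_type %in% c("SOQ", "MCL"),
                    , drop = FALSE]
  enf_min <- tapply(enf$value_ugL, enf$cas, min)
  mclg_zero <- unique(benchmarks$cas[benchmarks$benchmark_type == "MCLG" &
                                       benchmarks$value_ugL == 0])

  rows <- list()
  add <- function(sel, tier, thr) {
    if (!any(sel)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = det$sample_id[sel], cas = det$cas[sel],
      name = det$name[sel], tier = tier, conc_ugL = det$conc_ugL[sel],
      threshold_ugL = thr[sel], stringsAsFactors = FALSE)
  }
  thr1 <- unname(enf_min[det$cas])
  add(!is.na(thr1) & det$conc_ugL > thr1, 1L, thr1)
  add(det$cas %in% mclg_zero, 2L, rep(0, nrow(det)))
  thr3 <- thr1 * near_fraction
  add(!is.na(thr1) & det$conc_ugL > thr3 & det$conc_ugL <= thr1, 3L, thr3)

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sample_id = character(), cas = character(), name = character(),
    tier = integer(), conc_ugL = numeric(), threshold_ugL = numeric(),
    stringsAsFactors = FALSE)
  out <- out[order(out$tier, out$sample_id, out$cas), ]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: a study (or a synthetic
#' configuration to generate one), fixture tables, policies and
#' thresholds.
#'
#' @param study A [bw_study()], or `NULL` to generate one from `synth`.
#' @param synth A [synthetic_config()] used when `study` is `NULL`.
#' @param benchmarks Benchmark table.
#' @param acc ACC bioactivity table, or `NULL` to disable the EAR stage.
#' @param censor A [censor_policy()].
#' @param overrides MCLG-zero substitution overrides.
#' @param ear_policies Aggregation policies to report side by side.
#' @param near_fraction Tier-3 exceedance fraction.
#' @param stats_n_perm Permutations for the group PERMANOVA.
#' @param seed Seed for the analysis stages (permutation streams).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, synth = synthetic_config(),
                            benchmarks = default_fixtures()$benchmarks,
                            acc = default_fixtures()$acc,
                            censor = default_fixtures()$censor_policy,
                            overrides = default_overrides(),
                            ear_policies = EAR_POLICIES,
                            near_fraction = 0.5,
                            stats_n_perm = 9999,
                            seed = 1L) {
  structure(list(study = study, synth = synth, benchmarks = benchmarks,
                 acc = acc, censor = censor, overrides = overrides,
                 ear_policies = ear_policies,
                 near_fraction = near_fraction,
                 stats_n_perm = stats_n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Orchestrates the end-to-end analysis in QA-to-results order: blank
#' censoring, detection summaries (overall and by source type),
#' benchmark resolution and cumulative-TQ screening, ACC matching and
#' cumulative-EAR screening under the configured aggregation policies,
#' the three-tier exceedance report, and a group PERMANOVA of the
#' detected-concentration matrix by source type. Deterministic given the
#' configuration and seed; a run manifest records versions, the seed and
#' stage inventory.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `mixrisk_bundle` with elements `study`,
#'   `censoring_report`, `detection`, `detection_by_source`, `tq`, `ear`
#'   (named list per policy, `NULL` when disabled), `acc_coverage`,
#'   `exceedances`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  study <- stage("input", {
    if (!is.null(config$study)) config$study
    else generate_study(config$synth)
  })
  cens <- stage("qa_blanks", apply_censoring(study, config$censor))
  study <- cens$study

  detection <- stage("detection_summary", detection_summary(study))
  detection_by_source <- stage("detection_by_source",
                               detection_summary(study, "source_type"))

  resolved <- stage("benchmarks",
                    resolve_benchmarks(study$analytes, config$benchmarks,
                                       config$overrides))
  tq <- stage("tq", sum_tq(study, resolved))

  ear <- NULL
  acc_coverage <- NULL
  if (!is.null(config$acc) && nrow(config$acc) > 0) {
    matched <- stage("acc_match",
                     match_acc(detected_organics(study), config$acc))
    acc_coverage <- matched$coverage
    ear_long <- stage("ear", compute_ear(study, matched))
    ear <- lapply(config$ear_policies, function(pol) {
      aggregate_ear(ear_long, pol, sample_ids = study$samples$sample_id)
    })
    names(ear) <- config$ear_policies
  }

  exceed <- stage("exceedances",
                  exceedance_report(study, config$benchmarks,
                                    config$near_fraction))

  stats_res <- stage("stats", {
    det <- detections_ugL(study)
    det_cas <- sort(unique(det$cas))
    if (length(det_cas) >= 1 &&
        length(unique(study$samples$source_type)) >= 2) {
      m <- matrix(0, nrow(study$samples), length(det_cas),
                  dimnames = list(study$samples$sample_id, det_cas))
      idx <- cbind(match(det$sample_id, study$samples$sample_id),
                   match(det$cas, det_cas))
      m[idx] <- log10(1 + det$conc_ugL)
      permanova(m, study$samples$source_type,
                n_perm = config$stats_n_perm, seed = config$seed)
    } else NULL
  })

  manifest <- list(
    package = "mixriskscreen",
    package_version = as.character(utils::packageVersion("mixriskscreen")),
    seed = config$seed,
    stats_n_perm = config$stats_n_perm,
    ear_enabled = !is.null(ear),
    ear_policies = if (is.null(ear)) character() else names(ear),
    n_samples = nrow(study$samples),
    n_analytes = nrow(study$analytes))

  structure(list(study = study, censoring_report = cens$report,
                 detection = detection,
                 detection_by_source = detection_by_source,
                 resolved_benchmarks = resolved,
                 tq = tq, ear = ear, acc_coverage = acc_coverage,
                 exceedances = exceed, stats = stats_res,
                 manifest = manifest),
            class = "mixrisk_bundle")
}

#' @export
print.mixrisk_bundle <- function(x, ...) {
  cat("<mixrisk_bundle> cumulative mixture-risk screening results\n")
  cat(sprintf("  samples: %d | analytes: %d | censored records: %d\n",
              x$manifest$n_samples, x$manifest$n_analytes,
              sum(x$censoring_report$action == "censored")))
  print(x$tq)
  if (!is.null(x$ear)) {
    for (e in x$ear) print(e)
    cat(sprintf("  ACC coverage: %d/%d (%s%%)\n", x$acc_coverage$n_matched,
                x$acc_coverage$n_total, x$acc_coverage$pct))
  }
  cat(sprintf("  exceedances: tier1=%d tier2=%d tier3=%d\n",
              sum(x$exceedances$tier == 1), sum(x$exceedances$tier == 2),
              sum(x$exceedances$tier == 3)))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Write a pipeline bundle to tidy CSV outputs
#'
#' Writes every stage output as a tidy CSV plus a JSON run manifest with
#' MD5 hashes of the written files. Byte-identical across runs with the
#' same configuration and seed.
#'
#' @param bundle A `mixrisk_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mixrisk_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
    name
  }
  files <- c(
    wr(bundle$censoring_report, "censoring_report.csv"),
    wr(bundle$detection$by_analyte, "detection_by_analyte.csv"),
    wr(bundle$detection$panel, "detection_panel.csv"),
    wr(bundle$detection_by_source$by_analyte, "detection_by_source.csv"),
    wr(bundle$resolved_benchmarks, "resolved_benchmarks.csv"),
    wr(bundle$tq$totals, "tq_totals.csv"),
    wr(bundle$tq$contributions, "tq_contributions.csv"),
    wr(bundle$exceedances, "exceedances.csv"))
  if (!is.null(bundle$ear)) {
    for (pol in names(bundle$ear)) {
      files <- c(files, wr(bundle$ear[[pol]]$totals,
                           paste0("ear_totals_", pol, ".csv")))
    }
  }
  if (!is.null(bundle$stats)) {
    files <- c(files, wr(data.frame(
      f_statistic = bundle$stats$f_statistic,
      p_value = bundle$stats$p_value,
      n_permutations = bundle$stats$n_permutations), "permanova.csv"))
  }
  manifest <- bundle$manifest
  manifest$files <- as.list(tools::md5sum(file.path(dir, files)))
  names(manifest$files) <- files
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest_path)
}
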