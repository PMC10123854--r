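#' Health-benchmark types
#'
#' Benchmark entries carry a type and an enforceability flag. Standards of
#' quality (SOQ), maximum contaminant levels (MCL) and state MCLs are
#' enforceable "shall not exceed" values used for regulatory exceedance
#' reporting; the health-only set (MCLG, WHO guideline and provisional
#' guideline values, USGS health-based screening levels, state MCLs and
#' drinking-water health advisories) feeds the precautionary toxicity
#' quotient screen.
#' @keywords internal
BENCHMARK_TYPES <- c("SOQ", "MCL", "MCLG", "WHO_GV", "WHO_pGV", "HBSL",
                     "STATE_MCL", "DWHA")

# Candidate types for TQ resolution and the deterministic tie-break
# precedence among equal minima.
HEALTH_TYPES <- c("MCLG", "WHO_GV", "WHO_pGV", "HBSL", "STATE_MCL", "DWHA")

validate_benchmarks <- function(entries) {
  req(entries, c("cas", "benchmark_type", "value_ugL"), "benchmark table")
  bad <- setdiff(unique(entries$benchmark_type), BENCHMARK_TYPES)
  if (length(bad)) stop("unknown benchmark_type: ", paste(bad, collapse = ", "))
  if (any(entries$value_ugL < 0)) stop("benchmark values must be >= 0")
  zero_bad <- entries$value_ugL == 0 & entries$benchmark_type != "MCLG"
  if (any(zero_bad)) {
    stop("a zero benchmark value is only permitted for MCLG (cas: ",
         paste(entries$cas[zero_bad], collapse = ", "), ")")
  }
  if (is.null(entries$enforceable)) {
    entries$enforceable <- entries$benchmark_type %in% c("SOQ", "MCL", "STATE_MCL")
  }
  entries
}

#' Resolve the precautionary health benchmark for one analyte
#'
#' Implements the precautionary screening rule: among the health-based
#' candidate types (MCLG, WHO GV/pGV, HBSL, state MCL, DWHA), MCLG values
#' of zero — no identified safe exposure level — are first replaced by the
#' analyte's method reporting limit (converted to ug/L), or by an explicit
#' override value when one is configured for the CAS (lead defaults to
#' 1 ug/L, following the American Academy of Pediatrics recommendation);
#' the minimum of the post-substitution candidates is then returned. Ties
#' are broken by the fixed type precedence MCLG > WHO_GV > WHO_pGV > HBSL >
#' STATE_MCL > DWHA so provenance is deterministic. Enforceable SOQ/MCL
#' entries never enter the resolution; they are used only in exceedance
#' reporting.
#'
#' @param cas CAS number of the analyte.
#' @param entries Benchmark table (columns `cas`, `benchmark_type`,
#'   `value_ugL`, optional `enforceable`).
#' @param analyte One-row data frame (or list) with at least
#'   `reporting_limit` and `units` for the analyte, used for the MCLG-zero
#'   substitution.
#' @param overrides Named numeric vector mapping CAS to a fixed
#'   substitution value in ug/L; see [default_overrides()].
#' @return A one-row data frame `cas`, `value_ugL` (always > 0),
#'   `source_type` (winning benchmark type), `substituted`,
#'   `substitution_origin`; or `NULL` when the analyte has no health
#'   benchmark.
#' @export
resolve_benchmark <- function(cas, entries, analyte = NULL,
                              overrides = default_overrides()) {
  entries <- validate_benchmarks(entries)
  cand <- entries[entries$cas == cas & entries$benchmark_type %in% HEALTH_TYPES,
                  , drop = FALSE]
  if (!nrow(cand)) return(NULL)

  substituted <- FALSE
  substitution_origin <- NA_character_
  zero <- cand$benchmark_type == "MCLG" & cand$value_ugL == 0
  if (any(zero)) {
    substituted <- TRUE
    if (!is.null(overrides) && cas %in% names(overrides)) {
      cand$value_ugL[zero] <- unname(overrides[[cas]])
      substitution_origin <- "fixed_value"
    } else {
      if (is.null(analyte) || is.null(analyte$reporting_limit) ||
          is.na(analyte$reporting_limit)) {
        stop("MCLG of zero for ", cas,
             " requires a reporting_limit for substitution (configuration error)")
      }
      cand$value_ugL[zero] <- conc_to_ugL(analyte$reporting_limit,
                                          analyte$units)
      substitution_origin <- "reporting_limit"
    }
  }

  ord <- order(cand$value_ugL, match(cand$benchmark_type, HEALTH_TYPES))
  win <- cand[ord[1], ]
  if (win$value_ugL <= 0) {
    stop("internal error: resolved benchmark for ", cas, " is not positive")
  }
  data.frame(cas = cas, value_ugL = win$value_ugL,
             source_type = win$benchmark_type,
             substituted = substituted,
             substitution_origin = substitution_origin,
             stringsAsFactors = FALSE)
}

#' Default MCLG-zero substitution overrides
#'
#' Ships the lead override: an MCLG of zero for Pb (CAS 7439-92-1) is
#' substituted by 1 ug/L rather than the method reporting limit.
#' @return Named numeric vector (CAS -> ug/L).
#' @export
default_overrides <- function() c("7439-92-1" = 1.0)

#' Resolve benchmarks for a whole analyte panel
#'
#' @param analytes Analyte panel data frame (as in a [bw_study()]).
#' @param entries Benchmark table.
#' @param overrides See [resolve_benchmark()].
#' @return Data frame with one row per analyte that has a health benchmark.
#' @export
resolve_benchmarks <- function(analytes, entries,
                               overrides = default_overrides()) {
  rows <- lapply(seq_len(nrow(analytes)), function(i) {
    resolve_benchmark(analytes$cas[i], entries, analytes[i, ], overrides)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cas = character(), value_ugL = numeric(),
                      source_type = character(), substituted = logical(),
                      substitution_origin = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Toxicity quotient
#'
#' Ratio of a detected concentration to the resolved health benchmark,
#' both in ug/L.
#'
#' @param conc_ugL Detected concentration(s) in ug/L.
#' @param benchmark_ugL Resolved benchmark value(s) in ug/L (> 0).
#' @return Dimensionless TQ.
#' @export
compute_tq <- function(conc_ugL, benchmark_ugL) {
  if (any(benchmark_ugL <= 0)) stop("benchmark values must be > 0")
  conc_ugL / benchmark_ugL
}

#' Cumulative toxicity quotient (hazard index) per sample
#'
#' Sums toxicity quotients of individual detections under the
#' non-interactive concentration-addition model to give the sample-specific
#' hazard index (cumulative TQ), with a per-contaminant contribution table
#' sorted descending, flags at the screening thresholds (cumulative TQ >
#' 0.1 and > 1), and a flag for any single contaminant alone exceeding
#' TQ = 1. Detected analytes without a health benchmark are reported as
#' uncovered rather than entering the sum.
#'
#' @param study A censored [bw_study()].
#' @param resolved Resolved benchmark table from [resolve_benchmarks()].
#' @param include_semiquant Include semiquantitative detections (default
#'   `TRUE`; both result classes are treated as detections).
#' @return An object of class `tq_screen`: list with `totals` (per sample),
#'   `contributions` (per sample x contaminant, descending TQ), and
#'   `uncovered` (detected CAS with no benchmark).
#' @export
sum_tq <- function(study, resolved, include_semiquant = TRUE) {
  stopifnot(inherits(study, "bw_study"))
  det <- detections_ugL(study, include_semiquant)
  idx <- match(det$cas, resolved$cas)
  covered <- !is.na(idx)
  uncovered <- sort(unique(det$cas[!covered]))

  contrib <- det[covered, , drop = FALSE]
  if (nrow(contrib)) {
    contrib$benchmark_ugL <- resolved$value_ugL[idx[covered]]
    contrib$benchmark_type <- resolved$source_type[idx[covered]]
    contrib$tq <- compute_tq(contrib$conc_ugL, contrib$benchmark_ugL)
    contrib <- contrib[order(contrib$sample_id, -contrib$tq), ,
                       drop = FALSE]
    rownames(contrib) <- NULL
  } else {
    contrib$benchmark_ugL <- numeric(0)
    contrib$benchmark_type <- character(0)
    contrib$tq <- numeric(0)
  }

  totals <- do.call(rbind, lapply(study$samples$sample_id, function(sid) {
    tq <- contrib$tq[contrib$sample_id == sid]
    data.frame(sample_id = sid,
               sigma_tq = sum(tq),
               n_contaminants = length(tq),
               exceeds_0p1 = sum(tq) > 0.1,
               exceeds_1 = sum(tq) > 1,
               any_single_tq_gt_1 = any(tq > 1),
               stringsAsFactors = FALSE)
  }))
  if (is.null(totals)) {
    totals <- data.frame(sample_id = character(), sigma_tq = numeric(),
                         n_contaminants = integer(), exceeds_0p1 = logical(),
                         exceeds_1 = logical(), any_single_tq_gt_1 = logical())
  }
  structure(list(totals = totals, contributions = contrib,
                 uncovered = uncovered),
            class = "tq_screen")
}

#' @export
print.tq_screen <- function(x, ...) {
  cat("<tq_screen> cumulative toxicity quotients (concentration addition)\n")
  cat(sprintf("  samples: %d | sigma_TQ > 0.1: %d | sigma_TQ > 1: %d | single TQ > 1: %d\n",
              nrow(x$totals), sum(x$totals$exceeds_0p1), sum(x$totals$exceeds_1),
              sum(x$totals$any_single_tq_gt_1)))
  if (length(x$uncovered)) {
    cat("  uncovered (detected, no health benchmark):",
        paste(x$uncovered, collapse = ", "), "\n")
  }
  invisible(x)
}
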