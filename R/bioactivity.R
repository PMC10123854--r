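#' Match an analyte panel against an ACC bioactivity table
#'
#' Matches analytes to activity-concentration-at-cutoff (ACC) records by
#' exact CAS number. Records carrying any exclusion flag (non-specific
#' endpoint, baseline, unreliable response curve) are dropped before
#' exposure-activity ratios are computed; chemicals whose every endpoint is
#' flagged are reported separately as matched-but-unusable. The coverage
#' report gives matched / total analytes with the half-up-rounded percent.
#'
#' @param analytes Analyte panel data frame (typically restricted to the
#'   detected organics; see [detected_organics()]).
#' @param acc ACC table with columns `cas`, `assay_endpoint_id`,
#'   `acc_value`, `acc_units` (`"ug/L"` or `"uM"`), optional logical
#'   columns `flag_nonspecific`, `flag_baseline`, `flag_unreliable`, and
#'   optional `endpoint_family`.
#' @return A list of class `acc_match`: `usable` (unflagged ACC records
#'   with `acc_ugL` added), `coverage` (one-row data frame `n_matched`,
#'   `n_total`, `pct`), and `matched_no_usable` (CAS matched only by
#'   flagged records).
#' @export
match_acc <- function(analytes, acc) {
  req(acc, c("cas", "assay_endpoint_id", "acc_value", "acc_units"),
      "ACC table")
  if (any(acc$acc_value <= 0)) stop("ACC values must be positive")
  for (f in c("flag_nonspecific", "flag_baseline", "flag_unreliable")) {
    if (is.null(acc[[f]])) acc[[f]] <- FALSE
  }
  if (is.null(acc$endpoint_family)) acc$endpoint_family <- NA_character_

  matched <- acc[acc$cas %in% analytes$cas, , drop = FALSE]
  flagged <- matched$flag_nonspecific | matched$flag_baseline |
    matched$flag_unreliable
  usable <- matched[!flagged, , drop = FALSE]
  if (nrow(usable)) {
    mw <- analytes$molecular_weight[match(usable$cas, analytes$cas)]
    usable$acc_ugL <- acc_to_ugL(usable$acc_value, usable$acc_units, mw,
                                 usable$cas)
  } else {
    usable$acc_ugL <- numeric(0)
  }
  matched_cas <- unique(matched$cas)
  coverage <- data.frame(n_matched = length(matched_cas),
                         n_total = nrow(analytes),
                         pct = detection_percent(length(matched_cas),
                                                 nrow(analytes)))
  structure(list(usable = usable, coverage = coverage,
                 matched_no_usable = setdiff(matched_cas,
                                             unique(usable$cas))),
            class = "acc_match")
}

#' @export
print.acc_match <- function(x, ...) {
  cat(sprintf("<acc_match> coverage %d/%d (%s%%); %d usable endpoint records\n",
              x$coverage$n_matched, x$coverage$n_total, x$coverage$pct,
              nrow(x$usable)))
  if (length(x$matched_no_usable)) {
    cat("  matched but all endpoints flagged:",
        paste(x$matched_no_usable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detected organic analytes of a study
#'
#' Convenience accessor: the analyte-panel rows for organic-indicator
#' analytes (every class except inorganic) with at least one non-censored
#' detection.
#'
#' @param study A [bw_study()].
#' @return Subset of `study$analytes`.
#' @export
detected_organics <- function(study) {
  det_cas <- unique(study$records$cas[is_detection(study$records$status)])
  sel <- study$analytes$cas %in% det_cas &
    analyte_group(study$analytes$analyte_class) == "organic"
  study$analytes[sel, , drop = FALSE]
}

#' Harmonize ACC values to micrograms per litre
#'
#' ACC values in ug/L pass through; molar values (uM) are converted as
#' `acc_uM * MW` (g/mol), which is numerically ug/L.
#'
#' @param acc_value Positive ACC values.
#' @param acc_units `"ug/L"` or `"uM"` per record.
#' @param molecular_weight g/mol, required where units are uM.
#' @param cas Optional CAS labels for error messages.
#' @return Numeric vector in ug/L.
#' @export
acc_to_ugL <- function(acc_value, acc_units, molecular_weight = NA_real_,
                       cas = NULL) {
  n <- length(acc_value)
  acc_units <- rep_len(acc_units, n)
  molecular_weight <- rep_len(molecular_weight, n)
  if (any(acc_value <= 0)) stop("ACC values must be positive")
  u <- gsub("µ|μ", "u", tolower(acc_units))
  molar <- u %in% c("um", "umol/l")
  mass <- u %in% c("ug/l", "ugl")
  if (any(!molar & !mass)) {
    stop("unknown ACC units: ", paste(unique(acc_units[!molar & !mass]),
                                      collapse = ", "))
  }
  need_mw <- molar & (is.na(molecular_weight) | molecular_weight <= 0)
  if (any(need_mw)) {
    lab <- if (is.null(cas)) "some records" else
      paste(unique(rep_len(cas, n)[need_mw]), collapse = ", ")
    stop("molecular_weight required for uM ACC records: ", lab)
  }
  ifelse(molar, acc_value * molecular_weight, acc_value)
}

#' Exposure-activity ratios for all detections
#'
#' One EAR per (detection x usable assay endpoint): the detected
#' concentration divided by the endpoint's activity concentration at
#' cutoff, both in ug/L. Chemicals with no usable endpoint yield no rows.
#'
#' @param study A censored [bw_study()].
#' @param acc_match An [match_acc()] result (or an ACC table, which is
#'   matched against the study's detected organics first).
#' @param include_semiquant Include semiquantitative detections (default
#'   `TRUE`).
#' @return Data frame `sample_id`, `cas`, `assay_endpoint_id`,
#'   `endpoint_family`, `conc_ugL`, `acc_ugL`, `ear`.
#' @export
compute_ear <- function(study, acc_match, include_semiquant = TRUE) {
  stopifnot(inherits(study, "bw_study"))
  if (!inherits(acc_match, "acc_match")) {
    acc_match <- match_acc(detected_organics(study), acc_match)
  }
  det <- detections_ugL(study, include_semiquant)
  acc <- acc_match$usable
  det <- det[det$cas %in% acc$cas, , drop = FALSE]
  if (!nrow(det) || !nrow(acc)) {
    return(data.frame(sample_id = character(), cas = character(),
                      assay_endpoint_id = character(),
                      endpoint_family = character(),
                      conc_ugL = numeric(), acc_ugL = numeric(),
                      ear = numeric(), stringsAsFactors = FALSE))
  }
  out <- merge(det[, c("sample_id", "cas", "conc_ugL")],
               acc[, c("cas", "assay_endpoint_id", "endpoint_family",
                       "acc_ugL")],
               by = "cas")
  out$ear <- out$conc_ugL / out$acc_ugL
  out <- out[order(out$sample_id, out$cas, out$assay_endpoint_id),
             c("sample_id", "cas", "assay_endpoint_id", "endpoint_family",
               "conc_ugL", "acc_ugL", "ear")]
  rownames(out) <- NULL
  out
}

EAR_POLICIES <- c("sum_of_chem_max", "per_endpoint_sum_max", "grand_sum")

#' Aggregate exposure-activity ratios per sample
#'
#' Cumulative EAR under concentration addition, with three aggregation
#' policies over the chemical x endpoint grid:
#' * `sum_of_chem_max` (default): per chemical take the maximum EAR over
#'   endpoints, then sum over chemicals — precautionary per-chemical
#'   reading that avoids double-counting a chemical across correlated
#'   endpoints;
#' * `per_endpoint_sum_max`: per endpoint sum over chemicals, report the
#'   maximum endpoint and its family (identifies which endpoint family,
#'   e.g. DNA binding, drives the mixture signal);
#' * `grand_sum`: sum over every (chemical, endpoint) pair — an upper
#'   bound on both other policies.
#'
#' @param ear_results Output of [compute_ear()].
#' @param policy One of `"sum_of_chem_max"`, `"per_endpoint_sum_max"`,
#'   `"grand_sum"`.
#' @param sample_ids Optional full vector of sample ids so samples with no
#'   matched chemicals report a cumulative EAR of 0.
#' @return Object of class `ear_screen`: `totals` (per sample:
#'   `sigma_ear`, flags at > 0.001 and > 1, and for the endpoint policy
#'   the driving endpoint and family) and `attribution` (per-sample
#'   contributor table, descending).
#' @export
aggregate_ear <- function(ear_results, policy = "sum_of_chem_max",
                          sample_ids = NULL) {
  if (!policy %in% EAR_POLICIES) {
    stop("unknown aggregation policy: ", policy,
         " (expected one of ", paste(EAR_POLICIES, collapse = ", "), ")")
  }
  if (is.null(sample_ids)) sample_ids <- unique(ear_results$sample_id)

  totals <- list()
  attribution <- list()
  for (sid in sample_ids) {
    e <- ear_results[ear_results$sample_id == sid, , drop = FALSE]
    if (!nrow(e)) {
      sigma <- 0
      top_endpoint <- NA_character_
      top_family <- NA_character_
    } else if (policy == "sum_of_chem_max") {
      per_chem <- tapply(e$ear, e$cas, max)
      sigma <- sum(per_chem)
      attribution[[length(attribution) + 1]] <- data.frame(
        sample_id = sid, contributor = names(per_chem),
        ear = as.numeric(per_chem), stringsAsFactors = FALSE)
      top_endpoint <- NA_character_
      top_family <- NA_character_
    } else if (policy == "per_endpoint_sum_max") {
      per_end <- tapply(e$ear, e$assay_endpoint_id, sum)
      sigma <- max(per_end)
      top_endpoint <- names(per_end)[which.max(per_end)]
      top_family <- e$endpoint_family[match(top_endpoint,
                                            e$assay_endpoint_id)]
      attribution[[length(attribution) + 1]] <- data.frame(
        sample_id = sid, contributor = names(per_end),
        ear = as.numeric(per_end), stringsAsFactors = FALSE)
    } else { # grand_sum
      sigma <- sum(e$ear)
      per_chem <- tapply(e$ear, e$cas, sum)
      attribution[[length(attribution) + 1]] <- data.frame(
        sample_id = sid, contributor = names(per_chem),
        ear = as.numeric(per_chem), stringsAsFactors = FALSE)
      top_endpoint <- NA_character_
      top_family <- NA_character_
    }
    totals[[length(totals) + 1]] <- data.frame(
      sample_id = sid, policy = policy, sigma_ear = sigma,
      exceeds_0p001 = sigma > 0.001, exceeds_1 = sigma > 1,
      top_endpoint = top_endpoint, top_family = top_family,
      stringsAsFactors = FALSE)
  }
  totals <- if (length(totals)) do.call(rbind, totals) else data.frame(
    sample_id = character(), policy = character(), sigma_ear = numeric(),
    exceeds_0p001 = logical(), exceeds_1 = logical(),
    top_endpoint = character(), top_family = character())
  attribution <- if (length(attribution)) do.call(rbind, attribution) else
    data.frame(sample_id = character(), contributor = character(),
               ear = numeric())
  attribution <- attribution[order(attribution$sample_id, -attribution$ear), ]
  rownames(attribution) <- NULL
  structure(list(totals = totals, attribution = attribution,
                 policy = policy),
            class = "ear_screen")
}

#' @export
print.ear_screen <- function(x, ...) {
  cat(sprintf("<ear_screen> policy %s | samples: %d | sigma_EAR > 0.001: %d | > 1: %d\n",
              x$policy, nrow(x$totals), sum(x$totals$exceeds_0p001),
              sum(x$totals$exceeds_1)))
  invisible(x)
}
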