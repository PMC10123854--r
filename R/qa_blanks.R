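#' Blank-based censoring policy
#'
#' Describes how sample detections are censored against field/laboratory
#' blank contamination: by default every analyte detected in a blank has its
#' sample detections at or below the analyte-specific maximum blank
#' concentration censored; analytes on the doubled rule are censored at
#' twice the maximum blank concentration (used when single blank detections
#' fall within the range observed in samples); removal analytes are dropped
#' from the interpretive dataset entirely.
#'
#' @param doubled_rule Character vector of CAS numbers censored at 2x the
#'   maximum blank concentration.
#' @param removal Character vector of CAS numbers removed from the panel.
#' @return An object of class `censor_policy`.
#' @export
censor_policy <- function(doubled_rule = character(), removal = character()) {
  structure(list(doubled_rule = unique(as.character(doubled_rule)),
                 removal = unique(as.character(removal))),
            class = "censor_policy")
}

#' Read a censoring policy from YAML
#'
#' Expects top-level keys `doubled_rule` and `removal`, each a list of CAS
#' numbers.
#'
#' @param path Path to the YAML file.
#' @return A [censor_policy()].
#' @export
read_censor_policy <- function(path) {
  y <- yaml::read_yaml(path)
  censor_policy(doubled_rule = unlist(y$doubled_rule),
                removal = unlist(y$removal))
}

#' Maximum detected blank concentration for an analyte
#'
#' @param study A [bw_study()] (the blanks slot is used).
#' @param cas CAS number.
#' @return The maximum blank concentration (native units) over blank
#'   records classified as detections, or `NA` if the analyte was never
#'   detected in a blank.
#' @export
max_blank_concentration <- function(study, cas) {
  stopifnot(inherits(study, "bw_study"))
  b <- study$blanks
  x <- b$concentration[b$cas == cas & is_detection(b$status)]
  if (!length(x)) NA_real_ else max(x)
}

#' Apply blank-based censoring to a study
#'
#' For every analyte with at least one blank detection, sample detections
#' with concentration at or below the censoring threshold (maximum blank
#' concentration, doubled for analytes on the doubled rule) are set to
#' status `"censored"`; censored records keep their concentration and gain
#' an audit note, and are excluded from all downstream detection counts and
#' risk sums. Analytes on the removal list are dropped from the panel.
#' The operation is idempotent and, with empty blanks, the identity.
#'
#' @param study A [bw_study()].
#' @param policy A [censor_policy()].
#' @return A list with elements `study` (the censored `bw_study`) and
#'   `report` (a data frame auditing every changed record: `sample_id`,
#'   `cas`, `action`, `concentration`, `threshold`, `max_blank`,
#'   `multiplier`).
#' @export
apply_censoring <- function(study, policy = censor_policy()) {
  stopifnot(inherits(study, "bw_study"), inherits(policy, "censor_policy"))
  unknown <- setdiff(c(policy$doubled_rule, policy$removal), study$analytes$cas)
  if (length(unknown)) {
    warning("censor policy references CAS not in the analyte panel: ",
            paste(unknown, collapse = ", "))
  }

  report <- list()
  rec <- study$records
  blank_cas <- unique(study$blanks$cas[is_detection(study$blanks$status)])
  for (cc in blank_cas) {
    mb <- max_blank_concentration(study, cc)
    mult <- if (cc %in% policy$doubled_rule) 2 else 1
    thr <- mb * mult
    hit <- which(rec$cas == cc & is_detection(rec$status) &
                   rec$concentration <= thr)
    if (length(hit)) {
      report[[length(report) + 1]] <- data.frame(
        sample_id = rec$sample_id[hit], cas = cc, action = "censored",
        concentration = rec$concentration[hit], threshold = thr,
        max_blank = mb, multiplier = mult, stringsAsFactors = FALSE)
      rec$status[hit] <- "censored"
      rec$censor_note[hit] <- sprintf(
        "blank-censored: concentration %g <= threshold %g (max blank %g x %d)",
        rec$concentration[hit], thr, mb, mult)
    }
  }

  analytes <- study$analytes
  blanks <- study$blanks
  drop <- intersect(policy$removal, analytes$cas)
  if (length(drop)) {
    gone <- rec$cas %in% drop
    if (any(gone)) {
      report[[length(report) + 1]] <- data.frame(
        sample_id = rec$sample_id[gone], cas = rec$cas[gone],
        action = "removed", concentration = rec$concentration[gone],
        threshold = NA_real_, max_blank = NA_real_, multiplier = NA_integer_,
        stringsAsFactors = FALSE)
    }
    rec <- rec[!gone, , drop = FALSE]
    blanks <- blanks[!blanks$cas %in% drop, , drop = FALSE]
    analytes <- analytes[!analytes$cas %in% drop, , drop = FALSE]
  }
  rownames(rec) <- NULL

  out <- study
  out$records <- rec
  out$analytes <- analytes
  out$blanks <- blanks
  report <- if (length(report)) do.call(rbind, report) else data.frame(
    sample_id = character(), cas = character(), action = character(),
    concentration = numeric(), threshold = numeric(), max_blank = numeric(),
    multiplier = integer(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(study = out, report = report)
}
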