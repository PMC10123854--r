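#' Detection-frequency summary
#'
#' Tabulates, after any censoring, (i) per-analyte detection frequencies
#' (count of samples with a detection and half-up-rounded percent), (ii)
#' panel-level detection shares (how many inorganic / organic analytes were
#' detected at least once), and (iii) per-sample detected-analyte counts
#' with median, interquartile range and range. Optionally stratified by a
#' sample metadata key.
#'
#' @param study A [bw_study()], typically after [apply_censoring()].
#' @param group_by Optional metadata column to stratify by
#'   (`"source_type"` or `"origin"`).
#' @return A list of class `detection_summary` with elements `by_analyte`,
#'   `panel`, `per_sample`, and `sample_stats`.
#' @export
detection_summary <- function(study, group_by = NULL) {
  stopifnot(inherits(study, "bw_study"))
  if (!is.null(group_by) &&
      !group_by %in% c("source_type", "origin")) {
    stop("group_by must be 'source_type' or 'origin'")
  }
  samples <- study$samples
  groups <- if (is.null(group_by)) {
    list(all = samples$sample_id)
  } else {
    split(samples$sample_id, samples[[group_by]])
  }

  rec <- study$records[is_detection(study$records$status), , drop = FALSE]

  by_analyte <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    n <- length(ids)
    sub <- rec[rec$sample_id %in% ids, , drop = FALSE]
    k <- vapply(study$analytes$cas,
                function(cc) length(unique(sub$sample_id[sub$cas == cc])),
                integer(1))
    data.frame(group = g, cas = study$analytes$cas,
               name = study$analytes$name,
               analyte_class = study$analytes$analyte_class,
               n_samples = n, n_detected = as.integer(k),
               pct_detected = detection_percent(k, n),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  panel <- do.call(rbind, lapply(names(groups), function(g) {
    ba <- by_analyte[by_analyte$group == g, ]
    grp <- analyte_group(ba$analyte_class)
    rows <- lapply(c("inorganic", "organic", "all"), function(ag) {
      sel <- if (ag == "all") rep(TRUE, nrow(ba)) else grp == ag
      n_an <- sum(sel)
      n_det <- sum(ba$n_detected[sel] > 0)
      data.frame(group = g, analyte_group = ag, n_analytes = n_an,
                 n_detected = n_det,
                 pct_detected = detection_percent(n_det, n_an),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))

  idx <- match(rec$cas, study$analytes$cas)
  rec_grp <- analyte_group(study$analytes$analyte_class[idx])
  per_sample <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    sel <- rec$sample_id == sid
    data.frame(sample_id = sid,
               n_detected = sum(sel),
               n_inorganic = sum(sel & rec_grp == "inorganic"),
               n_organic = sum(sel & rec_grp == "organic"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_sample)) {
    per_sample <- data.frame(sample_id = character(), n_detected = integer(),
                             n_inorganic = integer(), n_organic = integer())
  }

  sample_stats <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    ps <- per_sample[per_sample$sample_id %in% ids, , drop = FALSE]
    do.call(rbind, lapply(c("n_detected", "n_inorganic", "n_organic"),
      function(v) {
        x <- ps[[v]]
        if (!length(x)) x <- 0L
        q <- stats::quantile(x, c(0.25, 0.75), type = 7)
        data.frame(group = g, variable = v,
                   median = stats::median(x), q25 = q[[1]], q75 = q[[2]],
                   min = min(x), max = max(x), stringsAsFactors = FALSE)
      }))
  }))

  structure(list(by_analyte = by_analyte, panel = panel,
                 per_sample = per_sample, sample_stats = sample_stats,
                 group_by = group_by),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("<detection_summary>")
  if (!is.null(x$group_by)) cat(" stratified by", x$group_by)
  cat("\nPanel-level detection shares:\n")
  print(x$panel, row.names = FALSE)
  cat("\nPer-sample detected-analyte counts:\n")
  print(x$sample_stats, row.names = FALSE)
  invisible(x)
}

#' Co-occurrence of two analytes
#'
#' Counts the samples (optionally within a source-type or origin subgroup)
#' in which both analytes are detections, and reports the half-up-rounded
#' percent of the subgroup size.
#'
#' @param study A [bw_study()] (censoring already applied).
#' @param cas1,cas2 CAS numbers of the two analytes.
#' @param subgroup Optional subgroup value: one of the study's
#'   `source_type` or `origin` values (e.g. `"spring"`).
#' @return A one-row data frame with `n_both`, `n_samples`, `pct`.
#' @examples
#' study <- generate_study(synthetic_config(seed = 1))
#' cooccurrence(study, "7440-38-2", "7440-61-1", subgroup = "spring")
#' @export
cooccurrence <- function(study, cas1, cas2, subgroup = NULL) {
  stopifnot(inherits(study, "bw_study"))
  for (cc in c(cas1, cas2)) {
    if (!cc %in% study$analytes$cas) stop("unknown analyte cas: ", cc)
  }
  ids <- study$samples$sample_id
  if (!is.null(subgroup)) {
    sel <- study$samples$source_type == subgroup |
      study$samples$origin == subgroup
    if (!any(sel)) stop("no samples in subgroup: ", subgroup)
    ids <- ids[sel]
  }
  rec <- study$records[is_detection(study$records$status), , drop = FALSE]
  has1 <- unique(rec$sample_id[rec$cas == cas1])
  has2 <- unique(rec$sample_id[rec$cas == cas2])
  both <- intersect(intersect(has1, has2), ids)
  data.frame(cas1 = cas1, cas2 = cas2,
             subgroup = if (is.null(subgroup)) "all" else subgroup,
             n_both = length(both), n_samples = length(ids),
             pct = detection_percent(length(both), length(ids)),
             stringsAsFactors = FALSE)
}
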