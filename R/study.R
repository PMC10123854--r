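#' Assemble a bottled-water study table
#'
#' Bundles sample metadata, the analyte panel, sample results, and blank
#' results into a validated `bw_study` object, the container every QA and
#' screening step consumes.
#'
#' @param samples Data frame with columns `sample_id`, `source_type`
#'   (`"purified_TW"` or `"spring"`), `origin` (`"domestic"` or
#'   `"imported"`), and optionally `treatment` (semicolon-separated list)
#'   and `packaging`.
#' @param analytes Data frame with columns `cas`, `name`, `analyte_class`
#'   (one of `"inorganic"`, `"DBP"`, `"VOC"`, `"pesticide"`,
#'   `"pharmaceutical"`, `"PFAS"`, `"other_organic"`), `units` (`"ug/L"` or
#'   `"mg/L"`), `mdl`, `loq`, and optionally `reporting_limit` (defaults to
#'   `loq`) and `molecular_weight` (g/mol, required only when bioactivity
#'   tables use molar units).
#' @param records Data frame of sample results with columns `sample_id`,
#'   `cas`, `concentration` (`NA` = nondetect), and optionally `status` and
#'   `censor_note`; statuses are recomputed from the limits via
#'   [classify_detection()] (a `"censored"` status is preserved).
#' @param blanks Data frame with the same shape as `records` for field and
#'   laboratory blanks; blank ids live in `sample_id` and need not appear in
#'   `samples`.
#' @param validate_cas Check CAS numbers with [cas_is_valid()]?
#' @return An object of class `bw_study`: a list with elements `samples`,
#'   `analytes`, `records`, `blanks`.
#' @seealso [read_study()], [generate_study()], [apply_censoring()]
#' @export
bw_study <- function(samples, analytes, records,
                     blanks = empty_records(), validate_cas = TRUE) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  analytes <- as.data.frame(analytes, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  blanks <- as.data.frame(blanks, stringsAsFactors = FALSE)

  req(samples, c("sample_id", "source_type", "origin"), "samples")
  req(analytes, c("cas", "name", "analyte_class", "units", "mdl", "loq"),
      "analytes")
  req(records, c("sample_id", "cas", "concentration"), "records")

  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in samples: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(analytes$cas)) {
    stop("duplicate cas in analyte panel: ",
         paste(unique(analytes$cas[duplicated(analytes$cas)]),
               collapse = ", "))
  }
  bad_src <- setdiff(unique(samples$source_type), c("purified_TW", "spring"))
  if (length(bad_src)) stop("unknown source_type: ", paste(bad_src, collapse = ", "))
  bad_org <- setdiff(unique(samples$origin), c("domestic", "imported"))
  if (length(bad_org)) stop("unknown origin: ", paste(bad_org, collapse = ", "))
  classes <- c("inorganic", "DBP", "VOC", "pesticide", "pharmaceutical",
               "PFAS", "other_organic")
  bad_cls <- setdiff(unique(analytes$analyte_class), classes)
  if (length(bad_cls)) stop("unknown analyte_class: ", paste(bad_cls, collapse = ", "))

  analytes$units <- normalize_units(analytes$units)
  if (is.null(analytes$reporting_limit)) analytes$reporting_limit <- analytes$loq
  analytes$reporting_limit[is.na(analytes$reporting_limit)] <-
    analytes$loq[is.na(analytes$reporting_limit)]
  if (is.null(analytes$molecular_weight)) analytes$molecular_weight <- NA_real_
  if (any(analytes$mdl <= 0)) stop("mdl must be > 0 for every analyte")
  if (any(analytes$mdl > analytes$loq)) {
    stop("mdl > loq for: ",
         paste(analytes$cas[analytes$mdl > analytes$loq], collapse = ", "))
  }
  if (validate_cas) {
    bad <- analytes$cas[!cas_is_valid(analytes$cas)]
    if (length(bad)) stop("invalid CAS registry numbers: ", paste(bad, collapse = ", "))
  }

  records <- finalize_records(records, analytes, samples$sample_id,
                              require_sample = TRUE)
  blanks <- finalize_records(blanks, analytes, character(), require_sample = FALSE)

  structure(list(samples = samples, analytes = analytes,
                 records = records, blanks = blanks),
            class = "bw_study")
}

empty_records <- function() {
  data.frame(sample_id = character(), cas = character(),
             concentration = numeric(), status = character(),
             censor_note = character(), stringsAsFactors = FALSE)
}

req <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
}

# Recompute statuses from limits; preserve censored rows; flag conflicts.
finalize_records <- function(records, analytes, sample_ids, require_sample) {
  if (nrow(records) == 0) return(empty_records())
  if (is.null(records$status)) records$status <- NA_character_
  if (is.null(records$censor_note)) records$censor_note <- NA_character_

  unknown <- setdiff(unique(records$cas), analytes$cas)
  if (length(unknown)) {
    stop("records reference undeclared analyte cas: ",
         paste(unknown, collapse = ", "))
  }
  if (require_sample) {
    unknown_s <- setdiff(unique(records$sample_id), sample_ids)
    if (length(unknown_s)) {
      stop("records reference undeclared sample_id: ",
           paste(unknown_s, collapse = ", "))
    }
  }
  key <- paste(records$sample_id, records$cas, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), c("sample_id", "cas"), drop = FALSE]
    stop("duplicate (sample_id, cas) pair(s): ",
         paste(unique(paste0("(", d$sample_id, ", ", d$cas, ")")), collapse = ", "))
  }

  idx <- match(records$cas, analytes$cas)
  derived <- classify_detection(records$concentration,
                                analytes$mdl[idx], analytes$loq[idx])
  keep_censored <- !is.na(records$status) & records$status == "censored"
  conflict <- !is.na(records$status) & !keep_censored & records$status != derived
  records$status[!keep_censored] <- derived[!keep_censored]
  attr_rows <- which(conflict)
  records <- records[, c("sample_id", "cas", "concentration", "status",
                         "censor_note")]
  rownames(records) <- NULL
  if (length(attr_rows)) attr(records, "status_conflicts") <- attr_rows
  records
}

#' @export
print.bw_study <- function(x, ...) {
  cat("<bw_study>\n")
  cat(sprintf("  samples : %d (%s)\n", nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$source_type)),
                            table(x$samples$source_type)), collapse = ", ")))
  cat(sprintf("  analytes: %d (%s)\n", nrow(x$analytes),
              paste(sprintf("%s=%d", names(table(x$analytes$analyte_class)),
                            table(x$analytes$analyte_class)), collapse = ", ")))
  ndet <- sum(is_detection(x$records$status))
  cat(sprintf("  records : %d (%d detections, %d censored)\n",
              nrow(x$records), ndet, sum(x$records$status == "censored")))
  cat(sprintf("  blanks  : %d records\n", nrow(x$blanks)))
  invisible(x)
}

# Analyte groups used in panel-level reporting: everything that is not
# inorganic is an organic-indicator analyte.
analyte_group <- function(analyte_class) {
  ifelse(analyte_class == "inorganic", "inorganic", "organic")
}

#' Read a study from long-format CSV files
#'
#' Reads the documented three-file contract — `results.csv` (one row per
#' sample x analyte; empty concentration = nondetect), `samples.csv`
#' (metadata), `blanks.csv` (same schema as results with blank ids) — and
#' returns a validated [bw_study()]. Unit tags are normalized but
#' concentrations are never silently rescaled; detection statuses are
#' recomputed from the stored limits.
#'
#' @param results_file,samples_file Paths to the results and sample CSVs.
#' @param blanks_file Optional path to the blank-results CSV.
#' @param validate_cas Check CAS checksums?
#' @return A `bw_study`.
#' @export
read_study <- function(results_file, samples_file, blanks_file = NULL,
                       validate_cas = TRUE) {
  res <- read_results_csv(results_file)
  samples <- utils::read.csv(samples_file, stringsAsFactors = FALSE,
                             colClasses = "character")
  allowed_s <- c("sample_id", "source_type", "origin", "treatment", "packaging")
  extra <- setdiff(names(samples), allowed_s)
  if (length(extra)) {
    stop("samples file ", samples_file, " has unknown column(s): ",
         paste(extra, collapse = ", "))
  }
  blanks <- if (!is.null(blanks_file)) read_results_csv(blanks_file)
            else NULL
  study <- bw_study(samples = samples, analytes = res$analytes,
                    records = res$records,
                    blanks = if (is.null(blanks)) empty_records()
                             else blanks$records,
                    validate_cas = validate_cas)
  study
}

results_columns <- c("sample_id", "cas", "analyte_name", "analyte_class",
                     "concentration", "units", "mdl", "loq",
                     "reporting_limit", "molecular_weight")

read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  allowed <- c(results_columns, "status", "censor_note")
  extra <- setdiff(names(df), allowed)
  if (length(extra)) {
    stop("results file ", path, " has unknown column(s): ",
         paste(extra, collapse = ", "))
  }
  req(df, setdiff(results_columns, c("reporting_limit", "molecular_weight")),
      path)
  analytes <- unique(df[, intersect(names(df),
                                    c("cas", "analyte_name", "analyte_class",
                                      "units", "mdl", "loq",
                                      "reporting_limit", "molecular_weight"))])
  names(analytes)[names(analytes) == "analyte_name"] <- "name"
  if (anyDuplicated(analytes$cas)) {
    stop("inconsistent analyte metadata across rows in ", path, " for cas: ",
         paste(unique(analytes$cas[duplicated(analytes$cas)]), collapse = ", "))
  }
  keep <- intersect(names(df), c("sample_id", "cas", "concentration",
                                 "status", "censor_note"))
  list(analytes = analytes, records = df[, keep])
}

#' Write a study to long-format CSV files
#'
#' Inverse of [read_study()]: writes `results.csv`, `samples.csv` and
#' `blanks.csv` under `dir`. Statuses and censor notes are written so a
#' round trip reproduces every record (including censored ones) exactly.
#'
#' @param study A `bw_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "bw_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(dir, "results.csv"),
             samples = file.path(dir, "samples.csv"),
             blanks = file.path(dir, "blanks.csv"))
  utils::write.csv(join_results(study$records, study$analytes),
                   paths["results"], row.names = FALSE, na = "")
  utils::write.csv(study$samples, paths["samples"], row.names = FALSE, na = "")
  utils::write.csv(join_results(study$blanks, study$analytes),
                   paths["blanks"], row.names = FALSE, na = "")
  invisible(paths)
}

join_results <- function(records, analytes) {
  idx <- match(records$cas, analytes$cas)
  data.frame(sample_id = records$sample_id,
             cas = records$cas,
             analyte_name = analytes$name[idx],
             analyte_class = analytes$analyte_class[idx],
             concentration = records$concentration,
             units = analytes$units[idx],
             mdl = analytes$mdl[idx],
             loq = analytes$loq[idx],
             reporting_limit = analytes$reporting_limit[idx],
             molecular_weight = analytes$molecular_weight[idx],
             status = records$status,
             censor_note = records$censor_note,
             stringsAsFactors = FALSE)
}

# Detections joined with analyte metadata and sample metadata, with
# concentrations harmonized to ug/L; the working table for screening.
detections_ugL <- function(study, include_semiquant = TRUE) {
  rec <- study$records
  keep <- if (include_semiquant) is_detection(rec$status)
          else rec$status == "quantitative"
  rec <- rec[keep, , drop = FALSE]
  idx <- match(rec$cas, study$analytes$cas)
  sdx <- match(rec$sample_id, study$samples$sample_id)
  data.frame(sample_id = rec$sample_id,
             cas = rec$cas,
             name = study$analytes$name[idx],
             analyte_class = study$analytes$analyte_class[idx],
             status = rec$status,
             conc_ugL = conc_to_ugL(rec$concentration, study$analytes$units[idx]),
             source_type = study$samples$source_type[sdx],
             origin = study$samples$origin[sdx],
             stringsAsFactors = FALSE)
}
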