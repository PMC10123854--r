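#' Classify a measurement against its detection limits
#'
#' Assigns the detection status of a concentration result relative to the
#' long-term method detection limit (MDL) and limit of quantitation (LOQ):
#' results at or above the LOQ are `"quantitative"`, results at or above the
#' MDL but below the LOQ are `"semiquantitative"`, and missing results or
#' results below the MDL are `"nondetect"`. Both quantitative and
#' semiquantitative results count as detections in all downstream screening.
#'
#' A concentration exactly equal to the MDL classifies as semiquantitative
#' (closed lower bound); a concentration exactly equal to the LOQ is
#' quantitative.
#'
#' @param concentration Numeric vector of concentrations; `NA` means the
#'   analyte was not reported (nondetect).
#' @param mdl,loq Positive numeric scalars or vectors (recycled), with
#'   `mdl <= loq`, in the same units as `concentration`.
#' @return Character vector with values in
#'   `c("nondetect", "semiquantitative", "quantitative")`.
#' @examples
#' classify_detection(c(0.5, 0.15, NA), mdl = 0.1, loq = 0.2)
#' @export
classify_detection <- function(concentration, mdl, loq) {
  n <- max(length(concentration), length(mdl), length(loq))
  concentration <- rep_len(concentration, n)
  mdl <- rep_len(mdl, n)
  loq <- rep_len(loq, n)
  if (any(!is.finite(mdl)) || any(!is.finite(loq))) {
    stop("mdl and loq must be finite")
  }
  if (any(mdl <= 0)) stop("mdl must be > 0")
  if (any(mdl > loq)) stop("mdl must not exceed loq (configuration error)")
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("negative concentrations are not valid measurement results")
  }
  status <- rep("nondetect", n)
  det <- !is.na(concentration)
  status[det & concentration >= mdl] <- "semiquantitative"
  status[det & concentration >= loq] <- "quantitative"
  status
}

#' Statuses that count as detections
#' @keywords internal
DETECTION_STATUSES <- c("semiquantitative", "quantitative")

is_detection <- function(status) status %in% DETECTION_STATUSES

#' Detection percentage with half-up integer rounding
#'
#' Computes `100 * k / n` rounded half-up to the nearest integer percent,
#' the convention used throughout detection-frequency and co-occurrence
#' reporting (so 48 of 53 is 91, not 90.57).
#'
#' @param k Number of detections (numerator).
#' @param n Number of opportunities (denominator).
#' @return Integer percent; `NA` when `n == 0`.
#' @examples
#' detection_percent(48, 53)
#' @export
detection_percent <- function(k, n) {
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  out <- floor(100 * k / n + 0.5)
  out[n == 0] <- NA_real_
  unname(out)
}

# Unit tags: concentrations are carried with explicit tags and converted to
# ug/L only where risk ratios are formed (mg/L x 1000).
normalize_units <- function(units) {
  u <- tolower(trimws(units))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("\\s", "", u)
  out <- rep(NA_character_, length(u))
  out[u %in% c("ug/l", "ugl", "ug.l-1")] <- "ug/L"
  out[u %in% c("mg/l", "mgl", "mg.l-1")] <- "mg/L"
  if (anyNA(out)) {
    stop("unknown concentration units: ",
         paste(unique(units[is.na(out)]), collapse = ", "),
         " (expected ug/L or mg/L)")
  }
  out
}

#' Convert tagged concentrations to micrograms per litre
#'
#' @param x Numeric concentrations.
#' @param units Character vector of unit tags (`"ug/L"` or `"mg/L"`,
#'   micro sign accepted), recycled against `x`.
#' @return Numeric vector in ug/L.
#' @export
conc_to_ugL <- function(x, units) {
  units <- normalize_units(units)
  ifelse(units == "mg/L", x * 1000, x)
}

#' Validate CAS registry numbers
#'
#' Checks the `NNNNNNN-NN-N` format and the CAS check digit (the last digit
#' equals the weighted sum of the preceding digits, weights increasing from
#' the right, modulo 10).
#'
#' @param cas Character vector of CAS registry numbers.
#' @return Logical vector, `TRUE` for syntactically valid numbers.
#' @examples
#' cas_is_valid(c("7440-38-2", "50-00-0", "1234-56-7"))
#' @export
cas_is_valid <- function(cas) {
  ok <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  vapply(seq_along(cas), function(i) {
    if (!ok[i]) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", cas[i]), "")[[1]])
    nd <- length(digits)
    check <- digits[nd]
    body <- rev(digits[-nd])
    sum(body * seq_along(body)) %% 10 == check
  }, logical(1))
}
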