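# Static covariate schema shared by the synthetic generator and the
# MIMIC-style extractor. Categorical variables are one-hot encoded with the
# stated reference groups omitted; numeric variables pass through
# un-standardised. The resulting vector has 23 entries in a fixed,
# documented column order.

#' Static covariate schema
#'
#' Returns the definition of the static covariate vector used by every
#' model: four numeric variables (age in years at ICU discharge, ICU length
#' of stay in days, pre-ICU hospital length of stay in days, number of ICU
#' admissions in the preceding year), two binary indicators (male gender,
#' elective surgery admission) and four categorical variables encoded
#' one-hot against reference groups female / white / Medicare /
#' married-or-life-partner / emergency-room admission.
#'
#' @return A list with elements `numeric` (names), `binary` (names),
#'   `categorical` (named list of level vectors, first level = reference)
#'   and `columns` (the fixed encoded column order, length 23).
#' @export
static_schema <- function() {
  numeric <- c("age", "icu_los", "preicu_los", "n_recent_admissions")
  binary <- c("gender_male", "elective_surgery")
  categorical <- list(
    ethnicity = c("white", "asian", "black", "hispanic",
                  "other_unknown", "unable_to_obtain"),
    insurance = c("medicare", "government", "medicaid", "private", "self_pay"),
    marital = c("married", "other_unknown", "single",
                "widowed_divorced_separated"),
    admission_location = c("emergency", "clinic_referral", "other_unknown",
                           "physician_referral", "transfer_hospital",
                           "transfer_snf")
  )
  cols <- c(numeric, binary,
            unlist(lapply(names(categorical), function(v) {
              paste(v, categorical[[v]][-1L], sep = ":")
            }), use.names = FALSE))
  list(numeric = numeric, binary = binary, categorical = categorical,
       columns = cols)
}

#' Encode raw static covariates as the fixed model vector
#'
#' @param raw A data frame with one row per stay and columns `age`,
#'   `icu_los`, `preicu_los`, `n_recent_admissions`, `gender_male`,
#'   `elective_surgery`, `ethnicity`, `insurance`, `marital`,
#'   `admission_location` (categoricals as character levels of
#'   [static_schema()]).
#' @return Numeric matrix, one row per stay, 23 named columns in the fixed
#'   schema order. Reference-group patients have all categorical entries 0.
#' @export
build_static_vector <- function(raw) {
  sch <- static_schema()
  n <- nrow(raw)
  out <- matrix(0, n, length(sch$columns),
                dimnames = list(NULL, sch$columns))
  for (v in c(sch$numeric, sch$binary)) {
    if (is.null(raw[[v]])) stop2("missing static covariate: ", v)
    out[, v] <- as.numeric(raw[[v]])
  }
  for (v in names(sch$categorical)) {
    levs <- sch$categorical[[v]]
    vals <- as.character(raw[[v]])
    bad <- !(vals %in% levs)
    if (any(bad)) {
      stop2("unknown level(s) for ", v, ": ",
            paste(unique(vals[bad]), collapse = ", "))
    }
    for (lv in levs[-1L]) {
      out[, paste(v, lv, sep = ":")] <- as.numeric(vals == lv)
    }
  }
  out
}

#' Decode a static vector back to raw categories
#'
#' Inverse of [build_static_vector()]; used to verify the encoding is a
#' bijection.
#'
#' @param x Encoded matrix (or single row) with schema columns.
#' @return Data frame of raw covariates.
#' @export
decode_static_vector <- function(x) {
  x <- as_matrix(x)
  sch <- static_schema()
  out <- as.data.frame(x[, c(sch$numeric, sch$binary), drop = FALSE])
  for (v in names(sch$categorical)) {
    levs <- sch$categorical[[v]]
    cols <- paste(v, levs[-1L], sep = ":")
    sub <- x[, cols, drop = FALSE]
    pick <- apply(sub, 1L, function(r) {
      j <- which(r == 1)
      if (length(j) == 0L) levs[1L] else levs[-1L][j[1L]]
    })
    out[[v]] <- pick
  }
  out
}
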