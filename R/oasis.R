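# OASIS-style categorisation of the seven monitored vital signs.
# Cut-points follow the published OASIS severity-of-illness score; the
# bins are hard-coded and exposed for inspection.

OASIS_BINS <- list(
  heart_rate = list(breaks = c(-Inf, 33, 89, 107, 126, Inf),
                    labels = c("lt33", "33-88", "89-106", "107-125", "gt125"),
                    range = c(0, 300)),
  map = list(breaks = c(-Inf, 20.65, 51, 61.33, 143.45, Inf),
             labels = c("lt20.65", "20.65-50.99", "51-61.32",
                        "61.33-143.44", "gt143.44"),
             range = c(0, 300)),
  resp_rate = list(breaks = c(-Inf, 6, 13, 23, 31, 45, Inf),
                   labels = c("lt6", "6-12", "13-22", "23-30", "31-44", "gt44"),
                   range = c(0, 120)),
  temp = list(breaks = c(-Inf, 33.22, 35.94, 36.40, 36.89, 39.89, Inf),
              labels = c("lt33.22", "33.22-35.93", "35.94-36.39",
                         "36.40-36.88", "36.89-39.88", "gt39.88"),
              range = c(25, 46)),
  urine_output = list(breaks = c(-Inf, 671, 1427, 2544, 6897, Inf),
                      labels = c("lt671", "671-1426", "1427-2543",
                                 "2544-6896", "gt6896"),
                      range = c(0, 20000)),
  gcs = list(breaks = c(-Inf, 8, 14, 15, 16),
             labels = c("3-7", "8-13", "14", "15"),
             range = c(3, 15))
)

#' OASIS bin for a vital-sign measurement
#'
#' Maps a continuous vital-sign value to its OASIS category and returns a
#' categorical code string `"<vital>:<bin>"`. Values outside configurable
#' physiological bounds are flagged by returning `NA` (callers drop them).
#' `ventilated` is binary and returns `"ventilated:yes"`/`"ventilated:no"`.
#'
#' @param vital One of `"gcs"`, `"heart_rate"`, `"map"`, `"resp_rate"`,
#'   `"temp"` (deg C), `"urine_output"` (mL/day), `"ventilated"`.
#' @param value Numeric measurement(s).
#' @param bounds Optional length-2 physiological range overriding the
#'   default for the vital.
#' @return Character code(s); `NA` where the value is out of range.
#' @export
oasis_bin_vital <- function(vital, value, bounds = NULL) {
  if (vital == "ventilated") {
    return(paste0("ventilated:", ifelse(value > 0, "yes", "no")))
  }
  spec <- OASIS_BINS[[vital]]
  if (is.null(spec)) {
    stop2("unknown vital '", vital, "'; expected one of: ",
          paste(c(names(OASIS_BINS), "ventilated"), collapse = ", "))
  }
  rng <- bounds %||% spec$range
  bin <- as.character(cut(value, breaks = spec$breaks, labels = spec$labels,
                          right = FALSE))
  out <- paste0(vital, ":", bin)
  out[is.na(value) | value < rng[1] | value > rng[2]] <- NA_character_
  out
}

#' All possible OASIS vital-sign codes
#'
#' @return Character vector of every `"<vital>:<bin>"` code (32 in total).
#' @export
oasis_vital_codes <- function() {
  c(unlist(lapply(names(OASIS_BINS), function(v) {
    paste0(v, ":", OASIS_BINS[[v]]$labels)
  }), use.names = FALSE), "ventilated:yes", "ventilated:no")
}
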