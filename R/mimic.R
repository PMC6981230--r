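# Cohort extraction from MIMIC-III v1.4 style CSV tables into the same
# stays/events schema the synthetic generator emits. The raw data are
# credentialed-access and never shipped; all functions operate on data
# frames with the standard MIMIC column names, so they are testable on
# synthetic fixtures with the same schema.

#' Default CHARTEVENTS/OUTPUTEVENTS item ids per monitored vital
#'
#' The source tables do not come with a canonical item-id map for the
#' seven OASIS vitals; this documented default covers the common CareVue
#' and MetaVision ids. GCS is taken from the CareVue total (198) or as the
#' per-charttime sum of the three MetaVision components; ventilation is
#' inferred from the presence of ventilator-mode settings; urine output is
#' aggregated per calendar day before binning (OASIS bins are per-day
#' totals).
#'
#' @return Named list of integer item-id vectors.
#' @export
mimic_vital_items <- function() {
  list(
    heart_rate = c(211L, 220045L),
    map = c(456L, 52L, 220052L, 220181L),
    resp_rate = c(618L, 220210L),
    temp_c = c(676L, 223762L),
    temp_f = c(678L, 223761L),
    gcs_total = 198L,
    gcs_components = c(220739L, 223900L, 223901L),
    ventilated = c(720L, 223849L),
    urine_output = c(40055L, 43175L, 40069L, 40094L, 226559L, 226560L)
  )
}

parse_dt <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(as.character(x), tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
}

days_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days"))
}

#' Apply the cohort exclusion rules
#'
#' Removes ICU stays where (a) the patient died during the stay, (b) the
#' patient was younger than 18 years at ICU discharge, or (c) the patient
#' died within 30 days of discharge without an intervening ICU
#' readmission. Stays with a missing discharge timestamp are rejected with
#' a logged reason. Ages above 89 (date-shifted in the source data) are
#' capped at 90 before the adult check.
#'
#' @param icustays Data frame with `SUBJECT_ID`, `ICUSTAY_ID`, `INTIME`,
#'   `OUTTIME`.
#' @param patients Data frame with `SUBJECT_ID`, `DOB`, `DOD` (NA if
#'   alive).
#' @return The included stays, with an `exclusions` attribute counting
#'   removals per rule and a `log` attribute listing rejected stay ids and
#'   reasons.
#' @export
apply_exclusions <- function(icustays, patients) {
  st <- icustays
  st$INTIME <- parse_dt(st$INTIME)
  st$OUTTIME <- parse_dt(st$OUTTIME)
  pt <- patients
  pt$DOB <- parse_dt(pt$DOB)
  pt$DOD <- parse_dt(pt$DOD)
  m <- match(st$SUBJECT_ID, pt$SUBJECT_ID)
  dob <- pt$DOB[m]; dod <- pt$DOD[m]
  log <- data.frame(ICUSTAY_ID = integer(0), reason = character(0))
  drop_missing <- is.na(st$OUTTIME)
  if (any(drop_missing)) {
    log <- rbind(log, data.frame(ICUSTAY_ID = st$ICUSTAY_ID[drop_missing],
                                 reason = "missing discharge timestamp"))
  }
  died_in_stay <- !is.na(dod) & !drop_missing &
    dod >= st$INTIME & dod <= st$OUTTIME
  age <- pmin(days_between(st$OUTTIME, dob) / 365.25, 300)
  age[age > 89] <- 90
  minor <- !drop_missing & !died_in_stay & age < 18
  # death within 30 days of discharge, no intervening readmission
  ord <- order(st$SUBJECT_ID, st$INTIME)
  next_in <- rep(as.POSIXct(NA, tz = "UTC"), nrow(st))
  so <- st[ord, ]
  nxt <- c(so$INTIME[-1L], as.POSIXct(NA, tz = "UTC"))
  nxt[so$SUBJECT_ID != c(so$SUBJECT_ID[-1L], NA)] <- NA
  next_in[ord] <- nxt
  death30 <- !drop_missing & !died_in_stay & !minor & !is.na(dod) &
    days_between(dod, st$OUTTIME) <= 30 &
    !(!is.na(next_in) & days_between(next_in, st$OUTTIME) <= 30 & next_in <= dod)
  keep <- !(drop_missing | died_in_stay | minor | death30)
  if (any(died_in_stay)) {
    log <- rbind(log, data.frame(ICUSTAY_ID = st$ICUSTAY_ID[died_in_stay],
                                 reason = "died during ICU stay"))
  }
  if (any(minor)) {
    log <- rbind(log, data.frame(ICUSTAY_ID = st$ICUSTAY_ID[minor],
                                 reason = "younger than 18 at discharge"))
  }
  if (any(death30)) {
    log <- rbind(log, data.frame(ICUSTAY_ID = st$ICUSTAY_ID[death30],
                                 reason = "died within 30 days, no readmission"))
  }
  out <- st[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    missing_outtime = sum(drop_missing),
    died_in_stay = sum(died_in_stay),
    under_18 = sum(minor),
    death_30d_no_readmit = sum(death30)
  )
  attr(out, "log") <- log
  out
}

#' Label 30-day ICU readmission for one patient's stays
#'
#' A stay is positive iff the same patient's next ICU admission starts at
#' most 30 days (inclusive) after this stay's ICU discharge. Any later
#' ICU stay row counts as a readmission candidate, including transfers
#' within the same hospitalisation.
#'
#' @param stays Data frame of one patient's stays with `ICUSTAY_ID`,
#'   `INTIME`, `OUTTIME`, sorted by admission time.
#' @return Integer 0/1 label per stay.
#' @export
label_readmission <- function(stays) {
  if (nrow(stays) == 0L) return(integer(0))
  intime <- parse_dt(stays$INTIME)
  outtime <- parse_dt(stays$OUTTIME)
  if (is.unsorted(as.numeric(intime))) stop2("stays must be sorted by admission time")
  if (nrow(stays) > 1L) {
    overlap <- which(intime[-1L] < outtime[-nrow(stays)])
    if (length(overlap)) {
      stop2("overlapping ICU stays: ",
            paste(stays$ICUSTAY_ID[overlap], stays$ICUSTAY_ID[overlap + 1L],
                  sep = "/", collapse = ", "))
    }
  }
  gap <- c(days_between(intime[-1L], outtime[-nrow(stays)]), Inf)
  as.integer(gap <= 30)
}

#' Keep only the latest of consecutive duplicate vital-sign codes
#'
#' Within a time-sorted event sequence, every maximal run of consecutive
#' identical vital-sign codes is collapsed to its latest observation;
#' non-vital codes are untouched (they also break runs).
#'
#' @param events Data frame with `code` and a time column, sorted in time
#'   order (oldest first).
#' @param is_vital Logical per event (default: all).
#' @return The deduplicated events.
#' @export
dedupe_consecutive <- function(events, is_vital = rep(TRUE, nrow(events))) {
  n <- nrow(events)
  if (n <= 1L) return(events)
  nxt_same <- c(events$code[-1L] == events$code[-n] & is_vital[-1L], FALSE)
  drop <- is_vital & nxt_same
  events[!drop, , drop = FALSE]
}

#' Relabel rare categorical values as "other"
#'
#' Every value associated with fewer than `threshold` distinct ICU stays
#' is mapped to `"other"`; all other values keep their identity. Returns
#' the mapped values together with the vocabulary (dense indices and
#' per-code stay counts).
#'
#' @param values Character vector of raw values (one per occurrence).
#' @param stay_ids Stay id per occurrence (stay-level association counts
#'   use distinct stays).
#' @param threshold Minimum number of distinct stays (default 100;
#'   strict: a value in exactly `threshold` stays is kept).
#' @return List with `mapped` (character vector) and `vocab` (data frame
#'   `value`, `index`, `n_stays`; `"other"` holds the reserved last
#'   index when any value was relabelled).
#' @export
relabel_rare <- function(values, stay_ids, threshold = 100L) {
  cnt <- tapply(stay_ids, values, function(s) length(unique(s)))
  rare <- names(cnt)[cnt < threshold]
  mapped <- ifelse(values %in% rare, "other", values)
  kept <- sort(setdiff(unique(mapped), "other"))
  vocab_vals <- c(kept, if (any(mapped == "other")) "other")
  vocab <- data.frame(
    value = vocab_vals,
    index = seq_along(vocab_vals),
    n_stays = vapply(vocab_vals, function(v) {
      length(unique(stay_ids[mapped == v]))
    }, 0L),
    row.names = NULL
  )
  list(mapped = mapped, vocab = vocab)
}

#' Elapsed time before the index ICU discharge
#'
#' `max(0, reference - event)` in days (diagnosis/procedure stream) or
#' hours (medication/vital stream). Events timestamped after the
#' reference are clamped to zero with a warning beyond the tolerance
#' (codes are assumed available at the time of ICU discharge).
#'
#' @param event_ts Event timestamp(s).
#' @param reference_ts Index ICU discharge timestamp.
#' @param unit `"days"` or `"hours"`.
#' @param tolerance Allowed post-discharge slack (same unit) before a
#'   warning is emitted.
#' @return Non-negative elapsed time(s).
#' @export
elapsed_time <- function(event_ts, reference_ts, unit = c("days", "hours"),
                         tolerance = 0) {
  unit <- match.arg(unit)
  el <- as.numeric(difftime(parse_dt(reference_ts), parse_dt(event_ts),
                            units = unit))
  if (any(el < -tolerance, na.rm = TRUE)) {
    warning(sum(el < -tolerance, na.rm = TRUE),
            " event(s) after the reference time; clamped to 0")
  }
  pmax(el, 0)
}

# map raw MIMIC categorical strings to the static schema levels
map_mimic_categories <- function(adm) {
  eth <- toupper(adm$ETHNICITY %||% "")
  ethnicity <- rep("other_unknown", nrow(adm))
  ethnicity[grepl("WHITE", eth)] <- "white"
  ethnicity[grepl("BLACK", eth)] <- "black"
  ethnicity[grepl("ASIAN", eth)] <- "asian"
  ethnicity[grepl("HISPANIC|LATINO", eth)] <- "hispanic"
  ethnicity[grepl("UNABLE", eth)] <- "unable_to_obtain"
  ins <- toupper(adm$INSURANCE %||% "")
  insurance <- rep("government", nrow(adm))
  insurance[grepl("MEDICARE", ins)] <- "medicare"
  insurance[grepl("MEDICAID", ins)] <- "medicaid"
  insurance[grepl("PRIVATE", ins)] <- "private"
  insurance[grepl("SELF", ins)] <- "self_pay"
  mar <- toupper(adm$MARITAL_STATUS %||% "")
  marital <- rep("other_unknown", nrow(adm))
  marital[grepl("MARRIED|LIFE PARTNER", mar)] <- "married"
  marital[grepl("SINGLE", mar)] <- "single"
  marital[grepl("WIDOWED|DIVORCED|SEPARATED", mar)] <- "widowed_divorced_separated"
  loc <- toupper(adm$ADMISSION_LOCATION %||% "")
  admission_location <- rep("other_unknown", nrow(adm))
  admission_location[grepl("EMERGENCY", loc)] <- "emergency"
  admission_location[grepl("CLINIC REFERRAL|PREMATURE", loc)] <- "clinic_referral"
  admission_location[grepl("PHYS REFERRAL|NORMAL DELI", loc)] <- "physician_referral"
  admission_location[grepl("TRANSFER FROM HOSP|EXTRAM", loc)] <- "transfer_hospital"
  admission_location[grepl("SKILLED NUR", loc)] <- "transfer_snf"
  data.frame(ethnicity = ethnicity, insurance = insurance, marital = marital,
             admission_location = admission_location,
             elective_surgery = as.integer(toupper(adm$ADMISSION_TYPE %||% "") == "ELECTIVE"))
}

#' Extract a labelled cohort from MIMIC-III style tables
#'
#' Applies, in order: the exclusion rules, 30-day readmission labelling,
#' static-covariate construction, diagnosis/procedure code collection over
#' the full clinical history (elapsed in days from the carrying hospital
#' admission's discharge; index-admission codes get elapsed 0),
#' medication and OASIS-binned vital-sign collection restricted to the
#' index ICU stay (elapsed in hours), consecutive-duplicate removal for
#' vitals, rare-value relabelling to "other" (stay-association threshold
#' 100), and a patient-level train/test split.
#'
#' @param tables Named list of data frames: `PATIENTS`, `ADMISSIONS`,
#'   `ICUSTAYS`, `DIAGNOSES_ICD`, `PROCEDURES_ICD`, `PRESCRIPTIONS`,
#'   `CHARTEVENTS`, `OUTPUTEVENTS` (the last three optional). Column
#'   names as in MIMIC-III v1.4.
#' @param threshold Rare-value stay-count threshold (default 100).
#' @param test_fraction Patient fraction in the test split.
#' @param seed Integer seed for the split.
#' @return An `emr_cohort` (without generator ground truth).
#' @export
extract_mimic_cohort <- function(tables, threshold = 100L,
                                 test_fraction = 0.10, seed = 1L) {
  icu <- apply_exclusions(tables$ICUSTAYS, tables$PATIENTS)
  exclusions <- attr(icu, "exclusions")
  icu$INTIME <- parse_dt(icu$INTIME); icu$OUTTIME <- parse_dt(icu$OUTTIME)
  icu <- icu[order(icu$SUBJECT_ID, icu$INTIME), , drop = FALSE]
  # labels consider every ICU stay of the patient, including stays that
  # the exclusion rules later remove (a readmission that ends in death is
  # still a readmission for the index stay)
  all_icu <- tables$ICUSTAYS
  all_icu$INTIME <- parse_dt(all_icu$INTIME)
  all_icu$OUTTIME <- parse_dt(all_icu$OUTTIME)
  all_icu <- all_icu[!is.na(all_icu$OUTTIME), , drop = FALSE]
  all_icu <- all_icu[order(all_icu$SUBJECT_ID, all_icu$INTIME), , drop = FALSE]
  all_labels <- unlist(lapply(split(all_icu, all_icu$SUBJECT_ID),
                              label_readmission), use.names = FALSE)
  icu$label <- all_labels[match(icu$ICUSTAY_ID, all_icu$ICUSTAY_ID)]

  adm <- tables$ADMISSIONS
  adm$ADMITTIME <- parse_dt(adm$ADMITTIME)
  adm$DISCHTIME <- parse_dt(adm$DISCHTIME)
  am <- match(icu$HADM_ID, adm$HADM_ID)
  pt <- tables$PATIENTS
  pm <- match(icu$SUBJECT_ID, pt$SUBJECT_ID)
  age <- pmin(days_between(icu$OUTTIME, parse_dt(pt$DOB[pm])) / 365.25, 300)
  age[age > 89] <- 90
  n_recent <- vapply(seq_len(nrow(icu)), function(i) {
    same <- icu$SUBJECT_ID == icu$SUBJECT_ID[i]
    sum(same & icu$INTIME < icu$INTIME[i] &
          days_between(icu$OUTTIME[i], icu$INTIME) <= 365, na.rm = TRUE)
  }, 0L)
  gender <- as.integer(toupper(pt$GENDER[pm]) == "M")
  cats <- map_mimic_categories(adm[am, , drop = FALSE])
  raw_static <- data.frame(
    age = age,
    icu_los = days_between(icu$OUTTIME, icu$INTIME),
    preicu_los = pmax(days_between(icu$INTIME, adm$ADMITTIME[am]), 0),
    n_recent_admissions = n_recent,
    gender_male = gender,
    cats
  )
  X <- build_static_vector(raw_static)
  stay_key <- as.character(icu$ICUSTAY_ID)

  # diagnosis/procedure codes over the whole history up to the index stay
  dxproc_raw <- list()
  for (tb in c("DIAGNOSES_ICD", "PROCEDURES_ICD")) {
    codes <- tables[[tb]]
    if (is.null(codes) || nrow(codes) == 0) next
    pref <- if (tb == "DIAGNOSES_ICD") "dx:" else "proc:"
    cm <- match(codes$HADM_ID, adm$HADM_ID)
    cdf <- data.frame(SUBJECT_ID = codes$SUBJECT_ID,
                      value = paste0(pref, codes$ICD9_CODE),
                      disch = adm$DISCHTIME[cm])
    for (i in seq_len(nrow(icu))) {
      is_index <- codes$HADM_ID == icu$HADM_ID[i]
      sel <- cdf$SUBJECT_ID == icu$SUBJECT_ID[i] & !is.na(cdf$disch) &
        (cdf$disch <= icu$OUTTIME[i] | is_index)
      if (!any(sel)) next
      sub <- cdf[sel, , drop = FALSE]
      # index-admission codes are assumed available at ICU discharge
      el <- elapsed_time(sub$disch, icu$OUTTIME[i], "days", tolerance = Inf)
      el[is_index[sel]] <- 0
      dxproc_raw[[length(dxproc_raw) + 1L]] <- data.frame(
        stay_id = stay_key[i], value = sub$value, elapsed = el)
    }
  }
  dxproc <- if (length(dxproc_raw)) do.call(rbind, dxproc_raw) else
    data.frame(stay_id = character(0), value = character(0), elapsed = numeric(0))

  # medications and vitals restricted to the index ICU stay
  medvit_raw <- list()
  rx <- tables$PRESCRIPTIONS
  if (!is.null(rx) && nrow(rx)) {
    rx$STARTDATE <- parse_dt(rx$STARTDATE)
    for (i in seq_len(nrow(icu))) {
      sel <- !is.na(rx$STARTDATE) &
        ((!is.null(rx$ICUSTAY_ID) & !is.na(rx$ICUSTAY_ID) &
            rx$ICUSTAY_ID == icu$ICUSTAY_ID[i]) |
           (rx$HADM_ID == icu$HADM_ID[i] &
              rx$STARTDATE >= icu$INTIME[i] - 1 & rx$STARTDATE <= icu$OUTTIME[i]))
      if (!any(sel)) next
      medvit_raw[[length(medvit_raw) + 1L]] <- data.frame(
        stay_id = stay_key[i],
        value = paste0("med:", tolower(rx$DRUG[sel])),
        elapsed = elapsed_time(rx$STARTDATE[sel], icu$OUTTIME[i], "hours"))
    }
  }
  vit <- extract_vitals(tables, icu)
  if (nrow(vit)) medvit_raw[[length(medvit_raw) + 1L]] <- vit
  medvit <- if (length(medvit_raw)) do.call(rbind, medvit_raw) else
    data.frame(stay_id = character(0), value = character(0), elapsed = numeric(0))

  # rare-value relabelling and dense indexing per stream
  rl1 <- relabel_rare(dxproc$value, dxproc$stay_id, threshold)
  rl2 <- relabel_rare(medvit$value, medvit$stay_id, threshold)
  dxproc$code <- rl1$vocab$index[match(rl1$mapped, rl1$vocab$value)]
  medvit$code <- rl2$vocab$index[match(rl2$mapped, rl2$vocab$value)]
  order_ev <- function(ev, ids) {
    ev <- ev[order(match(ev$stay_id, ids), -ev$elapsed, ev$code), , drop = FALSE]
    ev[, c("stay_id", "code", "elapsed")]
  }
  vocab <- list(
    dxproc = data.frame(index = rl1$vocab$index, name = rl1$vocab$value,
                        kind = sub(":.*", "", rl1$vocab$value),
                        vital_group = NA_character_),
    medvit = data.frame(index = rl2$vocab$index, name = rl2$vocab$value,
                        kind = sub(":.*", "", rl2$vocab$value),
                        vital_group = ifelse(startsWith(rl2$vocab$value, "vit:"),
                                             sub("^vit:([^:]+):.*$", "\\1",
                                                 rl2$vocab$value),
                                             NA_character_))
  )
  split_map <- split_patients(unique(as.character(icu$SUBJECT_ID)),
                              test_fraction, seed)
  stays <- data.frame(
    patient_id = as.character(icu$SUBJECT_ID),
    stay_id = stay_key,
    raw_static,
    label = icu$label,
    split = unname(split_map[as.character(icu$SUBJECT_ID)]),
    stringsAsFactors = FALSE
  )
  structure(list(
    stays = stays, X = X,
    events = list(dxproc = order_ev(dxproc, stay_key),
                  medvit = order_ev(medvit, stay_key)),
    vocab = vocab, truth = NULL, config = NULL,
    exclusions = exclusions
  ), class = "emr_cohort")
}

# OASIS-binned vital-sign events for each included stay (hours before
# ICU discharge), with consecutive duplicates removed
extract_vitals <- function(tables, icu) {
  ce <- tables$CHARTEVENTS
  oe <- tables$OUTPUTEVENTS
  out <- list()
  items <- mimic_vital_items()
  if (!is.null(ce) && nrow(ce)) {
    ce$CHARTTIME <- parse_dt(ce$CHARTTIME)
    for (i in seq_len(nrow(icu))) {
      sel <- ce$ICUSTAY_ID == icu$ICUSTAY_ID[i] & !is.na(ce$CHARTTIME)
      if (!any(sel, na.rm = TRUE)) next
      sub <- ce[which(sel), , drop = FALSE]
      ev <- vital_codes_for_stay(sub, items)
      if (is.null(ev) || nrow(ev) == 0) next
      ev <- ev[order(ev$time), , drop = FALSE]
      ev <- dedupe_consecutive(ev)
      out[[length(out) + 1L]] <- data.frame(
        stay_id = as.character(icu$ICUSTAY_ID[i]),
        value = ev$code,
        elapsed = elapsed_time(ev$time, icu$OUTTIME[i], "hours"))
    }
  }
  if (!is.null(oe) && nrow(oe)) {
    oe$CHARTTIME <- parse_dt(oe$CHARTTIME)
    for (i in seq_len(nrow(icu))) {
      sel <- oe$ICUSTAY_ID == icu$ICUSTAY_ID[i] & oe$ITEMID %in% items$urine_output
      if (!any(sel, na.rm = TRUE)) next
      sub <- oe[which(sel), , drop = FALSE]
      day <- as.Date(sub$CHARTTIME)
      daily <- tapply(sub$VALUE, day, sum)
      tim <- as.POSIXct(paste(names(daily), "23:59:59"), tz = "UTC")
      tim <- pmin(tim, icu$OUTTIME[i])
      code <- oasis_bin_vital("urine_output", as.numeric(daily))
      keep <- !is.na(code)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        stay_id = as.character(icu$ICUSTAY_ID[i]),
        value = paste0("vit:", code[keep]),
        elapsed = elapsed_time(tim[keep], icu$OUTTIME[i], "hours"))
    }
  }
  if (!length(out)) {
    return(data.frame(stay_id = character(0), value = character(0),
                      elapsed = numeric(0)))
  }
  do.call(rbind, out)
}

# classify chartevents rows of one stay into OASIS codes with timestamps
vital_codes_for_stay <- function(sub, items) {
  recs <- list()
  add <- function(vital, value, time) {
    code <- oasis_bin_vital(vital, value)
    keep <- !is.na(code)
    if (any(keep)) {
      recs[[length(recs) + 1L]] <<- data.frame(
        code = paste0("vit:", code[keep]), time = time[keep])
    }
  }
  grab <- function(ids) sub$ITEMID %in% ids & !is.na(sub$VALUENUM)
  s <- grab(items$heart_rate)
  if (any(s)) add("heart_rate", sub$VALUENUM[s], sub$CHARTTIME[s])
  s <- grab(items$map)
  if (any(s)) add("map", sub$VALUENUM[s], sub$CHARTTIME[s])
  s <- grab(items$resp_rate)
  if (any(s)) add("resp_rate", sub$VALUENUM[s], sub$CHARTTIME[s])
  s <- grab(items$temp_c)
  if (any(s)) add("temp", sub$VALUENUM[s], sub$CHARTTIME[s])
  s <- grab(items$temp_f)
  if (any(s)) add("temp", (sub$VALUENUM[s] - 32) * 5 / 9, sub$CHARTTIME[s])
  s <- grab(items$gcs_total)
  if (any(s)) add("gcs", sub$VALUENUM[s], sub$CHARTTIME[s])
  s <- grab(items$gcs_components)
  if (any(s)) {
    comp <- sub[s, , drop = FALSE]
    tot <- tapply(comp$VALUENUM, as.character(comp$CHARTTIME), sum)
    complete <- tapply(comp$VALUENUM, as.character(comp$CHARTTIME), length) == 3
    if (any(complete)) {
      add("gcs", as.numeric(tot[complete]),
          parse_dt(names(tot)[complete]))
    }
  }
  s <- sub$ITEMID %in% items$ventilated
  if (any(s)) add("ventilated", rep(1, sum(s)), sub$CHARTTIME[s])
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

#' Read MIMIC-III CSV tables from a directory
#'
#' @param dir Directory holding `PATIENTS.csv`, `ADMISSIONS.csv`, ... (as
#'   named by the source distribution, optionally gzipped).
#' @param tables Table names to read.
#' @return Named list of data frames.
#' @export
read_mimic_tables <- function(dir, tables = c("PATIENTS", "ADMISSIONS",
                                              "ICUSTAYS", "DIAGNOSES_ICD",
                                              "PROCEDURES_ICD", "PRESCRIPTIONS",
                                              "CHARTEVENTS", "OUTPUTEVENTS")) {
  out <- list()
  for (tb in tables) {
    for (fn in file.path(dir, paste0(tb, c(".csv", ".csv.gz")))) {
      if (file.exists(fn)) {
        out[[tb]] <- as.data.frame(data.table::fread(fn))
        break
      }
    }
  }
  out
}
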