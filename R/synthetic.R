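# Synthetic EMR cohort generator.
#
# Emulates the statistical structure the risk models assume: two code
# streams on different time scales (diagnoses/procedures with day-scale
# elapsed times spanning the clinical history; medications/vital signs with
# hour-scale elapsed times within the index ICU stay), irregular sampling,
# rare categories (Zipf-like code frequencies), a ~12% positive prevalence,
# and time-decaying code relevance with a chronic (non-decaying) subset.
# The generative risk model is fully known, so recovery of planted effects
# and Bayes-optimality of the oracle score are testable.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the package is tested under:
#' target prevalence 12%, about 1.37 stays per patient, negative-binomial
#' sequence lengths, a Zipf-like code frequency profile, a mixture of
#' chronic (non-decaying) and rapidly decaying code effects, and a latent
#' patient frailty that tilts code sampling so that high-risk codes
#' co-occur within sicker patients.
#'
#' @param n_patients Number of patients.
#' @param stays_mean_extra Poisson mean of additional stays beyond the
#'   first (stays per patient = 1 + Pois).
#' @param vocab Named counts `c(dx=, proc=, med=, vit=)`. Diagnoses and
#'   procedures form one embedded stream, medications and vital signs the
#'   other.
#' @param seq_len List with negative-binomial `c(mean=, size=)` per stream.
#' @param p_index_dxproc Probability that a diagnosis/procedure code stems
#'   from the index admission (elapsed time 0 days).
#' @param dxproc_time_mean Mean of the exponential elapsed-time component
#'   for historical diagnosis/procedure codes, in days.
#' @param horizon_days Cap on historical elapsed times, in days.
#' @param prevalence Target fraction of positive (readmitted) stays.
#' @param chronic_frac Fraction of codes whose effect does not decay
#'   (decay rate 0).
#' @param lambda_range_dxproc,lambda_range_medvit Log-uniform range of
#'   decay rates for non-chronic codes (per day / per hour).
#' @param beta_slab_prob,beta_slab_sd,beta_spike_sd Spike-and-slab
#'   parameters of per-code base effects on the logit scale.
#' @param beta_static Named numeric vector of planted static-covariate
#'   effects (logit scale) over the encoded columns of [static_schema()];
#'   missing names get 0.
#' @param cooccurrence Strength of the frailty tilt on code sampling
#'   (0 = codes sampled independently of patient risk profile).
#' @param test_fraction Fraction of patients assigned to the test split.
#' @param icu_los_meanlog,icu_los_sdlog Log-normal ICU length of stay
#'   (days).
#' @param seed Default seed carried with the configuration.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             stays_mean_extra = 0.37,
                             vocab = c(dx = 200, proc = 60, med = 120, vit = 32),
                             seq_len = list(dxproc = c(mean = 12, size = 3),
                                            medvit = c(mean = 16, size = 3)),
                             p_index_dxproc = 0.45,
                             dxproc_time_mean = 300,
                             horizon_days = 1825,
                             prevalence = 0.12,
                             chronic_frac = 0.3,
                             lambda_range_dxproc = c(0.002, 0.2),
                             lambda_range_medvit = c(0.001, 0.1),
                             beta_slab_prob = 0.3,
                             beta_slab_sd = 0.25,
                             beta_spike_sd = 0.05,
                             beta_static = default_static_effects(),
                             cooccurrence = 0.5,
                             test_fraction = 0.10,
                             icu_los_meanlog = log(2.1),
                             icu_los_sdlog = 0.9,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 0) stop2("n_patients must be >= 0")
  if (any(cfg$vocab <= 0)) stop2("vocabulary sizes must be positive")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) {
    stop2("target prevalence must be in (0, 1)")
  }
  if (any(unlist(cfg$seq_len) <= 0)) stop2("sequence-length parameters must be positive")
  if (cfg$chronic_frac < 0 || cfg$chronic_frac > 1) stop2("chronic_frac must be in [0,1]")
  class(cfg) <- "generator_config"
  cfg
}

#' Default planted static-covariate effects
#'
#' Modest, clinically plausible log-odds effects: male gender, recent
#' admissions and age increase risk; elective surgery and longer pre-ICU
#' stays are mildly protective.
#'
#' @return Named numeric vector over encoded static columns.
#' @export
default_static_effects <- function() {
  c(gender_male = 0.11, n_recent_admissions = 0.17, age = 0.009,
    preicu_los = -0.006, elective_surgery = -0.06,
    "insurance:private" = -0.20, "ethnicity:black" = 0.15)
}

#' Sample a ground truth for the synthetic generator
#'
#' Draws per-code base effects (spike-and-slab) and decay rates (a chronic
#' fraction with rate 0, the rest log-uniform) for both streams, and takes
#' the planted static effects from the configuration. The intercept is left
#' `NA` until calibrated against the target prevalence.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Object of class `emr_ground_truth` with fields `b0`,
#'   `beta_static`, `beta_code` (per stream) and `lambda` (per stream,
#'   per day for diagnoses/procedures and per hour for medications/vitals).
#' @export
sample_ground_truth <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, 101L))
  sch <- static_schema()
  beta_static <- stats::setNames(numeric(length(sch$columns)), sch$columns)
  keep <- intersect(names(config$beta_static), sch$columns)
  beta_static[keep] <- config$beta_static[keep]
  draw_stream <- function(V, lam_range) {
    slab <- stats::rbinom(V, 1, config$beta_slab_prob) == 1
    beta <- ifelse(slab, stats::rnorm(V, 0, config$beta_slab_sd),
                   stats::rnorm(V, 0, config$beta_spike_sd))
    chronic <- stats::runif(V) < config$chronic_frac
    lam <- exp(stats::runif(V, log(lam_range[1]), log(lam_range[2])))
    lam[chronic] <- 0
    list(beta = beta, lambda = lam)
  }
  v1 <- sum(config$vocab[c("dx", "proc")])
  v2 <- sum(config$vocab[c("med", "vit")])
  s1 <- draw_stream(v1, config$lambda_range_dxproc)
  s2 <- draw_stream(v2, config$lambda_range_medvit)
  structure(list(
    b0 = NA_real_,
    beta_static = beta_static,
    beta_code = list(dxproc = s1$beta, medvit = s2$beta),
    lambda = list(dxproc = s1$lambda, medvit = s2$lambda)
  ), class = "emr_ground_truth")
}

#' True readmission risk of a stay under the generative model
#'
#' The oracle risk is
#' `sigmoid(b0 + x . beta_static + sum_events beta_code * exp(-lambda_code * t))`,
#' with elapsed times `t` in days for the diagnosis/procedure stream and in
#' hours for the medication/vital stream. This is the Bayes-optimal score
#' for the generated labels.
#'
#' @param stay A stay record: list with `static` (named numeric vector over
#'   schema columns), `events_dxproc` and `events_medvit` (data frames with
#'   `code`, `elapsed`).
#' @param truth An `emr_ground_truth` with calibrated intercept.
#' @return Probability in (0, 1).
#' @export
true_risk <- function(stay, truth) {
  sigmoid(linear_predictor(stay, truth) + truth$b0)
}

linear_predictor <- function(stay, truth) {
  eta <- sum(stay$static * truth$beta_static[names(stay$static)])
  for (stream in c("dxproc", "medvit")) {
    ev <- stay[[paste0("events_", stream)]]
    if (is.null(ev) || nrow(ev) == 0) next
    beta <- truth$beta_code[[stream]]
    bad <- ev$code < 1 | ev$code > length(beta)
    if (any(bad)) {
      stop2("unknown ", stream, " code id(s): ",
            paste(unique(ev$code[bad]), collapse = ", "))
    }
    lam <- truth$lambda[[stream]]
    eta <- eta + sum(beta[ev$code] * exp(-lam[ev$code] * ev$elapsed))
  }
  eta
}

# ---- internal cohort-structure simulation (shared by calibration and
# generation so that the intercept is calibrated on exactly the process
# that generates the data) ----

gen_structure <- function(config, truth, seed) {
  set.seed(derive_seed(seed, 202L))
  sch <- static_schema()
  np <- config$n_patients
  if (np == 0) {
    return(list(stays = data.frame(), X = matrix(0, 0, length(sch$columns)),
                events = list(dxproc = empty_events(), medvit = empty_events()),
                eta = numeric(0)))
  }
  # patient-level draws; frailty is discretised to 40 levels so that code
  # sampling can be vectorised by frailty group
  u_raw <- stats::rnorm(np)
  qs <- stats::qnorm((seq_len(40) - 0.5) / 40)
  u <- qs[pmax(1L, pmin(40L, findInterval(u_raw, stats::qnorm(seq_len(39) / 40)) + 1L))]
  gender_male <- stats::rbinom(np, 1, 0.56)
  age <- pmin(90, pmax(18, round(stats::rnorm(np, 64, 16))))
  ethnicity <- sample(sch$categorical$ethnicity, np, TRUE,
                      prob = c(0.70, 0.03, 0.10, 0.05, 0.10, 0.02))
  insurance <- sample(sch$categorical$insurance, np, TRUE,
                      prob = c(0.50, 0.03, 0.10, 0.34, 0.03))
  marital <- sample(sch$categorical$marital, np, TRUE,
                    prob = c(0.45, 0.12, 0.25, 0.18))
  n_stays <- 1L + stats::rpois(np, config$stays_mean_extra)
  ns <- sum(n_stays)
  pat_of_stay <- rep.int(seq_len(np), n_stays)
  raw <- data.frame(
    age = age[pat_of_stay],
    icu_los = stats::rlnorm(ns, config$icu_los_meanlog, config$icu_los_sdlog),
    preicu_los = stats::rlnorm(ns, log(1.2), 1.0),
    n_recent_admissions = stats::rpois(ns, 0.3),
    gender_male = gender_male[pat_of_stay],
    elective_surgery = stats::rbinom(ns, 1, 0.16),
    ethnicity = ethnicity[pat_of_stay],
    insurance = insurance[pat_of_stay],
    marital = marital[pat_of_stay],
    admission_location = sample(sch$categorical$admission_location, ns, TRUE,
                                prob = c(0.48, 0.10, 0.04, 0.22, 0.12, 0.04))
  )
  X <- build_static_vector(raw)
  stays <- data.frame(
    patient_id = sprintf("P%05d", pat_of_stay),
    stay_id = sprintf("S%06d", seq_len(ns)),
    stringsAsFactors = FALSE
  )
  los_hours <- raw$icu_los * 24

  draw_events <- function(stream) {
    pars <- config$seq_len[[stream]]
    len <- stats::rnbinom(ns, size = pars[["size"]], mu = pars[["mean"]])
    ne <- sum(len)
    stay_idx <- rep.int(seq_len(ns), len)
    beta <- truth$beta_code[[stream]]
    V <- length(beta)
    base_freq <- (1 / seq_len(V)^0.8)
    z <- beta / max(stats::sd(beta), 1e-8)
    codes <- integer(ne)
    uf <- u[pat_of_stay][stay_idx]
    for (lev in unique(uf)) {
      pick <- which(uf == lev)
      w <- base_freq * exp(config$cooccurrence * lev * z)
      codes[pick] <- sample.int(V, length(pick), replace = TRUE, prob = w)
    }
    if (stream == "dxproc") {
      at_index <- stats::runif(ne) < config$p_index_dxproc
      elapsed <- ifelse(at_index, 0,
                        pmin(stats::rexp(ne, 1 / config$dxproc_time_mean),
                             config$horizon_days))
    } else {
      elapsed <- stats::runif(ne, 0, los_hours[stay_idx])
    }
    ev <- data.frame(stay_idx = stay_idx, code = codes, elapsed = elapsed)
    # chronological order within stay: largest elapsed time (oldest) first;
    # ties broken by code index for determinism
    ev[order(ev$stay_idx, -ev$elapsed, ev$code), , drop = FALSE]
  }

  ev1 <- draw_events("dxproc")
  ev2 <- draw_events("medvit")
  eta_code <- function(ev, stream) {
    if (nrow(ev) == 0) return(numeric(ns))
    beta <- truth$beta_code[[stream]]
    lam <- truth$lambda[[stream]]
    contr <- beta[ev$code] * exp(-lam[ev$code] * ev$elapsed)
    out <- numeric(ns)
    agg <- rowsum(contr, ev$stay_idx)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  eta <- as.numeric(X %*% truth$beta_static) +
    eta_code(ev1, "dxproc") + eta_code(ev2, "medvit")
  ev1$stay_id <- stays$stay_id[ev1$stay_idx]
  ev2$stay_id <- stays$stay_id[ev2$stay_idx]
  list(stays = cbind(stays, raw), X = X,
       events = list(dxproc = ev1[, c("stay_id", "code", "elapsed")],
                     medvit = ev2[, c("stay_id", "code", "elapsed")]),
       eta = eta, pat_of_stay = pat_of_stay)
}

empty_events <- function() {
  data.frame(stay_id = character(0), code = integer(0), elapsed = numeric(0))
}

#' Calibrate the generative intercept to the target prevalence
#'
#' Simulates a Monte-Carlo cohort under the configuration and solves for
#' the intercept `b0` by bisection so that the mean oracle risk matches the
#' target prevalence. Deterministic given the seed.
#'
#' @param truth An `emr_ground_truth` (intercept may be `NA`).
#' @param config A [generator_config()].
#' @param n_mc Number of Monte-Carlo patients (>= 1000).
#' @param seed Integer seed.
#' @param tol Tolerance on the achieved mean risk.
#' @return The calibrated intercept (scalar, logit scale).
#' @export
calibrate_intercept <- function(truth, config, n_mc = 5000, seed = config$seed,
                                tol = 1e-4) {
  if (n_mc < 1000) stop2("n_mc must be >= 1000 for stable calibration")
  cfg <- config
  cfg$n_patients <- n_mc
  eta <- gen_structure(cfg, truth, seed)$eta
  target <- config$prevalence
  f <- function(b0) mean(sigmoid(b0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop2("intercept calibration failed: target outside achievable range")
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  stop2("intercept calibration did not converge after 200 bisection steps")
}

#' Generate a labelled synthetic cohort
#'
#' Draws patients, stays, static covariates and two timestamped code
#' streams, computes each stay's oracle risk under the ground truth and
#' draws binary 30-day readmission labels Bernoulli(risk). Patients are
#' split into train/validation vs test by patient identifier.
#'
#' @param config A [generator_config()].
#' @param truth An `emr_ground_truth`; if `NULL` one is sampled and its
#'   intercept calibrated to the target prevalence.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Object of class `emr_cohort`: list with `stays` (data frame with
#'   patient/stay ids, label, split, oracle risk and raw statics), `X`
#'   (encoded static matrix), `events` (per-stream data frames with
#'   `stay_id`, `code`, `elapsed`, chronologically sorted, oldest first),
#'   `vocab`, `truth`, `config`.
#' @export
generate_cohort <- function(config, truth = NULL, seed = config$seed) {
  if (is.null(truth)) {
    truth <- sample_ground_truth(config, seed)
    truth$b0 <- calibrate_intercept(truth, config, seed = seed)
  }
  if (is.na(truth$b0)) {
    stop2("ground truth has no intercept; run calibrate_intercept() first")
  }
  st <- gen_structure(config, truth, seed)
  risk <- sigmoid(truth$b0 + st$eta)
  set.seed(derive_seed(seed, 303L))
  label <- stats::rbinom(length(risk), 1, risk)
  split <- rep("train_valid", length(risk))
  if (config$n_patients > 0) {
    pat_ids <- unique(st$stays$patient_id)
    assign <- split_patients(pat_ids, config$test_fraction, seed)
    split <- assign[st$stays$patient_id]
  }
  stays <- st$stays
  stays$label <- label
  stays$split <- unname(split)
  stays$oracle_risk <- risk
  structure(list(
    stays = stays, X = st$X, events = st$events,
    vocab = synthetic_vocabulary(config),
    truth = truth, config = config
  ), class = "emr_cohort")
}

#' Vocabulary of a synthetic cohort
#'
#' Codes are indexed densely from 1 per stream. Diagnoses and procedures
#' share the first stream; medications and vital signs the second. Each
#' vital-sign code is assigned to one of the seven monitored vitals
#' (round-robin) so that the logistic baseline can select the most recent
#' code per vital.
#'
#' @param config A [generator_config()].
#' @return List with per-stream data frames (`index`, `name`, `kind`,
#'   `vital_group`).
#' @export
synthetic_vocabulary <- function(config) {
  v <- config$vocab
  dxproc <- data.frame(
    index = seq_len(v[["dx"]] + v[["proc"]]),
    name = c(sprintf("dx%03d", seq_len(v[["dx"]])),
             sprintf("proc%03d", seq_len(v[["proc"]]))),
    kind = c(rep("dx", v[["dx"]]), rep("proc", v[["proc"]])),
    vital_group = NA_character_,
    stringsAsFactors = FALSE
  )
  vitals <- c("gcs", "heart_rate", "map", "resp_rate", "temp",
              "urine_output", "ventilated")
  medvit <- data.frame(
    index = seq_len(v[["med"]] + v[["vit"]]),
    name = c(sprintf("med%03d", seq_len(v[["med"]])),
             sprintf("vit%03d", seq_len(v[["vit"]]))),
    kind = c(rep("med", v[["med"]]), rep("vit", v[["vit"]])),
    vital_group = c(rep(NA_character_, v[["med"]]),
                    vitals[(seq_len(v[["vit"]]) - 1L) %% 7L + 1L]),
    stringsAsFactors = FALSE
  )
  list(dxproc = dxproc, medvit = medvit)
}

#' Assign patients to train/validation vs test splits
#'
#' A fixed fraction of patients (rounded to the nearest count) is sampled
#' into the test split; every stay of a patient shares the patient's
#' split.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param test_fraction Fraction of patients in the test split.
#' @param seed Integer seed.
#' @return Named character vector (`train_valid` / `test`) indexed by
#'   patient id.
#' @export
split_patients <- function(patient_ids, test_fraction = 0.10, seed = 1L) {
  patient_ids <- unique(patient_ids)
  set.seed(derive_seed(seed, 404L))
  n_test <- round(length(patient_ids) * test_fraction)
  test <- sample(patient_ids, n_test)
  out <- stats::setNames(rep("train_valid", length(patient_ids)), patient_ids)
  out[test] <- "test"
  out
}

#' Extract one stay record from a cohort
#'
#' @param cohort An `emr_cohort`.
#' @param stay_id Stay identifier.
#' @return A stay record list (`static`, `events_dxproc`, `events_medvit`,
#'   `label`, `patient_id`).
#' @export
get_stay <- function(cohort, stay_id) {
  i <- match(stay_id, cohort$stays$stay_id)
  if (is.na(i)) stop2("unknown stay_id: ", stay_id)
  list(
    patient_id = cohort$stays$patient_id[i],
    stay_id = stay_id,
    static = cohort$X[i, ],
    events_dxproc = cohort$events$dxproc[cohort$events$dxproc$stay_id == stay_id,
                                         c("code", "elapsed"), drop = FALSE],
    events_medvit = cohort$events$medvit[cohort$events$medvit$stay_id == stay_id,
                                         c("code", "elapsed"), drop = FALSE],
    label = cohort$stays$label[i]
  )
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("Synthetic EMR cohort:", nrow(x$stays), "stays,",
      length(unique(x$stays$patient_id)), "patients\n")
  if (nrow(x$stays)) {
    cat(sprintf("  prevalence: %.3f | test fraction (patients): %.3f\n",
                mean(x$stays$label),
                mean(tapply(x$stays$split, x$stays$patient_id, `[`, 1) == "test")))
    cat(sprintf("  events: %d dx/proc (days), %d med/vit (hours)\n",
                nrow(x$events$dxproc), nrow(x$events$medvit)))
  }
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Emits `stays.csv` (ids, label, split, raw static covariates),
#' `events_dxproc.csv` and `events_medvit.csv` (`stay_id`, `code`,
#' `elapsed`), `vocabulary.json` and, when present, `ground_truth.json`.
#' The same schema is produced by the MIMIC-style extractor.
#'
#' @param cohort An `emr_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$stays, file.path(dir, "stays.csv"))
  data.table::fwrite(cohort$events$dxproc, file.path(dir, "events_dxproc.csv"))
  data.table::fwrite(cohort$events$medvit, file.path(dir, "events_medvit.csv"))
  jsonlite::write_json(cohort$vocab, file.path(dir, "vocabulary.json"),
                       dataframe = "columns")
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(unclass(cohort$truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return An `emr_cohort` (without generator config; `truth` only if the
#'   ground-truth file is present).
#' @export
read_cohort <- function(dir) {
  stays <- as.data.frame(data.table::fread(file.path(dir, "stays.csv")))
  ev1 <- as.data.frame(data.table::fread(file.path(dir, "events_dxproc.csv")))
  ev2 <- as.data.frame(data.table::fread(file.path(dir, "events_medvit.csv")))
  vocab <- jsonlite::read_json(file.path(dir, "vocabulary.json"),
                               simplifyVector = TRUE)
  vocab <- lapply(vocab, as.data.frame)
  truth <- NULL
  tf <- file.path(dir, "ground_truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$beta_static <- unlist(truth$beta_static)
    class(truth) <- "emr_ground_truth"
  }
  X <- build_static_vector(stays)
  structure(list(stays = stays, X = X,
                 events = list(dxproc = ev1, medvit = ev2),
                 vocab = vocab, truth = truth, config = NULL),
            class = "emr_cohort")
}
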