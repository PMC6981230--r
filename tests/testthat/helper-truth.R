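# Minimal hand-built ground truths and stay records for oracle tests.

blank_truth <- function(V1 = 5, V2 = 4, b0 = 0) {
  sch <- static_schema()
  structure(list(
    b0 = b0,
    beta_static = stats::setNames(numeric(length(sch$columns)), sch$columns),
    beta_code = list(dxproc = numeric(V1), medvit = numeric(V2)),
    lambda = list(dxproc = numeric(V1), medvit = numeric(V2))
  ), class = "emr_ground_truth")
}

blank_stay <- function(dx = NULL, mv = NULL, static = NULL) {
  sch <- static_schema()
  x <- stats::setNames(numeric(length(sch$columns)), sch$columns)
  if (!is.null(static)) x[names(static)] <- static
  list(
    static = x,
    events_dxproc = dx %||% data.frame(code = integer(0), elapsed = numeric(0)),
    events_medvit = mv %||% data.frame(code = integer(0), elapsed = numeric(0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small cohort shared across model-level tests
small_cohort <- function(n_patients = 120, seed = 33) {
  generate_cohort(generator_config(
    n_patients = n_patients,
    vocab = c(dx = 15, proc = 5, med = 10, vit = 7),
    seq_len = list(dxproc = c(mean = 4, size = 4), medvit = c(mean = 4, size = 4)),
    prevalence = 0.2, seed = seed))
}

vocab_sizes <- function(cohort) {
  c(dxproc = nrow(cohort$vocab$dxproc), medvit = nrow(cohort$vocab$medvit))
}
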