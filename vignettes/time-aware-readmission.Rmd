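---
title: "Time-aware neural risk models for 30-day ICU readmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware neural risk models for 30-day ICU readmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

About one in ten patients discharged from an intensive care unit is
readmitted within 30 days. Predicting that risk from the electronic
medical record (EMR) is an irregular-time-series problem: the record is a
set of static covariates plus timestamped discrete codes — diagnoses and
procedures accumulated over years of clinical history (day-scale elapsed
times), and medications and vital-sign measurements from the index ICU
stay (hour-scale elapsed times). Codes differ in how long they stay
relevant: a chronic-disease diagnosis matters years later, a transient
vital-sign derangement may not matter next week. `icuread` implements a
benchmark family of neural architectures that differ only in how they
handle this temporal structure, together with a Bayesian treatment of the
most interpretable member of the family.

## Model family

Every deep model shares one scaffold:

1. **Embedding.** Each code is mapped to a learned vector. The embedding
   width per stream is `round(2 * V^(1/4))` for vocabulary size `V` — the
   fourth-root rule gives 12 dimensions at V = 1290 and 10 at V = 618,
   realistic EMR scales. Time enters the embedding stage in one of three
   ways: it is ignored (plain end-to-end embeddings, optionally pretrained
   as medical concept embeddings, MCE), the elapsed time is concatenated
   as an extra coordinate, or the embedding is *evolved* over elapsed time
   by a neural ordinary differential equation: the stored row is the
   embedding at the moment of ICU discharge (time zero), and the embedding
   of a code recorded `t` units earlier is the solution of an initial
   value problem `dy/ds = f(y)` integrated over `[0, t]` with the Euler
   method, where `f` is a multilayer perceptron with three hidden layers
   of width equal to the embedding.
2. **Sequence integration.** Either dot-product attention pools the
   embedded events directly into a context vector, or a bi-directional GRU
   consumes the sequence (state width equal to the embedding width) and is
   itself made time-aware by one of three mechanisms: concatenating the
   time gap between consecutive observations to the inputs, decaying the
   memory state as `h * exp(-softplus(w) * dt)` before each update, or
   evolving the memory state between observations with a neural ODE.
   Pooling uses either dot-product attention over the per-step outputs or
   the concatenated final memory states of the two directions.
3. **Scores and logistic layer.** A linear head reduces each stream's
   pooled vector to one scalar score; the two scores are concatenated with
   the 23 static covariates and passed through a final fully connected
   layer with a sigmoid. The output is the readmission risk, and the final
   layer's weights are log-odds increments exactly as in logistic
   regression.

Crossing these axes yields the 13 named deep architectures available from
`arch_names()`, plus a logistic-regression baseline over the static
covariates and the most recent code per monitored vital sign.

Because no deep-learning framework is assumed, the package ships a small
tape-based reverse-mode automatic differentiation engine (`R/autodiff.R`)
over plain R matrices; every gradient it produces is checked against
central finite differences in the test suite.

## Bayesian interpretation layer

For interpretation the `Attention(concat time)` model is trained with
Bayes by Backprop: a diagonal-Gaussian variational posterior per weight
(`sigma = softplus(rho)`), a scale-mixture prior of two zero-mean
Gaussians with standard deviations 1 and `e^-6` and mixture weight 0.5
(encouraging sparsity), one Monte-Carlo weight draw per minibatch, and the
KL complexity term scaled by `1/n_batches` so that exactly one KL is paid
per epoch. Training runs on the full data set — the goal is description,
not generalisation — and stops when the epoch loss has not decreased for
10 consecutive epochs.

From the fitted posterior the package reports odds ratios `exp(w)` for
every static covariate (posterior mean, with the median alongside, and
2.5/97.5-percentile credible intervals from posterior sampling; 10,000
samples by default) and a ranked table of per-code risk scores: passing a
single code through its stream's score head — the attention weight of a
singleton sequence is exactly 1 — gives the score that code contributes
on its own, and sampling weights gives its credible interval.

Two identifiability choices matter here. First, a stream's head and its
final-layer weight are only defined up to a joint sign flip, so fitted
models are canonicalised to a non-negative final-layer score weight
(`orient_scores()`); "higher score = higher risk" then holds by
construction, and predictions are unchanged. Second, odds ratios are
reported as the posterior mean of `exp(w)`; the median is included since
the lognormal mean is systematically larger.

## The synthetic cohort generator

Real ICU EMR data are credentialed-access, so the package is exercised on
synthetic cohorts with known ground truth. The generator emulates the
statistical features the architectures are designed to exploit:

* two code streams on different time scales: diagnosis/procedure events
  are a mixture of at-discharge codes (elapsed 0) and historical codes
  with exponentially distributed day-scale elapsed times up to a 5-year
  horizon; medication/vital events are uniform over the stay duration in
  hours;
* irregular sampling with negative-binomial sequence lengths;
* rare categories via a Zipf-like code frequency profile;
* time-decaying relevance: each code has a base effect `beta_c` (logit
  scale, spike-and-slab) and a decay rate `lambda_c`; a configurable
  chronic fraction has `lambda = 0` and the rest decay log-uniformly, so a
  stay's true risk is
  `sigmoid(b0 + x'beta_static + sum_events beta_c * exp(-lambda_c * t))`;
* a latent patient frailty (discretised to 40 levels so sampling stays
  vectorised) that tilts code sampling, making high-risk codes co-occur
  within sicker patients — the co-occurrence structure MCE pretraining
  feeds on;
* about 1.37 stays per patient, and a 12% target prevalence reached by
  calibrating the intercept `b0` with bisection against a Monte-Carlo
  cohort simulated under the same seed-derived stream.

The oracle risk is by construction the Bayes-optimal score for the
generated labels, which gives every discrimination test a ceiling to
compare against. What the generator does *not* emulate: ICD-9 hierarchy
and code semantics, informative observation timing (measurement times are
independent of severity), within-patient correlation of labels beyond
shared covariates, missingness mechanisms, and free-text. Passing tests
on synthetic cohorts therefore demonstrate that the machinery learns the
temporal structure it targets, not clinical-grade performance on real
records.

Static covariates mirror a realistic ICU schema (gender, age, ethnicity,
insurance, marital status, admission location, elective surgery, ICU and
pre-ICU lengths of stay, recent ICU admissions), one-hot encoded against
fixed reference groups (female / white / Medicare / married / emergency
admission) into 23 columns shared verbatim with the MIMIC-style extractor,
so synthetic and extracted cohorts are schema-compatible.

## Cohort extraction from MIMIC-style tables

`extract_mimic_cohort()` implements the cohort rules against MIMIC-III
v1.4 CSV schemas: exclusion of in-stay deaths, of patients under 18 at
ICU discharge (ages date-shifted above 89 are capped at 90), and of
deaths within 30 days of discharge without an intervening readmission;
30-day readmission labelling with an inclusive boundary (a gap of exactly
30.0 days counts) computed against *all* of a patient's ICU stays, since
a readmission that itself ends in death still makes the index stay
positive; diagnosis/procedure codes over the full clinical history
(elapsed days from the carrying hospital admission's discharge;
index-admission codes get elapsed 0, the simplifying availability
assumption); medications and vitals restricted to the index stay (elapsed
hours); OASIS-style binning of the seven monitored vitals with hard-coded
published cut-points; consecutive-duplicate removal keeping the latest
observation of a run; relabelling of values associated with fewer than
100 distinct stays as "other" (strictly fewer: 100 stays keep the value);
and a patient-level 90/10 split. Events with equal timestamps are ordered
by code index for determinism.

The source tables do not fix which CHARTEVENTS item ids define each
vital; `mimic_vital_items()` documents the package's choice (CareVue +
MetaVision ids, Fahrenheit conversion, MetaVision GCS as the per-charttime
sum of its three components, ventilation inferred from ventilator-mode
settings, urine output totalled per calendar day before binning). Any
later ICU stay row counts as a readmission candidate, including
transfers within one hospitalisation.

## Numerical choices

* **Time units inside the models.** Wherever a model consumes a time
  numerically — ODE integration horizons, the concatenated elapsed-time
  coordinate, concatenated time gaps — the value is divided by a
  per-stream scale (365 days for diagnoses/procedures, 24 hours for
  medications/vitals, configurable). Day-scale raw values of up to 1825
  would otherwise dominate attention logits and blow up Euler steps; the
  rescale expresses times in order-one units (years / days) without
  changing the architecture. The user-facing accessors keep the stream's
  native units.
* **Euler integration.** A fixed step count per solve (default 10,
  configurable) keeps batched solves rectangular; the dynamics MLP's
  output layer is initialised small so the initial flow is near zero and
  an untrained ODE model coincides with its static-embedding
  counterpart. On linear test
  dynamics the implementation shows the expected first-order behaviour:
  the global error halves when the step count doubles.
* **Attention.** Scores are scaled by `sqrt(width)` (numerically safer at
  the widths in use; switchable). Masked positions receive exactly zero
  weight; a stream with no events yields a zero context vector, so
  event-free stays are handled without special cases.
* **Time gaps.** Gaps between consecutive observations are recomputed per
  direction of the bi-GRU (the first processed step of each direction
  gets gap 0) and never straddle the padding boundary. The decay (exp or
  ODE) is applied to the previous memory state before the gate
  computations.
* **MCE.** Continuous bag-of-words with one attention scalar per (code,
  integer time-difference bucket clipped at ±365). The returned embedding
  is the average of the input- and output-side matrices, which reflects
  co-occurrence similarity more robustly than either side alone.
  Pretraining uses the training split only.
* **ODE direction.** The stored row is the time-zero (discharge)
  embedding and integration runs forward over the elapsed time, matching
  the initial-value formulation; the alternative backward reading is not
  used.
* **Stability.** Binary cross-entropy is computed from logits with a
  fused stable kernel; the scale-mixture log prior uses an elementwise
  log-sum-exp; softplus and sigmoid are tail-stable.
* **Determinism.** All randomness flows from one integer master seed
  through deterministic per-component seed derivation; two runs with the
  same seed produce byte-identical cohorts, weights and reports.
  Minibatch composition is fixed by one seeded shuffle, with the batch
  order reshuffled each epoch.

## Training protocol

Maximum-likelihood training uses Adam (batch size 128, learning rate
0.001), class weights `N_neg/N_pos` on the positive class, dropout with
50% probability after the embedding, RNN and attention layers, and a
fixed 80-epoch budget; validation average precision is logged per epoch
but does not stop training. The train/validation sub-split within the
90% development set is 8:1 by patient. Evaluation reports average
precision, AUROC, maximal F1 over thresholds, and sensitivity/specificity
at the threshold maximising Youden's J (ties toward higher sensitivity),
each with a 95% percentile bootstrap interval from 100 resamples drawn at
the patient level — patients, with all their stays, are resampled with
replacement, because stays of one patient are not independent events.

## Problem sizes in the test suite

The package's own test and acceptance runs use deliberately compact
cohorts so that the full suite executes on a single CPU in minutes; these
sizes are package choices, stated here for reproducibility:

* metric oracles: 200 random instances of up to 50 observations against
  brute-force enumeration, and 60 more in the unit tests;
* discrimination benchmark: 800 patients (≈1,100 stays, 25% test
  fraction) with compact vocabularies (dx 40, proc 12, med 24, vit 14),
  strong planted effects (oracle AUROC ≈ 0.94), sequences capped at the
  10 most recent events per stream, 6 training epochs at learning rate
  0.02 with 10% dropout, 2 Euler steps — every architecture must beat
  AUROC 0.70 and every deep architecture must beat the logistic baseline;
* Bayesian recovery: 4,000 patients (≈5,400 stays), planted static
  effects of |0.35|–|0.5| on the logit scale, continuous per-code effects
  (sd 0.8) with an 80% chronic fraction, Bayes by Backprop at learning
  rate 0.02 for up to 60 epochs (patience 10) — recovered odds ratios
  must match every planted sign at |effect| ≥ 0.3, and the posterior-mean
  code ranking must reach Spearman ≥ 0.8 against the planted effects;
* generator calibration: 20,000 patients for the ±0.02 prevalence check.

## Known limitations

* The autodiff engine favours clarity over speed; paper-scale training
  (45k stays, 80 epochs, 13 architectures) is out of desk scope, though
  nothing in the code limits cohort size.
* Attention pooling averages event contributions; additive accumulation
  of many weak risk factors is represented only through the learned
  weighting, which attenuates per-code effect recovery for strongly
  decaying codes.
* The MIMIC extractor covers the seven OASIS vitals only and makes its
  item-id choices explicit rather than exhaustive; CareVue/MetaVision
  harmonisation beyond those vitals, ICD-9 rollups and clinical notes are
  out of scope.
* Multi-head or key/value-separated attention, LSTM cells, Bayesian
  ensembles and calibration post-processing are intentionally not
  implemented.

## A minimal session

```{r, eval = FALSE}
library(icuread)

cfg <- generator_config(n_patients = 1000, seed = 1)
cohort <- generate_cohort(cfg)

vs <- c(dxproc = nrow(cohort$vocab$dxproc),
        medvit = nrow(cohort$vocab$medvit))
model <- build_model(arch_spec("RNN(exp time decay)+Attention",
                               dropout = 0.1, seed = 1), vs)
fit <- train_model(model, cohort,
                   train_config(epochs = 10, lr = 0.01, dropout = 0.1))
evaluate_model(fit, cohort, split = "test", n_boot = 100, seed = 1)

post <- fit_bbb(build_model(arch_spec("Attention(concat time)",
                                      dropout = 0, seed = 1), vs),
                cohort, bbb_config(lr = 0.02, max_epochs = 60))
odds_ratios(post)
code_risk_ranking(post, "dxproc", n_samples = 1000)
```
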