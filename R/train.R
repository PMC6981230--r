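# Maximum-likelihood training loop and model-level evaluation.

#' Training configuration
#'
#' Defaults follow the benchmark protocol: Adam with batch size 128 and
#' learning rate 0.001, 80 epochs with no early stopping (validation
#' average precision is logged each epoch but not used to stop), dropout
#' with 50% probability after embedding, RNN and attention layers, and
#' class weighting that scales the positive-class cost by N_neg/N_pos.
#'
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param epochs Number of epochs.
#' @param dropout Dropout probability in \[0, 1).
#' @param class_weighting Weight the minority class (default TRUE).
#' @param valid_fraction Fraction of training patients held out as the
#'   validation set (default 1/9, i.e. 10% of all patients when the test
#'   split holds 10%).
#' @param max_len Optional per-stream sequence-length cap (most recent
#'   events kept); `NULL` = no cap.
#' @param seed Integer seed controlling shuffling, dropout and the
#'   validation sub-split.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, lr = 0.001, epochs = 80L,
                         dropout = 0.5, class_weighting = TRUE,
                         valid_fraction = 1 / 9, max_len = NULL, seed = 1L) {
  if (batch_size < 1 || lr < 0 || epochs < 0) stop2("invalid training configuration")
  if (dropout < 0 || dropout >= 1) stop2("dropout must be in [0, 1)")
  structure(as.list(environment()), class = "train_config")
}

# pre-packed minibatches: one seeded shuffle fixes the batch composition,
# batch order is reshuffled every epoch
make_batches <- function(cohort, rows, batch_size, seed, max_len = NULL) {
  set.seed(derive_seed(seed, 601L))
  rows <- sample(rows)
  splits <- split(rows, ceiling(seq_along(rows) / batch_size))
  lapply(splits, function(rr) pack_stays(cohort, rr, max_len = max_len))
}

#' Train a risk model by maximum likelihood
#'
#' Minimises the (optionally class-weighted) log-loss with Adam for a
#' fixed number of epochs. The training split is sub-divided by patient
#' into train and validation parts; validation average precision is
#' recorded per epoch.
#'
#' @param model A `risk_model` from [build_model()].
#' @param cohort An `emr_cohort`; stays with split `"train_valid"` are
#'   used.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The fitted model, with a `history` data frame (epoch, mean
#'   train loss, validation average precision) attached.
#' @export
train_model <- function(model, cohort, config = train_config(),
                        verbose = FALSE) {
  rows <- which(cohort$stays$split == "train_valid")
  if (!length(rows)) stop2("no training stays in cohort")
  pats <- unique(cohort$stays$patient_id[rows])
  set.seed(derive_seed(config$seed, 602L))
  valid_pats <- sample(pats, round(length(pats) * config$valid_fraction))
  valid_rows <- rows[cohort$stays$patient_id[rows] %in% valid_pats]
  train_rows <- setdiff(rows, valid_rows)
  y_train <- cohort$stays$label[train_rows]
  wts <- c(1, 1)
  if (config$class_weighting && length(unique(y_train)) == 2L) {
    cw <- class_weights(y_train)
    wts <- c(cw[["negative"]], cw[["positive"]])
  }
  batches <- make_batches(cohort, train_rows, config$batch_size, config$seed,
                          max_len = config$max_len)
  valid_pack <- if (length(valid_rows))
    pack_stays(cohort, valid_rows, max_len = config$max_len) else NULL
  st <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_ap = numeric(0))
  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, 7000L + ep))
    ep_loss <- 0
    for (b in sample(seq_along(batches))) {
      batch <- batches[[b]]
      tape <- ad_tape()
      lv <- make_leaves(model, tape)
      fg <- forward_graph(model, batch, tape, lv, dropout = config$dropout)
      w <- ifelse(batch$y == 1, wts[2L], wts[1L])
      loss <- ad_bce_logits(tape, fg$logits, matrix(batch$y, ncol = 1L),
                            matrix(w, ncol = 1L), reduce = "mean")
      ad_backward(tape, loss)
      if (config$lr > 0) {
        grads <- lapply(lv[names(model$params)], function(nd) nd$grad)
        step <- adam_step(model$params, grads, st, lr = config$lr)
        model$params <- step$params
        st <- step$state
      }
      ep_loss <- ep_loss + ad_val(loss)[1L] * length(batch$y)
    }
    vap <- NA_real_
    if (!is.null(valid_pack) && length(unique(valid_pack$y)) == 2L) {
      pr <- predict_risk(model, valid_pack)
      vap <- average_precision(valid_pack$y, pr$risk)
    }
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / length(train_rows), valid_ap = vap))
    if (verbose) {
      message(sprintf("epoch %3d | loss %.4f | valid AP %s", ep,
                      ep_loss / length(train_rows),
                      ifelse(is.na(vap), "-", sprintf("%.3f", vap))))
    }
  }
  if (model$spec$name != "LogisticBaseline") {
    model$params <- orient_scores(model$params, model$meta$n_static)
  }
  model$history <- history
  model
}

#' Predict risks for a subset of cohort stays
#'
#' Evaluation-mode forward pass in memory-bounded chunks.
#'
#' @param model A `risk_model`.
#' @param cohort An `emr_cohort`.
#' @param rows Stay rows to score (default: all).
#' @param chunk Chunk size (default 256).
#' @param max_len Optional per-stream sequence-length cap.
#' @return Numeric risk per requested stay, in row order.
#' @export
predict_cohort <- function(model, cohort, rows = NULL, chunk = 256L,
                           max_len = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cohort$stays))
  parts <- split(rows, ceiling(seq_along(rows) / chunk))
  unlist(lapply(parts, function(rr) {
    predict_risk(model, pack_stays(cohort, rr, max_len = max_len))$risk
  }), use.names = FALSE)
}

#' Evaluate a model on a cohort split
#'
#' Scores the requested split and computes the full metric panel with
#' patient-level bootstrap confidence intervals.
#'
#' @param model A `risk_model`.
#' @param cohort An `emr_cohort`.
#' @param split `"test"` (default) or `"train_valid"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, cohort, split = "test", n_boot = 100,
                           seed = 1L) {
  rows <- which(cohort$stays$split == split)
  if (!length(rows)) stop2("no stays in split '", split, "'")
  risk <- predict_cohort(model, cohort, rows)
  evaluate_scores(cohort$stays$label[rows], risk,
                  cohort$stays$patient_id[rows], n_boot = n_boot, seed = seed)
}
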