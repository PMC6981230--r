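# Risk-model assembly: 13 deep architectures plus the logistic baseline
# behind one construction interface. Every deep architecture factorises
# into three orthogonal axes -- embedding time-handling (end-to-end, +time
# concat, neural-ODE dynamics, pretrained MCE), sequence integrator (none
# or bi-GRU with a time mechanism) and pooling (dot-product attention or
# final memory states) -- ending in two scalar stream scores that join the
# static covariates in a logistic output layer.

ARCH_TABLE <- list(
  "ODE+RNN+Attention"            = list(embed = "ode",        rnn = "plain", pool = "attention"),
  "ODE+RNN"                      = list(embed = "ode",        rnn = "plain", pool = "final"),
  "RNN(ODE time decay)+Attention" = list(embed = "plain",     rnn = "ode",   pool = "attention"),
  "RNN(ODE time decay)"          = list(embed = "plain",      rnn = "ode",   pool = "final"),
  "RNN(exp time decay)+Attention" = list(embed = "plain",     rnn = "exp",   pool = "attention"),
  "RNN(exp time decay)"          = list(embed = "plain",      rnn = "exp",   pool = "final"),
  "RNN(concat dt)+Attention"     = list(embed = "plain_dt",   rnn = "plain", pool = "attention"),
  "RNN(concat dt)"               = list(embed = "plain_dt",   rnn = "plain", pool = "final"),
  "ODE+Attention"                = list(embed = "ode",        rnn = "none",  pool = "attention"),
  "Attention(concat time)"       = list(embed = "plain_time", rnn = "none",  pool = "attention"),
  "MCE+RNN+Attention"            = list(embed = "mce",        rnn = "plain", pool = "attention"),
  "MCE+RNN"                      = list(embed = "mce",        rnn = "plain", pool = "final"),
  "MCE+Attention"                = list(embed = "mce",        rnn = "none",  pool = "attention"),
  "LogisticBaseline"             = list(embed = "none",       rnn = "none",  pool = "none")
)

#' Names of the available architectures
#'
#' @return Character vector of the 13 deep architectures plus
#'   `"LogisticBaseline"`.
#' @export
arch_names <- function() names(ARCH_TABLE)

#' Architecture specification
#'
#' @param name One of [arch_names()].
#' @param ode_steps Euler steps per neural-ODE solve (default 10).
#' @param ode_time_scale Named per-stream divisors applied to elapsed
#'   times / time gaps wherever the model consumes them numerically --
#'   ODE integration horizons, concatenated elapsed-time coordinates and
#'   concatenated time gaps (defaults: 365 days for diagnoses/procedures,
#'   24 hours for medications/vitals). Times are thus expressed in
#'   order-one units (years / days), which keeps Euler steps small and
#'   input coordinates on the scale of the embeddings.
#' @param dropout Dropout probability after embedding, RNN and attention
#'   layers during training (default 0.5).
#' @param scaled_attention Scale attention scores by `sqrt(width)`
#'   (default TRUE).
#' @param mce_finetune Update pretrained MCE matrices during supervised
#'   training (default FALSE: frozen).
#' @param seed Seed for weight initialisation.
#' @return Object of class `arch_spec`.
#' @export
arch_spec <- function(name, ode_steps = 10L, dropout = 0.5,
                      scaled_attention = TRUE, mce_finetune = FALSE,
                      ode_time_scale = c(dxproc = 365, medvit = 24),
                      seed = 1L) {
  if (!name %in% names(ARCH_TABLE)) {
    stop2("unknown architecture '", name, "'; valid names:\n  ",
          paste(names(ARCH_TABLE), collapse = "\n  "))
  }
  structure(c(list(name = name), ARCH_TABLE[[name]],
              list(ode_steps = as.integer(ode_steps), dropout = dropout,
                   scaled_attention = scaled_attention,
                   mce_finetune = mce_finetune,
                   ode_time_scale = ode_time_scale, seed = seed)),
            class = "arch_spec")
}

#' Build a risk model
#'
#' Initialises all parameters of the architecture for the given vocabulary
#' sizes and static-covariate width. Embedding dimensions follow the
#' fourth-root size rule per stream. The attention width equals the width
#' of the pooled representations (embedding width, +1 when elapsed time is
#' concatenated, or 2d over bi-GRU outputs).
#'
#' @param spec An [arch_spec()].
#' @param vocab_sizes Named counts `c(dxproc =, medvit =)`.
#' @param n_static Number of static covariates (default 23, the schema
#'   width).
#' @param mce Optional list of pretrained embedding matrices per stream
#'   (required for the MCE architectures).
#' @param n_vit Number of vital-sign codes at the end of the med/vit
#'   vocabulary (used by the logistic baseline's most-recent-vitals
#'   one-hot).
#' @return Object of class `risk_model` with elements `spec`, `params`
#'   (named list of matrices), `consts` (frozen matrices), `meta`.
#' @export
build_model <- function(spec, vocab_sizes, n_static = length(static_schema()$columns),
                        mce = NULL, n_vit = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  set.seed(derive_seed(spec$seed, 57L))
  params <- list()
  consts <- list()
  meta <- list(vocab_sizes = vocab_sizes, n_static = n_static, n_vit = n_vit)
  if (spec$name == "LogisticBaseline") {
    if (is.null(n_vit)) stop2("LogisticBaseline needs n_vit (vital-sign code count)")
    width <- n_static + vocab_sizes[["medvit"]]
    params$final.w <- init_zeros(width, 1L)
    params$final.b <- init_zeros(1L, 1L)
    meta$input_width <- width
    return(structure(list(spec = spec, params = params, consts = consts,
                          meta = meta), class = "risk_model"))
  }
  for (s in c("dxproc", "medvit")) {
    V <- vocab_sizes[[s]]
    d <- embedding_dim(V)
    meta[[paste0("d_", s)]] <- d
    if (spec$embed == "mce") {
      if (is.null(mce[[s]])) stop2("architecture '", spec$name,
                                   "' needs pretrained MCE matrices")
      if (!all(dim(mce[[s]]) == c(V, d))) {
        stop2("MCE matrix for ", s, " must be ", V, " x ", d)
      }
      if (spec$mce_finetune) {
        params[[paste0(s, ".E")]] <- unclass(mce[[s]])[, , drop = FALSE]
      } else {
        consts[[paste0(s, ".E")]] <- unclass(mce[[s]])[, , drop = FALSE]
      }
    } else {
      params[[paste0(s, ".E")]] <- matrix(stats::rnorm(V * d, 0, 0.1), V, d)
    }
    if (spec$embed == "ode") {
      dyn <- ode_dynamics(d, seed = derive_seed(spec$seed, 60L + match(s, c("dxproc", "medvit"))))
      for (nm in names(dyn)) params[[paste0(s, ".edyn.", nm)]] <- dyn[[nm]]
    }
    in_width <- d + as.integer(spec$embed == "plain_dt")
    pooled_width <- d + as.integer(spec$embed == "plain_time")
    if (spec$rnn != "none") {
      for (dir in c("f", "b")) {
        gp <- gru_params(in_width, d,
                         seed = derive_seed(spec$seed, 70L + match(s, c("dxproc", "medvit")) * 2L +
                                              as.integer(dir == "b")))
        for (nm in names(gp)) params[[paste0(s, ".rnn", dir, ".", nm)]] <- gp[[nm]]
        if (spec$rnn == "exp") {
          params[[paste0(s, ".decay.", dir)]] <- matrix(-2, 1L, d)
        }
      }
      if (spec$rnn == "ode") {
        dyn <- ode_dynamics(d, seed = derive_seed(spec$seed, 80L + match(s, c("dxproc", "medvit"))))
        for (nm in names(dyn)) params[[paste0(s, ".hdyn.", nm)]] <- dyn[[nm]]
      }
      pooled_width <- 2L * d
    }
    if (spec$pool == "attention") {
      ap <- attention_params(pooled_width,
                             seed = derive_seed(spec$seed, 90L + match(s, c("dxproc", "medvit"))))
      params[[paste0(s, ".att.K")]] <- ap$K
      params[[paste0(s, ".att.q")]] <- ap$q
    }
    params[[paste0(s, ".head.w")]] <- init_weight(pooled_width, 1L)
    params[[paste0(s, ".head.b")]] <- init_zeros(1L, 1L)
    meta[[paste0("pooled_", s)]] <- pooled_width
  }
  params$final.w <- init_zeros(n_static + 2L, 1L)
  params$final.b <- init_zeros(1L, 1L)
  structure(list(spec = spec, params = params, consts = consts, meta = meta),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("risk_model:", x$spec$name, "|", length(x$params), "parameter tensors,",
      np, "parameters\n")
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `risk_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

#' Canonicalise score orientation
#'
#' A stream's score head and its final-layer weight are only identified up
#' to a simultaneous sign flip. This flips each stream's head (weights and
#' bias) together with the corresponding final-layer entry so that the
#' final-layer weight on every stream score is non-negative: a high
#' per-code score then always means higher predicted risk, the orientation
#' assumed when interpreting score rankings. Predictions are unchanged.
#'
#' @param params Named parameter list of a deep `risk_model`.
#' @param n_static Number of static covariates.
#' @return The re-oriented parameter list.
#' @export
orient_scores <- function(params, n_static) {
  for (s in c("dxproc", "medvit")) {
    i <- n_static + match(s, c("dxproc", "medvit"))
    wn <- paste0(s, ".head.w")
    if (!is.null(params[[wn]]) && params$final.w[i, 1L] < 0) {
      params[[wn]] <- -params[[wn]]
      params[[paste0(s, ".head.b")]] <- -params[[paste0(s, ".head.b")]]
      params$final.w[i, 1L] <- -params$final.w[i, 1L]
    }
  }
  params
}

# ---- batch packing ----

#' Pack cohort stays into padded model batches
#'
#' Right-pads each stream's event sequences (code 0 = padding), keeps the
#' chronological order (oldest first), and precomputes the logistic
#' baseline's most-recent-vital one-hot block.
#'
#' @param cohort An `emr_cohort`.
#' @param rows Optional integer subset of stay rows.
#' @param max_len Optional cap on events per stream and stay; longer
#'   sequences keep their `max_len` most recent events.
#' @return List with `X`, `y`, `patient_id`, `stay_id`, per-stream
#'   `codes`/`elapsed`/`mask` matrices, and `Xbase` (statics +
#'   most-recent-vital one-hot).
#' @export
pack_stays <- function(cohort, rows = NULL, max_len = NULL) {
  stays <- cohort$stays
  if (is.null(rows)) rows <- seq_len(nrow(stays))
  ids <- stays$stay_id[rows]
  B <- length(ids)
  out <- list(X = cohort$X[rows, , drop = FALSE],
              y = stays$label[rows],
              patient_id = stays$patient_id[rows],
              stay_id = ids)
  for (s in c("dxproc", "medvit")) {
    ev <- cohort$events[[s]]
    ev <- ev[ev$stay_id %in% ids, , drop = FALSE]
    uids <- unique(ids)
    by_id <- split(seq_len(nrow(ev)), factor(ev$stay_id, levels = uids))
    idx <- by_id[match(ids, uids)]   # duplicates in a batch are allowed
    if (!is.null(max_len)) {
      # events are chronological (oldest first): keep the most recent tail
      idx <- lapply(idx, function(v) {
        if (length(v) > max_len) v[(length(v) - max_len + 1L):length(v)] else v
      })
    }
    L <- max(1L, max(vapply(idx, length, 0L)))
    codes <- matrix(0L, B, L)
    elapsed <- matrix(0, B, L)
    for (i in seq_len(B)) {
      take <- idx[[i]]
      if (length(take)) {
        codes[i, seq_along(take)] <- ev$code[take]
        elapsed[i, seq_along(take)] <- ev$elapsed[take]
      }
    }
    out[[s]] <- list(codes = codes, elapsed = elapsed,
                     mask = (codes > 0) * 1)
  }
  # logistic-baseline features: statics + one-hot of the most recent code
  # per vital sign
  Vmv <- nrow(cohort$vocab$medvit)
  onehot <- matrix(0, B, Vmv)
  vit_group <- cohort$vocab$medvit$vital_group
  ev <- cohort$events$medvit
  ev <- ev[ev$stay_id %in% ids & !is.na(vit_group[ev$code]), , drop = FALSE]
  if (nrow(ev)) {
    ev$grp <- vit_group[ev$code]
    ev$row <- match(ev$stay_id, ids)
    o <- order(ev$row, ev$grp, ev$elapsed)  # smallest elapsed = most recent
    ev <- ev[o, , drop = FALSE]
    first <- !duplicated(ev[, c("row", "grp")])
    sel <- ev[first, , drop = FALSE]
    onehot[cbind(sel$row, sel$code)] <- 1
  }
  out$Xbase <- cbind(out$X, onehot)
  out
}

# ---- forward pass ----

# Build the forward graph for one stream; returns the stream's scalar
# score node (B x 1). `lv` holds parameter nodes (or sampled weight nodes
# for the Bayesian layer) keyed like model$params/model$consts.
stream_score_graph <- function(tape, model, batch, s, lv, dropout = 0,
                               collect = NULL) {
  spec <- model$spec
  d <- model$meta[[paste0("d_", s)]]
  str <- batch[[s]]
  B <- nrow(str$codes); L <- ncol(str$codes)
  mask <- str$mask
  E <- lv[[paste0(s, ".E")]]
  drop_mask <- function(nr, nc) {
    if (dropout <= 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1, 1 - dropout) / (1 - dropout), nr, nc)
  }
  gaps <- time_gaps(str$elapsed, mask)
  embeds <- vector("list", L)
  for (t in seq_len(L)) {
    idx <- pmax(str$codes[, t], 1L)
    mcol <- matrix(mask[, t], ncol = 1L)
    X <- ad_mul(tape, ad_rows(tape, E, idx), mcol)
    if (spec$embed == "ode") {
      tcol <- matrix(str$elapsed[, t] * mask[, t] / spec$ode_time_scale[[s]],
                     ncol = 1L)
      dyn <- lv_prefix(lv, paste0(s, ".edyn."))
      X <- ad_euler(tape, X, tcol, dyn, spec$ode_steps)
      X <- ad_mul(tape, X, mcol)
    }
    dm <- drop_mask(B, d)
    if (!is.null(dm)) X <- ad_mul(tape, X, dm)
    embeds[[t]] <- X
  }
  if (spec$embed == "plain_time") {
    tsc0 <- spec$ode_time_scale[[s]]
    embeds <- lapply(seq_len(L), function(t) {
      ad_cbind(tape, list(embeds[[t]],
                          matrix(str$elapsed[, t] * mask[, t] / tsc0, ncol = 1L)))
    })
  }
  if (spec$rnn != "none") {
    mk_inputs <- function(gap) {
      if (spec$embed != "plain_dt") return(embeds)
      tsc0 <- spec$ode_time_scale[[s]]
      lapply(seq_len(L), function(t) {
        ad_cbind(tape, list(embeds[[t]],
                            matrix(gap[, t] * mask[, t] / tsc0, ncol = 1L)))
      })
    }
    mk_decay <- function(dir) {
      switch(spec$rnn,
        exp = list(type = "exp", rates = lv[[paste0(s, ".decay.", dir)]]),
        ode = list(type = "ode", dyn = lv_prefix(lv, paste0(s, ".hdyn.")),
                   n_steps = spec$ode_steps),
        list(type = "none"))
    }
    tsc <- spec$ode_time_scale[[s]]
    gf <- if (spec$rnn == "ode") gaps$fwd / tsc else gaps$fwd
    gb <- if (spec$rnn == "ode") gaps$bwd / tsc else gaps$bwd
    of <- ad_gru_dir(tape, mk_inputs(gaps$fwd), mask, gf,
                     lv_prefix(lv, paste0(s, ".rnnf.")), d, FALSE, mk_decay("f"))
    ob <- ad_gru_dir(tape, mk_inputs(gaps$bwd), mask, gb,
                     lv_prefix(lv, paste0(s, ".rnnb.")), d, TRUE, mk_decay("b"))
    steps <- lapply(seq_len(L), function(t) {
      o <- ad_cbind(tape, list(of[[t]], ob[[t]]))
      dm <- drop_mask(B, 2L * d)
      if (!is.null(dm)) o <- ad_mul(tape, o, dm)
      o
    })
    pooled_final <- ad_cbind(tape, list(of[[L]], ob[[1L]]))
  } else {
    steps <- embeds
    pooled_final <- NULL
  }
  if (spec$pool == "attention") {
    att <- ad_attention(tape, steps, mask,
                        lv[[paste0(s, ".att.K")]], lv[[paste0(s, ".att.q")]],
                        scaled = spec$scaled_attention)
    pooled <- att$context
    if (!is.null(collect)) collect$weights[[s]] <- ad_val(att$weights)
    dm <- drop_mask(B, ncol(ad_val(pooled)))
    if (!is.null(dm)) pooled <- ad_mul(tape, pooled, dm)
  } else {
    pooled <- pooled_final
  }
  ad_add(tape, ad_matmul(tape, pooled, lv[[paste0(s, ".head.w")]]),
         lv[[paste0(s, ".head.b")]])
}

lv_prefix <- function(lv, prefix) {
  nms <- names(lv)[startsWith(names(lv), prefix)]
  out <- lv[nms]
  names(out) <- substring(nms, nchar(prefix) + 1L)
  out
}

# full forward graph; returns logits node plus stream score nodes
forward_graph <- function(model, batch, tape, lv, dropout = 0) {
  spec <- model$spec
  if (spec$name == "LogisticBaseline") {
    logits <- ad_add(tape, ad_matmul(tape, batch$Xbase, lv$final.w), lv$final.b)
    return(list(logits = logits, scores = NULL))
  }
  s1 <- stream_score_graph(tape, model, batch, "dxproc", lv, dropout)
  s2 <- stream_score_graph(tape, model, batch, "medvit", lv, dropout)
  inp <- ad_cbind(tape, list(batch$X, s1, s2))
  logits <- ad_add(tape, ad_matmul(tape, inp, lv$final.w), lv$final.b)
  list(logits = logits, scores = list(dxproc = s1, medvit = s2))
}

make_leaves <- function(model, tape) {
  lv <- lapply(model$params, function(m) ad_leaf(tape, m))
  # frozen constants participate in the graph without gradients
  for (nm in names(model$consts)) lv[[nm]] <- model$consts[[nm]]
  lv
}

#' Predict readmission risk for a batch of stays
#'
#' Deterministic evaluation-mode forward pass (no dropout).
#'
#' @param model A fitted or freshly built `risk_model`.
#' @param batch A packed batch from [pack_stays()].
#' @return List with `risk` (per-stay probability in (0,1)), `logit`, and
#'   per-stream `scores` (NULL for the baseline).
#' @export
predict_risk <- function(model, batch) {
  tape <- ad_tape()
  lv <- make_leaves(model, tape)
  fg <- forward_graph(model, batch, tape, lv, dropout = 0)
  scores <- NULL
  if (!is.null(fg$scores)) {
    scores <- lapply(fg$scores, function(s) as.numeric(ad_val(s)))
  }
  list(risk = as.numeric(sigmoid(ad_val(fg$logits))),
       logit = as.numeric(ad_val(fg$logits)),
       scores = scores)
}

#' Score of a single code
#'
#' The scalar stream score that a length-1 sequence containing only the
#' given code (at the given elapsed time) would produce; the single
#' unmasked element receives attention weight exactly 1. High positive
#' scores mark codes whose presence in a patient's record pushes the
#' predicted readmission risk up (given a positive final-layer weight).
#'
#' @param model A `risk_model` (not the logistic baseline).
#' @param code Code index (may be a vector).
#' @param stream `"dxproc"` or `"medvit"`.
#' @param elapsed Elapsed time of the synthetic single event (default 0 =
#'   at discharge).
#' @return Numeric score per code.
#' @export
code_score <- function(model, code, stream = c("dxproc", "medvit"),
                       elapsed = 0) {
  stream <- match.arg(stream)
  if (model$spec$name == "LogisticBaseline") {
    stop2("code_score is not defined for the logistic baseline")
  }
  batch <- single_code_batch(model, code, stream, elapsed)
  tape <- ad_tape()
  lv <- make_leaves(model, tape)
  sc <- stream_score_graph(tape, model, batch, stream, lv, dropout = 0)
  as.numeric(ad_val(sc))
}

# batch of |codes| one-event stays in `stream`; the other stream is empty
single_code_batch <- function(model, codes, stream, elapsed = 0) {
  B <- length(codes)
  other <- setdiff(c("dxproc", "medvit"), stream)
  batch <- list(X = matrix(0, B, model$meta$n_static))
  batch[[stream]] <- list(codes = matrix(as.integer(codes), B, 1L),
                          elapsed = matrix(rep_len(elapsed, B), B, 1L),
                          mask = matrix(1, B, 1L))
  batch[[other]] <- list(codes = matrix(0L, B, 1L),
                         elapsed = matrix(0, B, 1L),
                         mask = matrix(0, B, 1L))
  batch
}
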