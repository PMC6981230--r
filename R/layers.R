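# Sequence-integration blocks: dot-product attention pooling, bi-directional
# GRUs with three time-handling mechanisms (concatenated time gaps,
# exponential memory decay, neural-ODE memory dynamics) and linear score
# heads. A single autodiff implementation serves both training and the
# numeric user-facing functions.

#' Parameters for dot-product attention
#'
#' A square key projection (the hidden width is left unchanged) and a
#' learned query vector.
#'
#' @param width Input width `d`.
#' @param seed Integer seed.
#' @return List with `K` (`d x d`) and `q` (`d x 1`).
#' @export
attention_params <- function(width, seed = 1L) {
  set.seed(derive_seed(seed, 41L))
  list(K = init_weight(width, width), q = init_weight(width, 1L))
}

#' Dot-product attention pooling
#'
#' Computes softmax weights over unmasked positions from the scaled
#' query-key scores `q . (K h_i) / sqrt(d)` and returns the weighted
#' average of the inputs. Masked positions receive exactly zero weight; an
#' all-masked input yields a zero context and zero weights.
#'
#' @param inputs `L x d` matrix of sequence elements.
#' @param mask Length-`L` 0/1 vector (default all ones).
#' @param params [attention_params()]; fresh ones are drawn if omitted.
#' @param scaled Divide scores by `sqrt(d)` (default TRUE).
#' @return List with `context` (length-`d` vector) and `weights`
#'   (length-`L`, summing to 1 over unmasked positions).
#' @export
dot_attention <- function(inputs, mask = NULL, params = NULL, scaled = TRUE) {
  inputs <- as_matrix(inputs)
  L <- nrow(inputs); d <- ncol(inputs)
  if (is.null(mask)) mask <- rep(1, L)
  if (is.null(params)) params <- attention_params(d)
  scores <- as.numeric(inputs %*% params$K %*% params$q)
  if (scaled) scores <- scores / sqrt(d)
  if (all(mask == 0)) {
    return(list(context = numeric(d), weights = numeric(L)))
  }
  x <- ifelse(mask > 0, scores, -Inf)
  e <- exp(x - max(x))
  w <- e / sum(e)
  list(context = as.numeric(crossprod(w, inputs)), weights = w)
}

#' Linear score head
#'
#' Affine map of a pooled representation to one scalar score; no
#' nonlinearity, so scores are directly interpretable as additive risk
#' contributions in the final logistic layer.
#'
#' @param x Input vector or matrix (rows = examples).
#' @param w Weight vector (length = input width).
#' @param b Bias scalar (default 0).
#' @return Scalar score per row.
#' @export
score_head <- function(x, w, b = 0) {
  as.numeric(as_matrix(x) %*% matrix(w, ncol = 1L) + b)
}

#' Exponential time decay of a memory state
#'
#' `h * exp(-softplus(w) * dt)`, applied elementwise; the softplus
#' transform keeps rates non-negative. Applied to the previous memory
#' state before each recurrent update.
#'
#' @param h State vector or matrix (rows = examples).
#' @param dt Non-negative time gap(s), scalar or one per row.
#' @param rates Unconstrained rate parameters (length = state width);
#'   effective rate is `softplus(rates)`.
#' @return Decayed state, same shape as `h`.
#' @export
decay_exp <- function(h, dt, rates) {
  h <- as_matrix(h)
  if (any(dt < 0)) stop2("time gaps must be non-negative")
  lam <- softplus(rates)
  fac <- exp(-outer(rep_len(as.numeric(dt), nrow(h)), lam))
  h * fac
}

#' Neural-ODE time decay of a memory state
#'
#' Euler-integrates `dh/ds = f(h)` over `[0, dt]`; with `dt = 0` or a zero
#' field the state is returned unchanged.
#'
#' @param h State vector or matrix.
#' @param dt Non-negative time gap(s).
#' @param dynamics An [ode_dynamics()].
#' @param n_steps Euler steps (default 10).
#' @return Evolved state.
#' @export
decay_ode <- function(h, dt, dynamics, n_steps = 10L) {
  ode_evolve(as_matrix(h), dt, dynamics, n_steps)
}

#' Parameters for one GRU direction
#'
#' Update/reset/candidate gates with state width `d` (equal to the input
#' embedding width, per the shared design of all recurrent variants) and
#' input width `input_dim` (d, or d+1 when time gaps are concatenated).
#'
#' @param input_dim Input width.
#' @param d State width.
#' @param seed Integer seed.
#' @return Named list of nine matrices.
#' @export
gru_params <- function(input_dim, d, seed = 1L) {
  set.seed(derive_seed(seed, 43L))
  list(Wz = init_weight(input_dim, d), Uz = init_weight(d, d), bz = init_zeros(1, d),
       Wr = init_weight(input_dim, d), Ur = init_weight(d, d), br = init_zeros(1, d),
       Wn = init_weight(input_dim, d), Un = init_weight(d, d), bn = init_zeros(1, d))
}

# ---- autodiff building blocks ----

# dynamics MLP forward on the tape; p = named list of nodes W1..b4
ad_dynamics <- function(tape, X, p) {
  a1 <- ad_tanh(tape, ad_add(tape, ad_matmul(tape, X, p$W1), p$b1))
  a2 <- ad_tanh(tape, ad_add(tape, ad_matmul(tape, a1, p$W2), p$b2))
  a3 <- ad_tanh(tape, ad_add(tape, ad_matmul(tape, a2, p$W3), p$b3))
  ad_add(tape, ad_matmul(tape, a3, p$W4), p$b4)
}

# Euler evolution of node X over per-row times t (constant column vector)
ad_euler <- function(tape, X, t, dyn, n_steps) {
  h <- matrix(as.numeric(t) / n_steps, ncol = 1L)
  Y <- X
  for (k in seq_len(n_steps)) {
    Y <- ad_add(tape, Y, ad_mul(tape, ad_dynamics(tape, Y, dyn), h))
  }
  Y
}

# one GRU direction over a list of per-step input nodes (B x in each).
# mask, dt: B x L constants. decay: list(type = "none"/"exp"/"ode",
# rates = node, dyn = node list, n_steps). Returns list of per-step state
# nodes (B x d); with right-padded sequences the state at the last
# processed step is the final state of the direction.
ad_gru_dir <- function(tape, inputs, mask, dt, p, d, reverse = FALSE,
                       decay = list(type = "none")) {
  L <- length(inputs)
  B <- nrow(ad_val(inputs[[1L]]))
  H <- matrix(0, B, d)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  out <- vector("list", L)
  for (t in steps) {
    mcol <- matrix(mask[, t], ncol = 1L)
    dcol <- matrix(pmax(dt[, t], 0), ncol = 1L)
    Hd <- H
    if (decay$type == "exp") {
      lam <- ad_softplus(tape, decay$rates)
      fac <- ad_exp(tape, ad_neg(tape, ad_matmul(tape, dcol, lam)))
      Hd <- ad_mul(tape, H, fac)
    } else if (decay$type == "ode") {
      Hd <- ad_euler(tape, H, dcol, decay$dyn, decay$n_steps)
    }
    x <- inputs[[t]]
    z <- ad_sigmoid(tape, ad_add(tape, ad_add(tape, ad_matmul(tape, x, p$Wz),
                                              ad_matmul(tape, Hd, p$Uz)), p$bz))
    r <- ad_sigmoid(tape, ad_add(tape, ad_add(tape, ad_matmul(tape, x, p$Wr),
                                              ad_matmul(tape, Hd, p$Ur)), p$br))
    n <- ad_tanh(tape, ad_add(tape, ad_add(tape, ad_matmul(tape, x, p$Wn),
                                           ad_mul(tape, r, ad_matmul(tape, Hd, p$Un))),
                              p$bn))
    onem <- ad_sub(tape, 1, z)
    Hnew <- ad_add(tape, ad_mul(tape, onem, n), ad_mul(tape, z, Hd))
    # masked (padded) steps carry the previous state unchanged
    H <- ad_add(tape, ad_mul(tape, Hnew, mcol), ad_mul(tape, H, 1 - mcol))
    out[[t]] <- H
  }
  out
}

# dot-product attention pooling on the tape over per-step nodes
ad_attention <- function(tape, steps, mask, K, q, scaled = TRUE) {
  width <- ncol(ad_val(steps[[1L]]))
  sc <- lapply(steps, function(s) {
    ad_matmul(tape, ad_matmul(tape, s, K), q)
  })
  S <- ad_cbind(tape, sc)
  if (scaled) S <- ad_scale(tape, S, 1 / sqrt(width))
  W <- ad_softmax_rows(tape, S, mask)
  ctx <- NULL
  for (t in seq_along(steps)) {
    term <- ad_mul(tape, steps[[t]], ad_col(tape, W, t))
    ctx <- if (is.null(ctx)) term else ad_add(tape, ctx, term)
  }
  list(context = ctx, weights = W)
}

#' Run a bi-directional GRU over a padded batch
#'
#' Numeric convenience wrapper around the training implementation: runs
#' both directions over right-padded sequences and returns per-step
#' outputs (forward and backward states concatenated) and the final states
#' of both directions. Time gaps between consecutive observations are
#' recomputed per direction and handled according to `variant`:
#' `"plain"` ignores them, `"concat_dt"` appends them to the inputs,
#' `"exp_decay"` decays the memory state exponentially, `"ode_decay"`
#' evolves it with a neural ODE.
#'
#' @param X Array-like: `L x in` matrix (single sequence) or list of
#'   per-step `B x in` matrices.
#' @param elapsed `B x L` (or length-`L`) elapsed times, decreasing along
#'   the sequence (oldest event first).
#' @param mask `B x L` (or length-`L`) 0/1 mask.
#' @param params_f,params_b [gru_params()] per direction.
#' @param variant One of `"plain"`, `"concat_dt"`, `"exp_decay"`,
#'   `"ode_decay"`.
#' @param rates_f,rates_b Decay-rate parameters (exp variant), length `d`.
#' @param dynamics An [ode_dynamics()] (ode variant), shared by both
#'   directions.
#' @param n_steps Euler steps for the ode variant.
#' @return List with `outputs` (`L`-list of `B x 2d` matrices) and
#'   `final` (`B x 2d` matrix: forward final, backward final).
#' @export
bi_gru <- function(X, elapsed, mask = NULL, params_f, params_b,
                   variant = c("plain", "concat_dt", "exp_decay", "ode_decay"),
                   rates_f = NULL, rates_b = NULL, dynamics = NULL,
                   n_steps = 10L) {
  variant <- match.arg(variant)
  if (is.matrix(X)) X <- lapply(seq_len(nrow(X)), function(i) X[i, , drop = FALSE])
  L <- length(X)
  B <- nrow(X[[1L]])
  elapsed <- if (is.matrix(elapsed)) elapsed else matrix(elapsed, B, L, byrow = B == 1L)
  if (is.null(mask)) mask <- matrix(1, B, L)
  mask <- if (is.matrix(mask)) mask else matrix(mask, B, L, byrow = B == 1L)
  d <- ncol(params_f$Uz)
  gaps <- time_gaps(elapsed, mask)
  tp <- ad_tape()
  inputs_f <- lapply(X, function(x) ad_leaf(tp, x))
  inputs_b <- inputs_f
  if (variant == "concat_dt") {
    inputs_f <- lapply(seq_len(L), function(t) {
      ad_cbind(tp, list(inputs_f[[t]], matrix(gaps$fwd[, t] * mask[, t], ncol = 1L)))
    })
    inputs_b <- lapply(seq_len(L), function(t) {
      ad_cbind(tp, list(inputs_b[[t]], matrix(gaps$bwd[, t] * mask[, t], ncol = 1L)))
    })
  }
  mk_decay <- function(rates) {
    switch(variant,
      exp_decay = list(type = "exp", rates = ad_leaf(tp, matrix(rates, 1L))),
      ode_decay = list(type = "ode",
                       dyn = lapply(dynamics, function(m) ad_leaf(tp, m)),
                       n_steps = n_steps),
      list(type = "none"))
  }
  pf <- lapply(params_f, function(m) ad_leaf(tp, m))
  pb <- lapply(params_b, function(m) ad_leaf(tp, m))
  of <- ad_gru_dir(tp, inputs_f, mask, gaps$fwd, pf, d, FALSE, mk_decay(rates_f))
  ob <- ad_gru_dir(tp, inputs_b, mask, gaps$bwd, pb, d, TRUE, mk_decay(rates_b))
  outputs <- lapply(seq_len(L), function(t) {
    cbind(ad_val(of[[t]]), ad_val(ob[[t]]))
  })
  final <- cbind(ad_val(of[[L]]), ad_val(ob[[1L]]))
  list(outputs = outputs, final = final)
}

# per-direction time gaps between consecutive observations. Sequences are
# sorted oldest first (elapsed decreasing); the first processed step of
# each direction gets gap 0, and gaps never look across the padding
# boundary.
time_gaps <- function(elapsed, mask) {
  B <- nrow(elapsed); L <- ncol(elapsed)
  fwd <- matrix(0, B, L)
  bwd <- matrix(0, B, L)
  if (L > 1L) {
    prev <- elapsed[, 1:(L - 1L), drop = FALSE]
    cur <- elapsed[, 2:L, drop = FALSE]
    fwd[, 2:L] <- pmax(prev - cur, 0) * mask[, 1:(L - 1L), drop = FALSE]
    bwd[, 1:(L - 1L)] <- pmax(prev - cur, 0) * mask[, 2:L, drop = FALSE]
  }
  list(fwd = fwd * mask, bwd = bwd * mask)
}
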