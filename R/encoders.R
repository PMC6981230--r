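# Code embeddings and their time dynamics.

#' Embedding dimension from vocabulary size
#'
#' The embedding size is proportional to the fourth root of the vocabulary
#' size; the proportionality constant is 2, which reproduces the dimensions
#' used for realistic EMR vocabularies (12 at V = 1290, 10 at V = 618).
#' Rounding is half-up for determinism.
#'
#' @param V Vocabulary size (>= 1).
#' @return Integer embedding dimension, at least 1.
#' @export
embedding_dim <- function(V) {
  if (any(V < 1)) stop2("vocabulary size must be >= 1")
  pmax(1L, as.integer(floor(2 * V^(1 / 4) + 0.5)))
}

#' Initialise an embedding matrix
#'
#' @param V Vocabulary size.
#' @param d Embedding dimension; defaults to [embedding_dim()] of `V`.
#' @param seed Integer seed.
#' @return `V x d` numeric matrix.
#' @export
new_embedding <- function(V, d = embedding_dim(V), seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  matrix(stats::rnorm(V * d, 0, 0.1), V, d)
}

#' Look up code embeddings
#'
#' Plain row lookup; index 0 denotes padding and maps to a zero vector.
#'
#' @param codes Integer code indices (0 = padding).
#' @param matrix Embedding matrix.
#' @return Matrix with one row per code.
#' @export
embed_codes <- function(codes, matrix) {
  out <- matrix(0, length(codes), ncol(matrix))
  live <- codes > 0
  if (any(codes > nrow(matrix))) stop2("code index out of vocabulary bounds")
  out[live, ] <- matrix[codes[live], , drop = FALSE]
  out
}

#' Append elapsed times as an extra coordinate
#'
#' @param vectors Matrix of embedded codes (one row per event).
#' @param elapsed Elapsed times, one per row (raw units: days or hours
#'   depending on the stream).
#' @param mask Optional 0/1 vector; masked rows get time 0.
#' @return Matrix with one additional final column holding the elapsed
#'   time.
#' @export
append_time <- function(vectors, elapsed, mask = NULL) {
  tcol <- as.numeric(elapsed)
  if (!is.null(mask)) tcol <- tcol * as.numeric(mask)
  cbind(vectors, tcol, deparse.level = 0)
}

#' Multilayer perceptron parameterising time dynamics
#'
#' The derivative field f: R^d -> R^d used for neural-ODE evolution of
#' embeddings or recurrent memory states: three hidden layers of constant
#' width `d` with tanh activations and a linear output layer. tanh keeps
#' derivatives bounded, stabilising long Euler integrations.
#'
#' @param d State width.
#' @param seed Integer seed.
#' @param out_scale Shrink factor on the output layer's initial weights
#'   (default 0.1): the initial flow starts close to zero, so an untrained
#'   model reduces to the static-embedding model and the dynamics are
#'   learned from there.
#' @return Named list of weight matrices/biases (class `ode_dynamics`).
#' @export
ode_dynamics <- function(d, seed = 1L, out_scale = 0.1) {
  set.seed(derive_seed(seed, 23L))
  p <- list(
    W1 = init_weight(d, d), b1 = init_zeros(1, d),
    W2 = init_weight(d, d), b2 = init_zeros(1, d),
    W3 = init_weight(d, d), b3 = init_zeros(1, d),
    W4 = init_weight(d, d) * out_scale, b4 = init_zeros(1, d)
  )
  class(p) <- "ode_dynamics"
  p
}

# numeric evaluation of the dynamics MLP on a matrix of states
dynamics_eval <- function(dyn, Y) {
  a1 <- tanh(sweep(Y %*% dyn$W1, 2, dyn$b1, "+"))
  a2 <- tanh(sweep(a1 %*% dyn$W2, 2, dyn$b2, "+"))
  a3 <- tanh(sweep(a2 %*% dyn$W3, 2, dyn$b3, "+"))
  sweep(a3 %*% dyn$W4, 2, dyn$b4, "+")
}

#' Evolve embeddings over elapsed time with a neural ODE
#'
#' Solves the initial value problem `dy/ds = f(y)`, `y(0) = y0` forward
#' over `[0, t]` with a fixed number of Euler steps. `y0` is the stored
#' time-zero embedding (the state at ICU discharge); the returned value is
#' the embedding of a code recorded `t` time units before discharge.
#'
#' @param y0 Matrix of initial states (one row per code occurrence).
#' @param t Elapsed times, scalar or one per row; must be >= 0.
#' @param dynamics An [ode_dynamics()] (or any function `f(Y)` returning
#'   `dY`).
#' @param n_steps Number of Euler steps over `[0, t]` (default 10).
#' @return Matrix of evolved states, same shape as `y0`.
#' @export
ode_evolve <- function(y0, t, dynamics, n_steps = 10L) {
  y0 <- as_matrix(y0)
  if (any(t < 0)) stop2("elapsed time must be non-negative")
  f <- if (is.function(dynamics)) dynamics else function(Y) dynamics_eval(dynamics, Y)
  h <- as.numeric(t) / n_steps
  Y <- y0
  for (k in seq_len(n_steps)) {
    Y <- Y + f(Y) * h   # h recycles per row when length(t) == nrow(y0)
  }
  Y
}

# ---- medical concept embeddings (MCE) with time-aware attention ----

mce_bucket <- function(dt, max_bucket = 365L) {
  pmin(max_bucket, pmax(-max_bucket, as.integer(round(dt)))) + max_bucket + 1L
}

#' Train medical concept embeddings with time-aware attention
#'
#' Unsupervised continuous bag-of-words pretraining of code embeddings in
#' which each context code's contribution to predicting the target code is
#' weighted by a learned attention value that depends on the (bucketed)
#' time difference between context and target. The temporal scope of a
#' code is therefore learned together with its embedding, rather than
#' imposed by a fixed context window. Time differences are bucketed at
#' integer resolution (in the stream's time unit) and clipped at +/-365,
#' with one attention scalar per (code, bucket).
#'
#' @param sequences List of data frames with columns `code` and `elapsed`
#'   (one per stay, any order).
#' @param V Vocabulary size.
#' @param d Embedding dimension (defaults to the size rule).
#' @param epochs Training epochs (default 5).
#' @param lr Adam learning rate.
#' @param max_targets_per_seq Targets subsampled per sequence per epoch.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return `V x d` embedding matrix: the average of the input-side and
#'   output-side matrices, which captures co-occurrence similarity more
#'   robustly than either side alone. The raw input/output matrices and
#'   the learned attention table are attached as attributes.
#' @export
mce_train <- function(sequences, V, d = embedding_dim(V), epochs = 5,
                      lr = 0.05, max_targets_per_seq = 10L, seed = 1L) {
  sequences <- Filter(function(s) nrow(s) >= 2, sequences)
  if (length(sequences) == 0) {
    stop2("mce_train: empty corpus (no sequence with >= 2 codes)")
  }
  set.seed(derive_seed(seed, 31L))
  nb <- 2L * 365L + 1L
  params <- list(
    Ein = matrix(stats::rnorm(V * d, 0, 0.1), V, d),
    Eout = matrix(stats::rnorm(V * d, 0, 0.1), V, d),
    A = matrix(0, V, nb)
  )
  st <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(sequences))
    for (si in ord) {
      sq <- sequences[[si]]
      n <- nrow(sq)
      tgts <- if (n <= max_targets_per_seq) seq_len(n) else
        sample.int(n, max_targets_per_seq)
      tp <- ad_tape()
      lv <- list(Ein = ad_leaf(tp, params$Ein),
                 Eout = ad_leaf(tp, params$Eout),
                 A = ad_leaf(tp, params$A))
      loss <- NULL
      for (i in tgts) {
        ctx <- setdiff(seq_len(n), i)
        cc <- sq$code[ctx]
        bk <- mce_bucket(sq$elapsed[ctx] - sq$elapsed[i])
        # attention over context positions: logit_j = A[code_j, bucket_j]
        arows <- ad_rows(tp, lv$A, cc)
        alog <- new_node_pick_row(tp, arows, bk)
        w <- ad_softmax_rows(tp, alog, matrix(1, 1, length(ctx)))
        H <- ad_matmul(tp, w, ad_rows(tp, lv$Ein, cc))
        logits <- ad_matmul(tp, H, t_node(tp, lv$Eout))
        tgt <- matrix(0, 1, V); tgt[sq$code[i]] <- 1
        lse <- ad_log(tp, ad_sum(tp, ad_exp(tp, logits)))
        li <- ad_sub(tp, lse, ad_sum(tp, ad_mul(tp, logits, tgt)))
        loss <- if (is.null(loss)) li else ad_add(tp, loss, li)
      }
      ad_backward(tp, loss)
      step <- adam_step(params,
                        list(Ein = lv$Ein$grad, Eout = lv$Eout$grad,
                             A = lv$A$grad),
                        st, lr = lr)
      params <- step$params
      st <- step$state
    }
  }
  out <- (params$Ein + params$Eout) / 2
  attr(out, "Ein") <- params$Ein
  attr(out, "Eout") <- params$Eout
  attr(out, "attention") <- params$A
  out
}

# gather one entry per row of `a` (row j, column idx[j]) into a 1 x m row
new_node_pick_row <- function(tape, a, idx) {
  va <- as_matrix(ad_val(a))
  keep <- cbind(seq_along(idx), idx)
  out <- new_node(tape, matrix(va[keep], 1L))
  if (is_adnode(a)) {
    out$backward <- function(g) {
      z <- matrix(0, nrow(va), ncol(va))
      z[keep] <- g
      ad_accum(a, z)
    }
  }
  out
}

t_node <- function(tape, a) {
  va <- as_matrix(ad_val(a))
  out <- new_node(tape, t(va))
  if (is_adnode(a)) out$backward <- function(g) ad_accum(a, t(g))
  out
}
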