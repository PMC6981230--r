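# Bayes by Backprop: mean-field variational inference over all network
# weights with a scale-mixture Gaussian prior, used to attach credible
# intervals to odds ratios and per-code risk scores.

#' Bayes-by-Backprop configuration
#'
#' The variational posterior is a diagonal Gaussian per weight
#' (parameterised by mean mu and pre-scale rho, sigma = softplus(rho));
#' the prior is a scale mixture of two zero-mean Gaussians with standard
#' deviations sigma1 = 1 and sigma2 = e^-6 and mixture weight pi = 0.5,
#' which encourages a priori sparsity of the weights. One Monte-Carlo
#' weight draw is used per minibatch step, and the KL complexity term is
#' scaled by 1/n_batches so it sums to exactly one KL per epoch. Training
#' stops when the epoch loss (the expected lower bound) has not decreased
#' for `patience` consecutive epochs.
#'
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience in epochs (default 10).
#' @param prior_pi Mixture weight of the broad component.
#' @param prior_s1,prior_s2 Prior standard deviations.
#' @param init_rho Initial pre-scale (sigma ~ softplus(init_rho)).
#' @param class_weighting Class-weight the likelihood (default TRUE).
#' @param dropout Dropout during variational training (default 0; the
#'   prior provides regularisation).
#' @param seed Integer seed.
#' @return Object of class `bbb_config`.
#' @export
bbb_config <- function(batch_size = 128L, lr = 0.001, max_epochs = 200L,
                       patience = 10L, prior_pi = 0.5, prior_s1 = 1,
                       prior_s2 = exp(-6), init_rho = -5,
                       class_weighting = TRUE, dropout = 0, seed = 1L) {
  structure(as.list(environment()), class = "bbb_config")
}

#' Draw one weight sample from a variational posterior
#'
#' `w = mu + softplus(rho) * eps` with standard-normal `eps`;
#' deterministic given the seed.
#'
#' @param posterior A `bbb_posterior`.
#' @param seed Integer seed.
#' @return Named list of weight matrices shaped like the model parameters.
#' @export
sample_weights <- function(posterior, seed = 1L) {
  set.seed(derive_seed(seed, 801L))
  out <- list()
  for (nm in names(posterior$mu)) {
    mu <- posterior$mu[[nm]]
    sg <- softplus(posterior$rho[[nm]])
    out[[nm]] <- mu + sg * matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  out
}

#' Log density of the scale-mixture prior
#'
#' `sum log( pi N(w; 0, s1^2) + (1-pi) N(w; 0, s2^2) )` over all weights,
#' evaluated with a numerically stable log-sum-exp.
#'
#' @param w Named list of weight matrices (or a single numeric array).
#' @param prior List with `pi`, `s1`, `s2` (defaults: 0.5, 1, e^-6).
#' @return Scalar log density.
#' @export
log_prior <- function(w, prior = list(pi = 0.5, s1 = 1, s2 = exp(-6))) {
  x <- unlist(w, use.names = FALSE)
  a <- log(prior$pi) - log(prior$s1) - 0.5 * (x / prior$s1)^2
  b <- log1p(-prior$pi) - log(prior$s2) - 0.5 * (x / prior$s2)^2
  m <- pmax(a, b)
  sum(m + log(exp(a - m) + exp(b - m))) - 0.5 * length(x) * log(2 * pi)
}

# log q(w | mu, sigma) of the diagonal Gaussian posterior
log_q <- function(w, mu, sigma) {
  x <- unlist(w, use.names = FALSE)
  m <- unlist(mu, use.names = FALSE)
  s <- unlist(sigma, use.names = FALSE)
  sum(stats::dnorm(x, m, s, log = TRUE))
}

# Build sampled-weight nodes for every parameter; returns list(lv = nodes
# usable by forward_graph, mu = mu leaves, rho = rho leaves, kl = KL node)
bbb_sample_graph <- function(tape, template, mu, rho, prior) {
  lv <- list(); mun <- list(); rhon <- list()
  logq <- NULL; logp <- NULL
  for (nm in names(mu)) {
    mnode <- ad_leaf(tape, mu[[nm]])
    rnode <- ad_leaf(tape, rho[[nm]])
    sg <- ad_softplus(tape, rnode)
    eps <- matrix(stats::rnorm(length(mu[[nm]])), nrow(mu[[nm]]), ncol(mu[[nm]]))
    w <- ad_add(tape, mnode, ad_mul(tape, sg, eps))
    lv[[nm]] <- w; mun[[nm]] <- mnode; rhon[[nm]] <- rnode
    # log q(w): -sum log sigma - 0.5 sum ((w-mu)/sigma)^2 - n/2 log(2 pi)
    dif <- ad_sub(tape, w, mnode)
    t1 <- ad_sum(tape, ad_log(tape, sg))
    t2 <- ad_scale(tape, ad_sum(tape, ad_square(tape, ad_div(tape, dif, sg))), 0.5)
    const_q <- -0.5 * length(mu[[nm]]) * log(2 * pi)
    lq <- ad_add(tape, ad_neg(tape, ad_add(tape, t1, t2)), matrix(const_q, 1, 1))
    # log p(w): scale-mixture via elementwise log-sum-exp
    ca <- log(prior$pi) - log(prior$s1)
    cb <- log1p(-prior$pi) - log(prior$s2)
    wa <- ad_add(tape, ad_scale(tape, ad_square(tape, ad_scale(tape, w, 1 / prior$s1)), -0.5),
                 matrix(ca, 1, 1))
    wb <- ad_add(tape, ad_scale(tape, ad_square(tape, ad_scale(tape, w, 1 / prior$s2)), -0.5),
                 matrix(cb, 1, 1))
    mx <- ad_pmax2(tape, wa, wb)
    lse <- ad_add(tape, mx, ad_log(tape, ad_add(tape,
                  ad_exp(tape, ad_sub(tape, wa, mx)),
                  ad_exp(tape, ad_sub(tape, wb, mx)))))
    const_p <- -0.5 * length(mu[[nm]]) * log(2 * pi)
    lp <- ad_add(tape, ad_sum(tape, lse), matrix(const_p, 1, 1))
    logq <- if (is.null(logq)) lq else ad_add(tape, logq, lq)
    logp <- if (is.null(logp)) lp else ad_add(tape, logp, lp)
  }
  for (nm in names(template$consts)) lv[[nm]] <- template$consts[[nm]]
  list(lv = lv, mu = mun, rho = rhon, kl = ad_sub(tape, logq, logp))
}

#' Evidence-lower-bound loss for one minibatch
#'
#' `(log q(w) - log p(w)) / n_batches + sum of class-weighted negative
#' log-likelihood over the batch`, with a single Monte-Carlo weight draw.
#' This is the quantity minimised by [fit_bbb()].
#'
#' @param posterior A `bbb_posterior` (or the in-training state).
#' @param batch A packed batch from [pack_stays()].
#' @param n_batches Number of minibatches per epoch (scales the complexity
#'   term).
#' @param seed Seed for the weight draw.
#' @param weights Length-2 class weights `c(negative, positive)`.
#' @return Scalar loss value.
#' @export
elbo_loss <- function(posterior, batch, n_batches = 1L, seed = 1L,
                      weights = c(1, 1)) {
  set.seed(derive_seed(seed, 811L))
  tape <- ad_tape()
  sg <- bbb_sample_graph(tape, posterior$template, posterior$mu,
                         posterior$rho, posterior$prior)
  fg <- forward_graph(posterior$template, batch, tape, sg$lv, dropout = 0)
  w <- ifelse(batch$y == 1, weights[2L], weights[1L])
  nll <- ad_bce_logits(tape, fg$logits, matrix(batch$y, ncol = 1L),
                       matrix(w, ncol = 1L), reduce = "sum")
  loss <- ad_add(tape, ad_scale(tape, sg$kl, 1 / n_batches), nll)
  ad_val(loss)[1L]
}

#' Fit a variational posterior with Bayes by Backprop
#'
#' Trains the given architecture on the entire cohort (train and test
#' pooled, as appropriate for a descriptive interpretation model),
#' minimising the ELBO loss with Adam, one weight draw per minibatch, and
#' stopping when the epoch loss has not decreased for `patience`
#' consecutive epochs.
#'
#' @param model A `risk_model` defining architecture and initial means
#'   (typically `Attention(concat time)`).
#' @param cohort An `emr_cohort`.
#' @param config A [bbb_config()].
#' @param rows Stay rows to train on (default: all stays).
#' @param verbose Print per-epoch progress.
#' @return Object of class `bbb_posterior`: `template` (the model),
#'   `mu`, `rho` (named lists), `prior`, `history`, `static_cols`.
#' @export
fit_bbb <- function(model, cohort, config = bbb_config(), rows = NULL,
                    verbose = FALSE) {
  if (is.null(rows)) rows <- seq_len(nrow(cohort$stays))
  y <- cohort$stays$label[rows]
  wts <- c(1, 1)
  if (config$class_weighting && length(unique(y)) == 2L) {
    cw <- class_weights(y)
    wts <- c(cw[["negative"]], cw[["positive"]])
  }
  prior <- list(pi = config$prior_pi, s1 = config$prior_s1, s2 = config$prior_s2)
  mu <- model$params
  rho <- lapply(mu, function(m) matrix(config$init_rho, nrow(m), ncol(m)))
  vp <- c(stats::setNames(mu, paste0("mu.", names(mu))),
          stats::setNames(rho, paste0("rho.", names(rho))))
  st <- adam_init(vp)
  batches <- make_batches(cohort, rows, config$batch_size, config$seed)
  nb <- length(batches)
  history <- numeric(0)
  best <- Inf; stale <- 0L
  for (ep in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, 9000L + ep))
    ep_loss <- 0
    for (b in sample(nb)) {
      batch <- batches[[b]]
      tape <- ad_tape()
      sg <- bbb_sample_graph(tape, model, mu, rho, prior)
      fg <- forward_graph(model, batch, tape, sg$lv, dropout = config$dropout)
      w <- ifelse(batch$y == 1, wts[2L], wts[1L])
      nll <- ad_bce_logits(tape, fg$logits, matrix(batch$y, ncol = 1L),
                           matrix(w, ncol = 1L), reduce = "sum")
      loss <- ad_add(tape, ad_scale(tape, sg$kl, 1 / nb), nll)
      if (!is.finite(ad_val(loss)[1L])) {
        stop2("Bayes-by-Backprop diverged (non-finite loss) at epoch ", ep)
      }
      ad_backward(tape, loss)
      grads <- c(
        stats::setNames(lapply(names(mu), function(nm) sg$mu[[nm]]$grad),
                        paste0("mu.", names(mu))),
        stats::setNames(lapply(names(mu), function(nm) sg$rho[[nm]]$grad),
                        paste0("rho.", names(mu)))
      )
      vp <- c(stats::setNames(mu, paste0("mu.", names(mu))),
              stats::setNames(rho, paste0("rho.", names(rho))))
      step <- adam_step(vp, grads, st, lr = config$lr)
      st <- step$state
      mu <- stats::setNames(step$params[paste0("mu.", names(mu))], names(mu))
      rho <- stats::setNames(step$params[paste0("rho.", names(rho))], names(rho))
      ep_loss <- ep_loss + ad_val(loss)[1L]
    }
    history <- c(history, ep_loss)
    if (verbose) message(sprintf("bbb epoch %3d | elbo loss %.2f", ep, ep_loss))
    if (ep_loss < best - 1e-8) {
      best <- ep_loss; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  if (model$spec$name != "LogisticBaseline") {
    mu <- orient_scores(mu, model$meta$n_static)
  }
  structure(list(template = model, mu = mu, rho = rho, prior = prior,
                 history = history, config = config,
                 static_cols = colnames(cohort$X)),
            class = "bbb_posterior")
}

#' @export
print.bbb_posterior <- function(x, ...) {
  cat("bbb_posterior over", x$template$spec$name, "|",
      sum(vapply(x$mu, length, 0L)), "weights |",
      length(x$history), "epochs\n")
  invisible(x)
}

#' Posterior odds ratios for the final-layer covariates
#'
#' The final fully connected layer acts on the static covariates and the
#' two stream scores, so its weights are increases in log-odds per unit
#' covariate increase, as in logistic regression. Each weight's posterior
#' is Gaussian, hence `exp(w)` is summarised over posterior samples by its
#' mean (median alongside) and 2.5/97.5 percentile credible bounds.
#'
#' @param posterior A `bbb_posterior`.
#' @param n_samples Posterior draws (default 10000).
#' @param seed Integer seed.
#' @return Data frame with `covariate`, `or` (posterior mean of exp(w)),
#'   `or_median`, `lower`, `upper`.
#' @export
odds_ratios <- function(posterior, n_samples = 10000L, seed = 1L) {
  mu <- posterior$mu$final.w
  sg <- softplus(posterior$rho$final.w)
  nms <- c(posterior$static_cols,
           if (posterior$template$spec$name != "LogisticBaseline")
             c("score_dxproc", "score_medvit"))
  if (length(nms) != nrow(mu)) nms <- paste0("w", seq_len(nrow(mu)))
  set.seed(derive_seed(seed, 821L))
  out <- lapply(seq_len(nrow(mu)), function(i) {
    draws <- exp(stats::rnorm(n_samples, mu[i, 1L], sg[i, 1L]))
    data.frame(covariate = nms[i], or = mean(draws),
               or_median = stats::median(draws),
               lower = unname(stats::quantile(draws, 0.025)),
               upper = unname(stats::quantile(draws, 0.975)))
  })
  do.call(rbind, out)
}

#' Posterior per-code risk scores, ranked
#'
#' Evaluates [code_score()] for every code in a stream under repeatedly
#' sampled network weights and reports each code's posterior mean score
#' with a 95% credible interval, sorted in decreasing order of mean score.
#' The higher the score, the higher the predicted readmission risk when a
#' patient's record contains that code.
#'
#' @param posterior A `bbb_posterior`.
#' @param stream `"dxproc"` or `"medvit"`.
#' @param n_samples Posterior draws (default 10000; per draw one forward
#'   pass over the whole vocabulary).
#' @param seed Integer seed.
#' @param elapsed Elapsed time of the probe event (default 0 = at
#'   discharge).
#' @return Data frame with `code`, `score` (posterior mean), `lower`,
#'   `upper`, sorted by decreasing score.
#' @export
code_risk_ranking <- function(posterior, stream = c("dxproc", "medvit"),
                              n_samples = 10000L, seed = 1L, elapsed = 0) {
  stream <- match.arg(stream)
  V <- posterior$template$meta$vocab_sizes[[stream]]
  model <- posterior$template
  draws <- matrix(NA_real_, n_samples, V)
  for (si in seq_len(n_samples)) {
    ws <- sample_weights(posterior, seed = derive_seed(seed, 830L + si))
    model$params <- ws
    draws[si, ] <- code_score(model, seq_len(V), stream, elapsed)
  }
  out <- data.frame(
    code = seq_len(V),
    score = colMeans(draws),
    lower = apply(draws, 2L, stats::quantile, 0.025),
    upper = apply(draws, 2L, stats::quantile, 0.975)
  )
  out[order(-out$score), ]
}
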