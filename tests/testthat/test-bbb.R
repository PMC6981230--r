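# helper: a hand-made posterior over a logistic-baseline template
toy_posterior <- function(mu_w, rho = -40, n_vit = 2, V2 = 2) {
  vs <- c(dxproc = 3, medvit = V2)
  m <- build_model(arch_spec("LogisticBaseline", seed = 1), vs, n_vit = n_vit)
  mu <- m$params
  mu$final.w[] <- rep_len(mu_w, nrow(mu$final.w))
  rho_l <- lapply(mu, function(x) matrix(rho, nrow(x), ncol(x)))
  structure(list(template = m, mu = mu, rho = rho_l,
                 prior = list(pi = 0.5, s1 = 1, s2 = exp(-6)),
                 history = numeric(0), config = bbb_config(),
                 static_cols = static_schema()$columns),
            class = "bbb_posterior")
}

test_that("weight sampling follows the reparameterisation exactly", {
  p <- toy_posterior(0.3, rho = -40)     # sigma ~ 4e-18: degenerate
  w1 <- sample_weights(p, seed = 5)
  expect_equal(w1$final.w, p$mu$final.w, tolerance = 1e-12)
  p2 <- toy_posterior(0, rho = 0)        # sigma = log(2)
  wa <- sample_weights(p2, seed = 5)
  wb <- sample_weights(p2, seed = 5)
  expect_identical(wa, wb)
  wc <- sample_weights(p2, seed = 6)
  expect_false(identical(wa, wc))
  # CLT: mean of many draws concentrates on mu
  draws <- vapply(1:3000, function(s) sample_weights(p2, seed = s)$final.b[1, 1], 0)
  sg <- softplus(0)
  expect_lt(abs(mean(draws)), 4 * sg / sqrt(3000))
})

test_that("the scale-mixture log prior is symmetric, stable and exact", {
  w <- list(a = matrix(c(0.5, -1.2), 1), b = matrix(0.01, 1, 1))
  wn <- lapply(w, function(x) -x)
  expect_equal(log_prior(w), log_prior(wn), tolerance = 1e-12)
  # pi = 1 reduces to a standard Gaussian log density
  x <- c(-2, 0, 1.3)
  expect_equal(log_prior(list(matrix(x, 1)), list(pi = 1 - 1e-16, s1 = 1, s2 = exp(-6))),
               sum(dnorm(x, log = TRUE)), tolerance = 1e-6)
  # w = 0 against direct evaluation of the mixture density
  direct <- log(0.5 * dnorm(0, 0, 1) + 0.5 * dnorm(0, 0, exp(-6)))
  expect_equal(log_prior(list(matrix(0, 1, 1))), direct, tolerance = 1e-10)
  # extreme values do not overflow
  expect_true(is.finite(log_prior(list(matrix(c(-50, 50), 1)))))
})

test_that("elbo_loss equals an independent recomputation on a tiny model", {
  set.seed(77)
  p <- toy_posterior(0.2, rho = -1, n_vit = 2, V2 = 2)
  n_static <- p$template$meta$n_static
  width <- n_static + 2
  batch <- list(Xbase = cbind(matrix(rnorm(3 * n_static), 3), matrix(0, 3, 2)),
                y = c(1, 0, 1))
  got <- elbo_loss(p, batch, n_batches = 4, seed = 9, weights = c(1, 2))
  # independent recomputation with the same derived RNG stream
  set.seed(icuread:::derive_seed(9, 811L))
  ws <- list(); lq <- 0; lp <- 0
  for (nm in names(p$mu)) {
    sg <- softplus(p$rho[[nm]])
    eps <- matrix(rnorm(length(p$mu[[nm]])), nrow(p$mu[[nm]]))
    ws[[nm]] <- p$mu[[nm]] + sg * eps
    lq <- lq + sum(dnorm(ws[[nm]], p$mu[[nm]], sg, log = TRUE))
    lp <- lp + log_prior(list(ws[[nm]]), p$prior)
  }
  l <- batch$Xbase %*% ws$final.w + ws$final.b[1, 1]
  wcl <- ifelse(batch$y == 1, 2, 1)
  nll <- sum(wcl * (softplus(l) - batch$y * l))
  expect_equal(got, (lq - lp) / 4 + nll, tolerance = 1e-8)
  # doubling n_batches halves the complexity term
  g2 <- elbo_loss(p, batch, n_batches = 8, seed = 9, weights = c(1, 2))
  expect_equal(got - g2, (lq - lp) / 8, tolerance = 1e-8)
})

test_that("odds ratios summarise the exponentiated posterior correctly", {
  p0 <- toy_posterior(0, rho = -40)
  or0 <- odds_ratios(p0, n_samples = 500, seed = 2)
  expect_true(all(abs(or0$or - 1) < 1e-10))
  expect_true(all(abs(or0$lower - 1) < 1e-10 & abs(or0$upper - 1) < 1e-10))
  p1 <- toy_posterior(log(2), rho = -40)
  expect_true(all(abs(odds_ratios(p1, n_samples = 100, seed = 2)$or - 2) < 1e-9))
  # mu = 0, sigma = 0.1: 95% interval ~ exp(+/- 1.96 * 0.1)
  p2 <- toy_posterior(0, rho = log(exp(0.1) - 1))
  or2 <- odds_ratios(p2, n_samples = 20000, seed = 3)
  expect_equal(or2$lower[1], exp(-1.96 * 0.1), tolerance = 0.02)
  expect_equal(or2$upper[1], exp(1.96 * 0.1), tolerance = 0.02)
  expect_equal(or2$or_median[1], 1, tolerance = 0.01)
})

test_that("degenerate posteriors give identical scores and vanishing intervals", {
  vs <- c(dxproc = 6, medvit = 4)
  m <- build_model(arch_spec("Attention(concat time)", seed = 3), vs)
  m$params$dxproc.E[2, ] <- m$params$dxproc.E[1, ]   # identical rows
  mu <- m$params
  rho <- lapply(mu, function(x) matrix(-40, nrow(x), ncol(x)))
  post <- structure(list(template = m, mu = mu, rho = rho,
                         prior = list(pi = 0.5, s1 = 1, s2 = exp(-6)),
                         history = numeric(0), config = bbb_config(),
                         static_cols = static_schema()$columns),
                    class = "bbb_posterior")
  rk <- code_risk_ranking(post, "dxproc", n_samples = 30, seed = 4)
  rk <- rk[order(rk$code), ]
  expect_equal(rk$score[1], rk$score[2], tolerance = 1e-10)
  expect_true(all(rk$upper - rk$lower < 1e-9))
  # widening sigma widens the intervals
  post2 <- post
  post2$rho <- lapply(mu, function(x) matrix(0, nrow(x), ncol(x)))
  rk2 <- code_risk_ranking(post2, "dxproc", n_samples = 30, seed = 4)
  expect_gt(mean(rk2$upper - rk2$lower), 0.01)
})

test_that("fit_bbb recovers the coefficients of a toy logistic problem", {
  sch <- static_schema()
  n <- 2500
  set.seed(12)
  beta <- c(gender_male = 1.0, elective_surgery = -0.8)
  X <- matrix(0, n, length(sch$columns), dimnames = list(NULL, sch$columns))
  X[, "gender_male"] <- rbinom(n, 1, 0.5)
  X[, "elective_surgery"] <- rbinom(n, 1, 0.4)
  eta <- X[, names(beta)] %*% beta
  y <- rbinom(n, 1, plogis(eta))
  cohort <- list(
    stays = data.frame(patient_id = sprintf("p%d", seq_len(n)),
                       stay_id = sprintf("s%d", seq_len(n)),
                       label = y, split = "train_valid"),
    X = X,
    events = list(dxproc = data.frame(stay_id = character(0), code = integer(0),
                                      elapsed = numeric(0)),
                  medvit = data.frame(stay_id = character(0), code = integer(0),
                                      elapsed = numeric(0))),
    vocab = list(dxproc = data.frame(index = 1, name = "dx", kind = "dx",
                                     vital_group = NA),
                 medvit = data.frame(index = 1, name = "vit", kind = "vit",
                                     vital_group = "gcs")))
  class(cohort) <- "emr_cohort"
  m <- build_model(arch_spec("LogisticBaseline", seed = 2),
                   c(dxproc = 1, medvit = 1), n_vit = 1)
  post <- fit_bbb(m, cohort,
                  bbb_config(lr = 0.05, batch_size = 256, max_epochs = 60,
                             patience = 10, class_weighting = FALSE, seed = 2))
  w <- post$mu$final.w[, 1]
  names(w) <- c(sch$columns, "vit1")
  expect_lt(abs(w["gender_male"] - 1.0), 0.3)
  expect_lt(abs(w["elective_surgery"] + 0.8), 0.3)
  # when stopped by patience the history is at least patience + 1 long
  if (length(post$history) < 60) expect_gte(length(post$history), 11)
  # seed reproducibility
  post2 <- fit_bbb(m, cohort,
                   bbb_config(lr = 0.05, batch_size = 256, max_epochs = 5,
                              patience = 10, class_weighting = FALSE, seed = 2))
  post3 <- fit_bbb(m, cohort,
                   bbb_config(lr = 0.05, batch_size = 256, max_epochs = 5,
                              patience = 10, class_weighting = FALSE, seed = 2))
  expect_equal(post2$mu$final.w, post3$mu$final.w, tolerance = 1e-12)
})
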