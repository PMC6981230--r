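test_that("all 14 architectures build and share one prediction contract", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  mce <- list(dxproc = new_embedding(vs[["dxproc"]], seed = 2),
              medvit = new_embedding(vs[["medvit"]], seed = 3))
  batch <- pack_stays(co, 1:10)
  for (nm in arch_names()) {
    m <- build_model(arch_spec(nm, ode_steps = 2, seed = 4), vs,
                     mce = mce, n_vit = sum(co$vocab$medvit$kind == "vit"))
    pr <- predict_risk(m, batch)
    expect_length(pr$risk, 10)
    expect_true(all(pr$risk > 0 & pr$risk < 1), info = nm)
    # a freshly built model has a zero final layer: risk exactly 0.5
    expect_equal(pr$risk, rep(0.5, 10), info = nm)
    expect_gt(n_parameters(m), 0)
  }
  expect_error(arch_spec("Transformer"), "valid names")
  expect_error(build_model(arch_spec("MCE+RNN"), vs), "pretrained MCE")
})

test_that("width bookkeeping follows the size rule, including the time column", {
  vs <- c(dxproc = 618, medvit = 20)
  m <- build_model(arch_spec("Attention(concat time)", seed = 1), vs)
  expect_equal(dim(m$params$dxproc.E), c(618, 10))
  expect_equal(dim(m$params$dxproc.att.K), c(11, 11))   # 10 + time column
  expect_equal(dim(m$params$dxproc.head.w), c(11, 1))
  # bi-GRU pooling widths: 2d over outputs
  m2 <- build_model(arch_spec("RNN(concat dt)", seed = 1), vs)
  expect_equal(dim(m2$params$dxproc.rnnf.Wz), c(11, 10))  # input d+1 -> state d
  expect_equal(dim(m2$params$dxproc.head.w), c(20, 1))
})

test_that("duplicated stays and padded junk do not change predictions", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  m <- build_model(arch_spec("RNN(exp time decay)+Attention", seed = 7), vs)
  m$params$final.w[] <- rnorm(nrow(m$params$final.w), 0, 0.3)
  b1 <- pack_stays(co, c(3, 5, 3))
  pr <- predict_risk(m, b1)
  expect_equal(pr$risk[1], pr$risk[3], tolerance = 1e-12)
  # scribbling over masked (padded) slots must not change anything
  b2 <- pack_stays(co, 1:8)
  pr1 <- predict_risk(m, b2)
  for (s in c("dxproc", "medvit")) {
    pad <- b2[[s]]$mask == 0
    b2[[s]]$codes[pad] <- 1L
    b2[[s]]$elapsed[pad] <- 123.4
  }
  pr2 <- predict_risk(m, b2)
  expect_equal(pr1$risk, pr2$risk, tolerance = 1e-12)
})

test_that("permuting same-time events leaves attention-model risk unchanged", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  m <- build_model(arch_spec("Attention(concat time)", seed = 8), vs)
  set.seed(1)
  for (nm in names(m$params)) {
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), 0, 0.05)
  }
  batch <- pack_stays(co, 2)
  base <- predict_risk(m, batch)$logit
  # same elapsed time for every event, then permute event order
  for (s in c("dxproc", "medvit")) batch[[s]]$elapsed[] <- 1.5
  r0 <- predict_risk(m, batch)$risk
  l0 <- predict_risk(m, batch)$logit
  set.seed(2)
  for (rep in 1:5) {
    bp <- batch
    for (s in c("dxproc", "medvit")) {
      live <- which(bp[[s]]$mask[1, ] == 1)
      perm <- sample(live)
      bp[[s]]$codes[1, live] <- bp[[s]]$codes[1, perm]
    }
    expect_equal(predict_risk(m, bp)$risk, r0, tolerance = 1e-6)
  }
  expect_false(isTRUE(all.equal(base, l0)))  # times do matter otherwise
})

test_that("code_score matches the forward pass of a single-event stay", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  for (nm in c("Attention(concat time)", "ODE+RNN", "RNN(concat dt)+Attention")) {
    m <- build_model(arch_spec(nm, ode_steps = 2, seed = 9), vs)
    set.seed(3)
    for (p in names(m$params)) {
      m$params[[p]] <- m$params[[p]] + rnorm(length(m$params[[p]]), 0, 0.1)
    }
    cs <- code_score(m, 3L, "dxproc", elapsed = 0)
    batch <- icuread:::single_code_batch(m, 3L, "dxproc", 0)
    pr <- predict_risk(m, batch)
    expect_equal(cs, pr$scores$dxproc, tolerance = 1e-10, info = nm)
  }
  # zero embedding row and zero head weights leave only the head bias
  m <- build_model(arch_spec("Attention(concat time)", seed = 9), vs)
  m$params$dxproc.E[5, ] <- 0
  m$params$dxproc.head.w[] <- 0
  m$params$dxproc.head.b[] <- 0.42
  expect_equal(code_score(m, 5L, "dxproc"), 0.42, tolerance = 1e-12)
  # rescaling the final layer does not touch pre-final-layer code scores
  before <- code_score(m, seq_len(vs[["dxproc"]]), "dxproc")
  m$params$final.w <- m$params$final.w * 3.7
  expect_equal(code_score(m, seq_len(vs[["dxproc"]]), "dxproc"), before)
  expect_error(code_score(build_model(arch_spec("LogisticBaseline", seed = 1),
                                      vs, n_vit = 7), 1L, "dxproc"),
               "not defined")
})

test_that("risk is monotone in a stream score under a positive final weight", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  m <- build_model(arch_spec("Attention(concat time)", seed = 10), vs)
  n_static <- m$meta$n_static
  m$params$final.w[n_static + 1, 1] <- 0.8  # dxproc score weight > 0
  batch <- pack_stays(co, 1:12)
  r0 <- predict_risk(m, batch)$risk
  m2 <- m
  m2$params$dxproc.head.b[] <- m$params$dxproc.head.b[] + 0.5  # shift score up
  r1 <- predict_risk(m2, batch)$risk
  expect_true(all(r1 > r0))
  # orientation canonicalisation: a negative score weight is flipped
  # without changing predictions
  m3 <- m
  m3$params$final.w[n_static + 1, 1] <- -0.8
  m3$params$dxproc.head.w <- -m3$params$dxproc.head.w
  m3$params$dxproc.head.b <- -m3$params$dxproc.head.b
  m4 <- m3
  m4$params <- orient_scores(m4$params, n_static)
  expect_gt(m4$params$final.w[n_static + 1, 1], 0)
  expect_equal(predict_risk(m4, batch)$risk, predict_risk(m3, batch)$risk,
               tolerance = 1e-12)
})

test_that("the logistic baseline sees statics and recent vitals only", {
  co <- small_cohort()
  vs <- vocab_sizes(co)
  m <- build_model(arch_spec("LogisticBaseline", seed = 1), vs,
                   n_vit = sum(co$vocab$medvit$kind == "vit"))
  set.seed(4)
  m$params$final.w[] <- rnorm(nrow(m$params$final.w), 0, 0.3)
  rows <- 1:15
  b <- pack_stays(co, rows)
  r1 <- predict_risk(m, b)$risk
  # removing the entire dx/proc history changes nothing
  co2 <- co
  co2$events$dxproc <- co$events$dxproc[0, ]
  r2 <- predict_risk(m, pack_stays(co2, rows))$risk
  expect_equal(r1, r2, tolerance = 1e-12)
  # dropping all medication (non-vital) events changes nothing either
  co3 <- co
  vit_codes <- co$vocab$medvit$index[co$vocab$medvit$kind == "vit"]
  co3$events$medvit <- co$events$medvit[co$events$medvit$code %in% vit_codes, ]
  r3 <- predict_risk(m, pack_stays(co3, rows))$risk
  expect_equal(r1, r3, tolerance = 1e-12)
  # but deleting the vitals themselves can change the prediction
  co4 <- co
  co4$events$medvit <- co$events$medvit[0, ]
  r4 <- predict_risk(m, pack_stays(co4, rows))$risk
  expect_false(isTRUE(all.equal(r1, r4)))
})
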