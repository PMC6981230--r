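# Independent brute-force oracles for the evaluation metrics: naive
# counting at every distinct threshold (O(n^2)), kept deliberately
# separate from the package's cumulative-count implementations.

brute_average_precision <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_r <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    p <- tp / sum(pred)
    r <- tp / npos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

brute_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

brute_best_f1 <- function(labels, scores) {
  best <- 0
  for (t in unique(scores)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    best <- max(best, f1)
  }
  best
}

brute_youden <- function(labels, scores) {
  best_j <- -Inf
  best <- NULL
  for (t in c(Inf, sort(unique(scores), decreasing = TRUE))) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && !is.null(best) && sens > best[1])) {
      best_j <- j
      best <- c(sens, spec)
    }
  }
  c(sensitivity = best[1], specificity = best[2])
}

# random binary-classification instance with ties in the scores
random_instance <- function(n) {
  labels <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
  if (all(labels == 1)) labels[1] <- 0
  if (all(labels == 0)) labels[1] <- 1
  scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
  list(labels = labels, scores = scores)
}
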