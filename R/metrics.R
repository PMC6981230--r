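# Evaluation protocol: average precision, AUROC, maximal F1, the Youden
# operating point, and patient-level bootstrap confidence intervals.

check_labels_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop2("labels and scores must have equal length")
  }
  if (anyNA(labels) || anyNA(scores)) stop2("labels/scores contain NA")
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  invisible(NULL)
}

#' Average precision
#'
#' Area under the precision-recall curve computed as the step-wise sum
#' \eqn{\sum_n (R_n - R_{n-1}) P_n} over thresholds placed at the distinct
#' score values in descending order. Tied scores are grouped at a single
#' threshold. Preferred over AUROC for imbalanced outcomes because it does
#' not reward true negatives.
#'
#' @param labels Binary 0/1 outcome vector.
#' @param scores Numeric risk scores (higher = more positive).
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(labels, scores) {
  check_labels_scores(labels, scores)
  npos <- sum(labels == 1)
  if (npos == 0) stop2("average_precision undefined: no positive labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  tp_at <- cumsum(vapply(seq_along(thr), function(k) sum(labels[grp == k]), 0))
  n_at <- cumsum(vapply(seq_along(thr), function(k) sum(grp == k), 0))
  prec <- tp_at / n_at
  rec <- tp_at / npos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with mid-rank tie correction:
#' the probability that a random positive outscores a random negative,
#' counting ties as one half.
#'
#' @inheritParams average_precision
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  check_labels_scores(labels, scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop2("auroc undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# internal: confusion counts for the rule "score >= threshold is positive"
# over the candidate thresholds (each distinct score, plus +Inf = predict
# nothing positive), vectorised over thresholds
threshold_scan <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  thr <- unique(s)
  last_idx <- cumsum(rle(s)$lengths)      # last position with score >= thr[k]
  tp <- cumsum(y)[last_idx]
  fp <- last_idx - tp
  data.frame(
    threshold = c(Inf, thr),
    tp = c(0, tp), fp = c(0, fp),
    fn = sum(labels == 1) - c(0, tp),
    tn = sum(labels == 0) - c(0, fp)
  )
}

#' Maximal F1 score over thresholds
#'
#' F1 is computed for every classification rule "score >= t positive", with
#' t ranging over the distinct observed scores, and the maximum is
#' returned.
#'
#' @inheritParams average_precision
#' @return The maximal F1 in \[0, 1\].
#' @export
best_f1 <- function(labels, scores) {
  check_labels_scores(labels, scores)
  if (sum(labels == 1) == 0) stop2("best_f1 undefined: no positive labels")
  sc <- threshold_scan(labels, scores)
  denom <- 2 * sc$tp + sc$fp + sc$fn
  f1 <- ifelse(denom == 0, 0, 2 * sc$tp / denom)
  max(f1)
}

#' Operating point maximising Youden's J
#'
#' Scans the classification rules "score >= t positive" (including the
#' degenerate all-negative rule) and returns sensitivity and specificity at
#' the threshold maximising J = sensitivity + specificity - 1. Ties in J
#' are broken toward higher sensitivity (i.e. the lower threshold).
#'
#' @inheritParams average_precision
#' @return Named numeric vector with `sensitivity`, `specificity`,
#'   `threshold` and `J`.
#' @export
youden_operating_point <- function(labels, scores) {
  check_labels_scores(labels, scores)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop2("youden_operating_point undefined: one class absent")
  }
  sc <- threshold_scan(labels, scores)
  sens <- sc$tp / (sc$tp + sc$fn)
  spec <- sc$tn / (sc$tn + sc$fp)
  j <- sens + spec - 1
  # ties toward higher sensitivity: among maximal J pick the largest sens
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(sens[best])]
  c(sensitivity = sens[pick], specificity = spec[pick],
    threshold = sc$threshold[pick], J = j[pick])
}

#' Patient-level bootstrap confidence interval for a metric
#'
#' Resamples patients (with all their stays, with multiplicity) with
#' replacement, recomputes the metric on each replicate, and reports the
#' replicate mean with 2.5/97.5 percentile bounds. Resampling patients
#' rather than stays respects within-patient clustering of ICU stays.
#' Replicates on which the metric is undefined (e.g. a single-class
#' resample) are dropped with a warning.
#'
#' @param metric Function of `(labels, scores)` returning a scalar.
#' @param labels Binary outcomes per stay.
#' @param scores Risk scores per stay.
#' @param patient_ids Patient identifier per stay; stays sharing an id are
#'   always resampled together.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return Named vector with `mean`, `lower`, `upper` plus attribute
#'   `replicates`.
#' @export
bootstrap_ci <- function(metric, labels, scores, patient_ids,
                         n_boot = 100, seed = 1L) {
  check_labels_scores(labels, scores)
  idx_by_pat <- split(seq_along(labels), patient_ids)
  reps <- bootstrap_replicates(length(idx_by_pat), n_boot, seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(idx_by_pat[reps[[b]]], use.names = FALSE)
    tryCatch(metric(labels[take], scores[take]), error = function(e) NA_real_)
  }, 0)
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " bootstrap replicate(s) dropped (metric undefined)")
  }
  out <- c(
    mean = mean(vals, na.rm = TRUE),
    lower = unname(stats::quantile(vals, 0.025, na.rm = TRUE)),
    upper = unname(stats::quantile(vals, 0.975, na.rm = TRUE))
  )
  attr(out, "replicates") <- vals
  out
}

# shared replicate index draws so all metrics in one evaluation use the
# same patient resamples
bootstrap_replicates <- function(n_patients, n_boot, seed) {
  set.seed(derive_seed(seed, 7001L))
  lapply(seq_len(n_boot), function(b) {
    sample.int(n_patients, n_patients, replace = TRUE)
  })
}

#' Evaluate risk scores with the full metric panel
#'
#' Computes average precision, AUROC, maximal F1 and the sensitivity /
#' specificity at the Youden-optimal threshold, each with a 95% bootstrap
#' confidence interval from `n_boot` patient-level resamples. All five
#' metrics share the same resamples within one call.
#'
#' @param labels Binary outcomes per stay.
#' @param scores Risk scores per stay.
#' @param patient_ids Patient identifiers per stay.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return An object of class `eval_report`: a data frame with one row per
#'   metric and columns `metric`, `mean`, `lower`, `upper`, plus the point
#'   estimates on the full data as attribute `point`.
#' @export
evaluate_scores <- function(labels, scores, patient_ids,
                            n_boot = 100, seed = 1L) {
  check_labels_scores(labels, scores)
  idx_by_pat <- split(seq_along(labels), patient_ids)
  reps <- bootstrap_replicates(length(idx_by_pat), n_boot, seed)
  metric_fns <- list(
    average_precision = average_precision,
    auroc = auroc,
    f1 = best_f1,
    sensitivity = function(l, s) youden_operating_point(l, s)[["sensitivity"]],
    specificity = function(l, s) youden_operating_point(l, s)[["specificity"]]
  )
  boot_vals <- matrix(NA_real_, n_boot, length(metric_fns),
                      dimnames = list(NULL, names(metric_fns)))
  for (b in seq_len(n_boot)) {
    take <- unlist(idx_by_pat[reps[[b]]], use.names = FALSE)
    lb <- labels[take]; sb <- scores[take]
    for (m in names(metric_fns)) {
      boot_vals[b, m] <- tryCatch(metric_fns[[m]](lb, sb),
                                  error = function(e) NA_real_)
    }
  }
  point <- vapply(metric_fns, function(f) f(labels, scores), 0)
  rep <- data.frame(
    metric = names(metric_fns),
    mean = colMeans(boot_vals, na.rm = TRUE),
    lower = apply(boot_vals, 2, stats::quantile, 0.025, na.rm = TRUE),
    upper = apply(boot_vals, 2, stats::quantile, 0.975, na.rm = TRUE),
    row.names = NULL
  )
  attr(rep, "point") <- point
  attr(rep, "n_boot") <- n_boot
  class(rep) <- c("eval_report", "data.frame")
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (", attr(x, "n_boot"),
      " patient-level bootstrap resamples)\n", sep = "")
  df <- as.data.frame(x)
  df$mean <- sprintf("%.3f", df$mean)
  df$ci <- sprintf("[%.3f, %.3f]", x$lower, x$upper)
  print(df[, c("metric", "mean", "ci")], row.names = FALSE)
  invisible(x)
}

#' Render an evaluation report as a markdown table
#'
#' @param reports Named list of `eval_report` objects (one per model).
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(reports) {
  stopifnot(length(reports) > 0)
  metrics <- reports[[1]]$metric
  header <- paste0("| Model | ", paste(metrics, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(metrics) + 1), collapse = "|"), "|")
  rows <- vapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cells <- sprintf("%.3f [%.3f,%.3f]", r$mean, r$lower, r$upper)
    paste0("| ", nm, " | ", paste(cells, collapse = " | "), " |")
  }, "")
  c(header, sep, rows)
}

#' Class weights for imbalanced binary outcomes
#'
#' The minority (positive) class receives weight N_neg / N_pos and the
#' negative class weight 1, so misclassifying a positive costs
#' proportionally more.
#'
#' @param labels Binary 0/1 vector.
#' @return Named vector `c(negative = 1, positive = N_neg/N_pos)`.
#' @export
class_weights <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop2("class_weights undefined: only one class present")
  }
  c(negative = 1, positive = nneg / npos)
}
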