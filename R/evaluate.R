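# Discrimination metrics and prevalence-aware predictive values.
#
# PPV and NPV are functions of sensitivity, specificity and the pre-test
# probability (prevalence):
#   PPV = Se * p / (Se * p + (1 - Sp) * (1 - p))
#   NPV = Sp * (1 - p) / ((1 - Se) * p + Sp * (1 - p))
# With p set to the empirical positive fraction these reduce exactly to the
# confusion-matrix ratios TP/(TP+FP) and TN/(TN+FN).

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via mid-ranks; tied score pairs count 1/2, so
#' the value equals exhaustive pair counting.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 ground truth.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0)
    stopf("AUC needs both classes; got %d positives and %d negatives", pos, neg)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Prevalence-adjusted predictive values
#'
#' @param sensitivity,specificity,prevalence Each in \[0, 1\].
#' @return list with `ppv` and `npv`.
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence))
    if (!is.finite(v) || v < 0 || v > 1) stopf("all inputs must lie in [0, 1]")
  den_p <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  den_n <- (1 - sensitivity) * prevalence + specificity * (1 - prevalence)
  if (den_p <= 0) stopf("PPV undefined: no positive predictions at this operating point")
  if (den_n <= 0) stopf("NPV undefined: no negative predictions at this operating point")
  list(ppv = sensitivity * prevalence / den_p,
       npv = specificity * (1 - prevalence) / den_n)
}

#' Back-solve prevalence from an operating point's PPV
#'
#' Closed-form inversion of the PPV equation:
#' `p = PPV (1 - Sp) / (Se (1 - PPV) + PPV (1 - Sp))`.
#'
#' @param sensitivity,specificity Operating point in \[0, 1\].
#' @param ppv Positive predictive value in (0, 1\].
#' @return The unique prevalence in (0, 1).
#' @export
solve_prevalence <- function(sensitivity, specificity, ppv) {
  b <- 1 - specificity
  den <- sensitivity * (1 - ppv) + ppv * b
  if (den <= 0) stopf("no prevalence in (0,1) yields PPV %.4f at this operating point", ppv)
  p <- ppv * b / den
  if (p <= 0 || p >= 1)
    stopf("no prevalence in (0,1) yields PPV %.4f at this operating point", ppv)
  p
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Case-level resampling; resamples containing a single class are redrawn
#' (their count is attached as `redraws`).
#'
#' @param scores,labels As in [auc_score()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed; identical seed gives identical intervals.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)` with attribute `redraws`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, seed = 0L,
                             level = 0.95) {
  labels <- as.integer(labels)
  n <- length(scores)
  if (length(unique(labels)) < 2L) stopf("both classes required")
  redraws <- 0L
  stat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redraws <<- redraws + 1L
      }
      auc_score(scores[idx], labels[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  ci <- unname(quantile(stat, c(a, 1 - a), type = 7))
  attr(ci, "redraws") <- redraws
  ci
}

# DeLong structural components: V10 (per positive), V01 (per negative),
# computed with mid-ranks.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  auc <- sum(r_all[seq_len(m)] - rx) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Implements the covariance structure of the paired AUC estimates directly
#' (mid-rank formulation); two-sided p-value from the asymptotic normal
#' difference.
#'
#' @param scores_a,scores_b Paired scores for the same cases.
#' @param labels Shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stopf("scores_a, scores_b and labels must be paired (equal length)")
  if (length(unique(labels)) < 2L) stopf("both classes required")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  delta <- ca$auc - cb$auc
  if (m < 2 || n < 2) {
    # the asymptotic covariance needs at least two cases per class
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                p_value = NA_real_))
  }
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  var_delta <- stats::var(d10) / m + stats::var(d01) / n
  p <- if (var_delta < 1e-16) {
    if (abs(delta) < 1e-12) 1 else 0
  } else {
    2 * pnorm(-abs(delta) / sqrt(var_delta))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, p_value = p)
}

#' Youden-J optimal threshold
#'
#' @param scores,labels As in [auc_score()].
#' @return The score threshold maximising sensitivity + specificity - 1.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Full evaluation report for one model on one cohort
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 ground truth.
#' @param threshold Operating threshold (default 0.5) or `"youden"`.
#' @param prevalence Prevalence for PPV/NPV; default the cohort's empirical
#'   positive fraction (any value may be supplied to transport the
#'   operating point to another pre-test probability).
#' @param n_boot,seed Bootstrap settings for the AUC CI.
#' @return An `eval_report` list: `auc`, `auc_ci`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `prevalence`, `threshold`, confusion
#'   counts, `n`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5, prevalence = NULL,
                        n_boot = 2000L, seed = 0L) {
  labels <- as.integer(labels)
  if (identical(threshold, "youden")) threshold <- youden_threshold(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0); fn <- sum(!pred & labels == 1)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  prev <- prevalence %||% mean(labels)
  if ((tp + fp) == 0 || (tn + fn) == 0) {
    warnf("degenerate operating point (all predictions on one side of the threshold); PPV/NPV undefined")
    pv <- list(ppv = NA_real_, npv = NA_real_)
  } else {
    pv <- ppv_npv(sens, spec, prev)
    # internal consistency: at empirical prevalence the equations must
    # equal the confusion-matrix ratios exactly
    if (is.null(prevalence)) {
      stopifnot(abs(pv$ppv - tp / (tp + fp)) < 1e-9,
                abs(pv$npv - tn / (tn + fn)) < 1e-9)
    }
  }
  structure(list(auc = auc_score(scores, labels),
                 auc_ci = bootstrap_auc_ci(scores, labels, n_boot, seed),
                 sensitivity = sens, specificity = spec,
                 ppv = pv$ppv, npv = pv$npv, prevalence = prev,
                 threshold = threshold,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report n=%d> AUC %.3f (%.3f-%.3f)  Se %.3f  ",
                     "Sp %.3f  PPV %.2f%%  NPV %.2f%% @ prev %.3f, thr %.3f\n"),
              x$n, x$auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity,
              x$specificity, 100 * x$ppv, 100 * x$npv, x$prevalence,
              x$threshold))
  invisible(x)
}
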