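# Empirical ROC analysis, implemented from first principles (the installed
# pROC package is used only as an independent cross-check in the test suite).

check_two_classes <- function(truth) {
  stopifnot_flag(truth, "truth")
  if (!any(truth) || all(truth)) {
    stop("both reference classes must be present; AUC is undefined otherwise",
         call. = FALSE)
  }
}

#' Empirical ROC curve with AUC
#'
#' Builds the empirical receiver operating characteristic curve of a
#' continuous score against a binary reference standard. Candidate
#' thresholds are the distinct observed scores plus a `+Inf` sentinel;
#' a subject screens positive when its score is at or above the threshold.
#' The AUC is the trapezoidal area under the empirical curve, which equals
#' the Mann-Whitney two-sample statistic ([auc_mannwhitney()]) exactly.
#'
#' @param scores numeric score vector (higher = more disease-like).
#' @param truth logical reference-standard vector, same length.
#' @param ci_method `"delong"` (default), `"bootstrap"`, or `"none"`.
#' @param level confidence level for the AUC interval.
#' @param boot_n bootstrap resamples (bootstrap method only).
#' @param seed RNG seed for the bootstrap (ignored by DeLong).
#' @return an object of class `"roc_curve"`: list with `thresholds`
#'   (decreasing), `fpr`, `tpr` (nondecreasing, from (0,0) to (1,1)),
#'   `auc`, `ci_low`, `ci_high`, `ci_method`, `level`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_curve(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE), ci_method = "none")
#' r$auc  # 0.875
#' @export
roc_curve <- function(scores, truth, ci_method = c("delong", "bootstrap", "none"),
                      level = 0.95, boot_n = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  check_two_classes(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, thr)
  tp_cum <- cumsum(tabulate(idx[truth], nbins = length(thr)))
  fp_cum <- cumsum(tabulate(idx[!truth], nbins = length(thr)))
  thresholds <- c(Inf, thr)
  tpr <- c(0, tp_cum / n_pos)
  fpr <- c(0, fp_cum / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  ci <- c(NA_real_, NA_real_)
  if (ci_method != "none") {
    ci <- auc_ci(scores, truth, level = level, method = ci_method,
                 boot_n = boot_n, seed = seed)
  }
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc,
                 ci_low = ci[[1]], ci_high = ci[[2]], ci_method = ci_method,
                 level = level, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("empirical ROC: %d positives, %d negatives, %d thresholds\n",
              x$n_pos, x$n_neg, length(x$thresholds)))
  if (x$ci_method == "none" || is.na(x$ci_low)) {
    cat(sprintf("AUC %.4f\n", x$auc))
  } else {
    cat(sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f, %s)\n", x$auc, 100 * x$level,
                x$ci_low, x$ci_high, x$ci_method))
  }
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' The probability that a randomly chosen reference-positive subject
#' outscores a randomly chosen reference-negative one, with ties counted
#' one half: the mean over all (positive, negative) pairs of
#' 1 / 0.5 / 0 for greater / equal / smaller. Computed via midranks, which
#' is algebraically identical to the pairwise mean, and equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return numeric AUC in \[0, 1\].
#' @export
auc_mannwhitney <- function(scores, truth) {
  check_two_classes(truth)
  stopifnot(length(scores) == length(truth))
  m <- sum(truth); n <- sum(!truth)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - m * (m + 1) / 2) / (m * n)
}

#' Confidence interval for the AUC
#'
#' DeLong's asymptotic method uses the placement values of each subject
#' (the per-subject components of the Mann-Whitney statistic): the AUC
#' variance is `var(V10)/n_pos + var(V01)/n_neg` and the interval is the
#' normal interval truncated to \[0, 1\]. The bootstrap method resamples
#' subjects with replacement, stratified by reference class, and takes the
#' percentile interval of the resampled Mann-Whitney AUCs.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` or `"bootstrap"`.
#' @return named numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, truth, level = 0.95,
                   method = c("delong", "bootstrap"),
                   boot_n = 2000, seed = NULL) {
  method <- match.arg(method)
  check_two_classes(truth)
  stopifnot(level > 0, level < 1)
  pos <- scores[truth]; neg <- scores[!truth]
  m <- length(pos); n <- length(neg)
  if (method == "delong") {
    if (m < 2 || n < 2) {
      stop("DeLong interval needs at least 2 subjects in each class",
           call. = FALSE)
    }
    r_all <- rank(c(pos, neg), ties.method = "average")
    v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
    auc <- mean(v10)
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    z <- stats::qnorm((1 + level) / 2)
    ci <- c(low = max(0, auc - z * se), high = min(1, auc + z * se))
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    boots <- vapply(seq_len(boot_n), function(b) {
      s <- c(pos[sample.int(m, m, replace = TRUE)],
             neg[sample.int(n, n, replace = TRUE)])
      auc_mannwhitney(s, rep(c(TRUE, FALSE), c(m, n)))
    }, numeric(1))
    q <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                         names = FALSE)
    ci <- c(low = q[1], high = q[2])
  }
  ci
}

#' Youden-optimal cut-off
#'
#' Evaluates the Youden index `J = sensitivity + specificity - 1` at every
#' candidate threshold (positivity is score >= threshold) and returns the
#' maximiser. By default candidates are the distinct observed score values
#' (plus a `+Inf` sentinel); `candidates = "integer"` instead searches the
#' integer grid spanning the observed range, the convention some published
#' validations appear to use. Ties in J are broken towards the smallest
#' threshold, which maximises sensitivity; a tie is reported, not hidden.
#'
#' @inheritParams roc_curve
#' @param candidates `"observed"` (default) or `"integer"`.
#' @return a list with `threshold`, `sensitivity`, `specificity`, `j`,
#'   `tie` (logical: was the maximum attained at several thresholds), and
#'   `tied_thresholds`.
#' @examples
#' optimal_cutoff_youden(c(3, 5, 7, 1, 2, 6), rep(c(TRUE, FALSE), each = 3))
#' @export
optimal_cutoff_youden <- function(scores, truth,
                                  candidates = c("observed", "integer")) {
  candidates <- match.arg(candidates)
  check_two_classes(truth)
  if (candidates == "observed") {
    cand <- c(Inf, sort(unique(scores), decreasing = TRUE))
  } else {
    cand <- c(Inf, seq(ceiling(max(scores)), floor(min(scores))))
  }
  n_pos <- sum(truth); n_neg <- sum(!truth)
  sens <- vapply(cand, function(t) sum(truth & scores >= t) / n_pos, numeric(1))
  spec <- vapply(cand, function(t) sum(!truth & scores < t) / n_neg, numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  tied <- cand[best]
  # candidates are in decreasing order, so the last hit is the smallest
  pick <- best[length(best)]
  list(threshold = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick], j = j[pick],
       tie = length(best) > 1, tied_thresholds = tied)
}
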