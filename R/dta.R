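#' Build a 2x2 contingency table from screen and reference flags
#'
#' Cross-tabulates a screening result against the reference-standard truth
#' into true/false positive/negative counts.
#'
#' @param screen logical vector, `TRUE` = screen positive.
#' @param truth logical vector, `TRUE` = reference-standard positive; same
#'   length as `screen`.
#' @return an object of class `"contingency_table"`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn`.
#' @examples
#' build_contingency(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
build_contingency <- function(screen, truth) {
  stopifnot_flag(screen, "screen"); stopifnot_flag(truth, "truth")
  if (length(screen) != length(truth) || length(screen) == 0) {
    stop("screen and truth must be nonempty vectors of equal length",
         call. = FALSE)
  }
  contingency_table(tp = sum(screen & truth), fp = sum(screen & !truth),
                    fn = sum(!screen & truth), tn = sum(!screen & !truth))
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @return an object of class `"contingency_table"`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cts) || any(cts < 0) || any(cts != round(cts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(cts) == 0) stop("contingency table is empty", call. = FALSE)
  structure(as.list(as.integer(cts)), names = names(cts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic-accuracy metrics from a contingency table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, likelihood ratios and the Youden index from a 2x2 table.
#' Predictive values are proportions among test-positives/-negatives at the
#' table's own prevalence (no external prevalence is injected). Undefined
#' ratios are flagged (`Inf` for a likelihood ratio with a zero
#' denominator but nonzero numerator, `NaN` when 0/0), never silently
#' zeroed.
#'
#' @param ct a [contingency_table()].
#' @return an object of class `"accuracy_metrics"`: a list with fields
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `lr_pos`, `lr_neg`,
#'   `youden_j` (all proportions on \[0,1\] except the LRs), plus the
#'   source `table`.
#' @examples
#' accuracy_metrics(contingency_table(tp = 38, fp = 27, fn = 43, tn = 371))
#' @export
accuracy_metrics <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  npos <- ct$tp + ct$fn; nneg <- ct$fp + ct$tn
  if (npos == 0) stop("no reference-positive subjects: sensitivity undefined",
                      call. = FALSE)
  if (nneg == 0) stop("no reference-negative subjects: specificity undefined",
                      call. = FALSE)
  sens <- ct$tp / npos
  spec <- ct$tn / nneg
  lr <- likelihood_ratios(sens, spec)
  out <- list(
    sensitivity = sens, specificity = spec,
    ppv = if (ct$tp + ct$fp > 0) ct$tp / (ct$tp + ct$fp) else NaN,
    npv = if (ct$tn + ct$fn > 0) ct$tn / (ct$tn + ct$fn) else NaN,
    lr_pos = lr[["lr_pos"]], lr_neg = lr[["lr_neg"]],
    youden_j = youden(sens, spec),
    table = ct
  )
  class(out) <- "accuracy_metrics"
  out
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %s  specificity %s  PPV %s  NPV %s  LR+ %s  LR- %s  J %.4f\n",
    fmt_pct(x$sensitivity), fmt_pct(x$specificity),
    fmt_pct(x$ppv, 0), fmt_pct(x$npv, 0),
    fmt_lr(x$lr_pos), fmt_lr(x$lr_neg), x$youden_j))
  invisible(x)
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`. A perfect
#' specificity with nonzero sensitivity yields a flagged-infinite LR+
#' (`Inf`); a zero specificity yields an undefined LR- (`NaN`).
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return named numeric vector `c(lr_pos, lr_neg)`.
#' @examples
#' likelihood_ratios(0.4691, 0.9322) # 6.92, 0.57 after 2-dp rounding
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  lr_pos <- if (specificity < 1) sensitivity / (1 - specificity)
            else if (sensitivity > 0) Inf else NaN
  lr_neg <- if (specificity > 0) (1 - sensitivity) / specificity else NaN
  c(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`, the screening instrument's overall
#' ability to separate cases from non-cases; ranges over \[-1, 1\].
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return numeric J.
#' @export
youden <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Reconstruct integer 2x2 tables from printed rounded metrics
#'
#' Published accuracy tables report sensitivity and specificity rounded to
#' a few decimal places in percent. Given the margin sizes (numbers of
#' reference-positive and -negative subjects), this enumerates every
#' integer table consistent with the printed values: all `tp` in
#' `0..n_pos` and `tn` in `0..n_neg` whose percentages, rounded half-up to
#' `decimals` places, equal the printed pair. An empty result is a finding
#' (the printed row is not attainable over those margins), not an error;
#' multiple results are reported as ambiguity, never collapsed to one.
#'
#' @param sens_pct,spec_pct printed sensitivity and specificity, percent.
#' @param n_pos,n_neg reference-positive / -negative margin totals.
#' @param decimals decimal places of the printed percentages (default 2).
#' @return object of class `"count_reconstruction"`: a list of
#'   [contingency_table()]s (possibly empty) with attributes recording the
#'   query.
#' @examples
#' reconstruct_counts(46.91, 93.22, n_pos = 81, n_neg = 398) # unique table
#' @export
reconstruct_counts <- function(sens_pct, spec_pct, n_pos, n_neg, decimals = 2) {
  stopifnot(n_pos > 0, n_neg > 0, decimals >= 0)
  tp_all <- 0:n_pos
  tn_all <- 0:n_neg
  # sensitivity depends only on tp and specificity only on tn, so the
  # exhaustive search over the (n_pos+1) x (n_neg+1) grid factorises
  tp_ok <- tp_all[round_half_up(100 * tp_all / n_pos, decimals) == sens_pct]
  tn_ok <- tn_all[round_half_up(100 * tn_all / n_neg, decimals) == spec_pct]
  tables <- list()
  for (tp in tp_ok) for (tn in tn_ok) {
    tables[[length(tables) + 1L]] <-
      contingency_table(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  }
  structure(tables, class = "count_reconstruction",
            query = list(sens_pct = sens_pct, spec_pct = spec_pct,
                         n_pos = n_pos, n_neg = n_neg, decimals = decimals))
}

#' @export
print.count_reconstruction <- function(x, ...) {
  q <- attr(x, "query")
  cat(sprintf("reconstruction of sens %s%% / spec %s%% over %d+ / %d- subjects:\n",
              q$sens_pct, q$spec_pct, q$n_pos, q$n_neg))
  if (length(x) == 0) {
    cat("  no integer table is consistent with the printed values\n")
  } else {
    if (length(x) > 1) cat("  AMBIGUOUS:", length(x), "consistent tables\n")
    for (ct in x) {
      cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", ct$tp, ct$fp, ct$fn, ct$tn))
    }
  }
  invisible(x)
}

# display helpers: percents with trailing zeros trimmed (79.90 prints as
# 79.9, matching the mixed precision of published accuracy tables)
fmt_pct <- function(p, decimals = 2) {
  if (is.na(p)) return("NA")
  v <- round_half_up(100 * p, decimals)
  paste0(format(v, trim = TRUE, scientific = FALSE), " %")
}

fmt_lr <- function(lr, decimals = 2) {
  if (is.nan(lr) || is.na(lr)) return("NA")
  if (is.infinite(lr)) return("∞")
  sprintf(paste0("%.", decimals, "f"), round_half_up(lr, decimals))
}

#' Format an accuracy report table
#'
#' Renders labelled [accuracy_metrics()] rows with the mixed precision of
#' published screening-validation tables: sensitivity and specificity to 2
#' decimal places in percent (trailing zeros trimmed), predictive values to
#' integer percent, likelihood ratios to 2 decimals. Flagged-infinite
#' ratios render as the infinity sign; undefined values as "NA".
#'
#' @param rows a named list of [accuracy_metrics()] objects; names are the
#'   row labels.
#' @return a data.frame of formatted strings with one row per input,
#'   suitable for printing or `write.csv`.
#' @export
format_accuracy_report <- function(rows) {
  stopifnot(length(rows) > 0, !is.null(names(rows)))
  out <- do.call(rbind, lapply(names(rows), function(lbl) {
    m <- rows[[lbl]]
    data.frame(
      model = lbl,
      sensitivity = fmt_pct(m$sensitivity),
      specificity = fmt_pct(m$specificity),
      ppv = fmt_pct(m$ppv, 0),
      npv = fmt_pct(m$npv, 0),
      lr_pos = fmt_lr(m$lr_pos),
      lr_neg = fmt_lr(m$lr_neg),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
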