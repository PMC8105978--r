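#' Run the full screening-validation analysis on a cohort
#'
#' The package's central estimator. Stratified by sex, it (1) classifies
#' every participant by the AWGS2019 reference standard, (2) computes the
#' Ishii score, (3) estimates the empirical ROC curve with AUC and a
#' confidence interval, (4) tabulates accuracy at the original chart
#' cut-offs (105 points male / 120 female) and (5) selects the
#' Youden-optimal cut-off and tabulates accuracy there. A sex stratum
#' missing one reference class has its ROC skipped with a warning rather
#' than aborting the study.
#'
#' @param cohort a `"sarc_cohort"` data.frame containing both sexes.
#' @param thresholds reference-standard thresholds ([awgs_thresholds()]).
#' @param convention screen positivity convention, `"ge"` or `"gt"`.
#' @param ci_method AUC interval method, `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed seed recorded in the report and used for any bootstrap.
#' @param cutoff_search `"observed"` or `"integer"` candidate grid for the
#'   Youden-optimal cut-off.
#' @return an object of class `"study_report"`: cohort summary, per-sex
#'   ROC and accuracy blocks (each with its archived contingency table, so
#'   every reported metric is recomputable), the conventions used, and the
#'   exclusion log carried over from the cohort.
#' @examples
#' cohort <- generate_cohort(default_config_from_table1(), n = 400, seed = 7)
#' rep <- validate_study(cohort, seed = 7)
#' print(rep)
#' @export
validate_study <- function(cohort, thresholds = awgs_thresholds(),
                           convention = c("ge", "gt"),
                           ci_method = c("delong", "bootstrap"),
                           boot_n = 2000, seed = 1L,
                           cutoff_search = c("observed", "integer")) {
  convention <- match.arg(convention)
  ci_method <- match.arg(ci_method)
  cutoff_search <- match.arg(cutoff_search)
  stopifnot(nrow(cohort) > 0)
  status <- classify_awgs2019(cohort, thresholds)
  scores <- ishii_score(cohort$sex, cohort$age, cohort$grip, cohort$cc)
  original_cut <- c(male = 105, female = 120)
  warnings <- character()
  strata <- lapply(c("male", "female"), function(s) {
    in_s <- cohort$sex == s
    truth <- status$sarcopenic[in_s]
    sc <- scores[in_s]
    if (!any(truth) || all(truth)) {
      warnings <<- c(warnings, sprintf(
        "stratum '%s' has a single reference class; ROC skipped", s))
      return(list(sex = s, n = sum(in_s), skipped = TRUE))
    }
    roc <- roc_curve(sc, truth, ci_method = ci_method, boot_n = boot_n,
                     seed = seed)
    at_cut <- function(cut) {
      scr <- ishii_screen(sc, s, cut, convention)
      ct <- build_contingency(scr$positive, truth)
      list(cutoff = cut, table = ct, metrics = accuracy_metrics(ct))
    }
    opt <- optimal_cutoff_youden(sc, truth, candidates = cutoff_search)
    list(sex = s, n = sum(in_s), skipped = FALSE, roc = roc,
         original = at_cut(original_cut[[s]]),
         optimal = c(at_cut(opt$threshold), list(tie = opt$tie)))
  })
  names(strata) <- c("male", "female")
  structure(list(
    summary = summarize_cohort(cohort, status),
    strata = strata,
    conventions = list(positivity = convention, ci_method = ci_method,
                       boot_n = boot_n, seed = seed,
                       cutoff_search = cutoff_search,
                       thresholds = unclass(thresholds)),
    exclusions = attr(cohort, "exclusions"),
    warnings = warnings
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== screening-validation study report ==\n")
  print(x$summary)
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    cat(sprintf("\n-- %s (n = %d) --\n", s, st$n))
    if (isTRUE(st$skipped)) {
      cat("  ROC skipped: single reference class\n")
      next
    }
    print(st$roc)
    rows <- list(original = st$original$metrics, optimal = st$optimal$metrics)
    names(rows) <- sprintf("%s cut-off %g", names(rows),
                           c(st$original$cutoff, st$optimal$cutoff))
    print(format_accuracy_report(rows), row.names = FALSE)
    if (isTRUE(st$optimal$tie)) cat("  (Youden maximum tied across thresholds)\n")
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  rows <- list()
  for (s in names(object$strata)) {
    st <- object$strata[[s]]
    if (isTRUE(st$skipped)) next
    for (k in c("original", "optimal")) {
      rows[[sprintf("%s sarcopenia / %s cut-off %g", s, k, st[[k]]$cutoff)]] <-
        st[[k]]$metrics
    }
  }
  format_accuracy_report(rows)
}

#' @export
plot.study_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    if (isTRUE(st$skipped)) next
    plot(st$roc, main = sprintf("%s (AUC %.2f)", s, st$roc$auc))
  }
  invisible(x)
}

# flatten a report into plain lists for JSON serialization
report_to_list <- function(report) {
  strat <- lapply(report$strata, function(st) {
    if (isTRUE(st$skipped)) return(list(sex = st$sex, n = st$n, skipped = TRUE))
    acc <- function(blk) list(
      cutoff = blk$cutoff,
      table = unclass(blk$table),
      sensitivity = blk$metrics$sensitivity,
      specificity = blk$metrics$specificity,
      ppv = blk$metrics$ppv, npv = blk$metrics$npv,
      lr_pos = blk$metrics$lr_pos, lr_neg = blk$metrics$lr_neg,
      youden_j = blk$metrics$youden_j)
    list(sex = st$sex, n = st$n, skipped = FALSE,
         auc = st$roc$auc, ci_low = st$roc$ci_low, ci_high = st$roc$ci_high,
         ci_method = st$roc$ci_method,
         original = acc(st$original), optimal = acc(st$optimal))
  })
  list(summary = unclass(report$summary), strata = strat,
       conventions = report$conventions,
       exclusions = report$exclusions, warnings = report$warnings)
}

#' Write a study report to disk
#'
#' Emits the report as machine-readable JSON (`report.json`), a
#' human-readable text rendering (`report.txt`), per-sex ROC coordinates
#' as CSV (`roc_<sex>.csv`), and a structured log of exclusions and
#' warnings (`log.txt`).
#'
#' @param report a [validate_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  for (s in names(report$strata)) {
    st <- report$strata[[s]]
    if (isTRUE(st$skipped)) next
    utils::write.csv(data.frame(threshold = st$roc$thresholds,
                                fpr = st$roc$fpr, tpr = st$roc$tpr),
                     file.path(dir, sprintf("roc_%s.csv", s)),
                     row.names = FALSE)
  }
  log_lines <- c(
    sprintf("exclusions: %d", nrow(report$exclusions %||% data.frame())),
    if (!is.null(report$exclusions) && nrow(report$exclusions)) {
      sprintf("  id=%s field=%s reason=%s", report$exclusions$id,
              report$exclusions$field, report$exclusions$reason)
    },
    sprintf("warning: %s", report$warnings))
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(dir)
}
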