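test_that("empirical curve and AUC match pair-counting on small cases", {
  scores <- c(2, 3, 1, 2); truth <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(scores, truth, ci_method = "none")
  expect_equal(r$auc, 0.875)                  # (1 + 0.5 + 1 + 1) / 4
  expect_equal(auc_mannwhitney(scores, truth), 0.875)
  expect_equal(auc_brute(scores, truth), 0.875)
  # curve anchored at (0,0) and (1,1), monotone in both coordinates
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # perfect separation and the chance line
  expect_equal(roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                         ci_method = "none")$auc, 1)
  expect_equal(roc_curve(rep(3, 6), rep(c(TRUE, FALSE), 3),
                         ci_method = "none")$auc, 0.5)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both reference classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle on random instances", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    scores <- sample(round(rnorm(n, 0, 2), 1))  # coarse grid forces ties
    truth <- random_truth(n)
    a_trap <- roc_curve(scores, truth, ci_method = "none")$auc
    a_mw <- auc_mannwhitney(scores, truth)
    expect_equal(a_trap, a_mw)
    if (i <= 40) expect_equal(a_trap, auc_brute(scores, truth))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- rnorm(n); truth <- random_truth(n)
    a <- auc_mannwhitney(scores, truth)
    expect_equal(auc_mannwhitney(exp(scores), truth), a)
    expect_equal(auc_mannwhitney(2 * scores + 7, truth), a)
    expect_equal(auc_mannwhitney(rank(scores, ties.method = "average"), truth), a)
  }
})

test_that("DeLong interval matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:5) {
    truth <- rep(c(TRUE, FALSE), c(60, 140))
    scores <- rnorm(200, mean = ifelse(truth, 1, 0))
    ci <- auc_ci(scores, truth, method = "delong")
    ref <- pROC::ci.auc(pROC::roc(truth, scores, quiet = TRUE,
                                  direction = "<"), method = "delong")
    expect_equal(unname(ci), c(ref[1], ref[3]), tolerance = 1e-10)
  }
  expect_error(auc_ci(c(1, 2, 3), c(TRUE, FALSE, FALSE), method = "delong"),
               "at least 2 subjects")
})

test_that("DeLong interval attains nominal coverage under a binormal model", {
  set.seed(34)
  true_auc <- 0.84
  d <- qnorm(true_auc) * sqrt(2)
  hits <- 0; reps <- 500
  for (i in seq_len(reps)) {
    truth <- rep(c(TRUE, FALSE), c(50, 100))
    scores <- rnorm(150, mean = ifelse(truth, d, 0))
    ci <- auc_ci(scores, truth, method = "delong")
    hits <- hits + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  # binomial 3-SD band around 0.95 over 500 replicates
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("bootstrap interval is reproducible and truncated to [0, 1]", {
  set.seed(35)
  truth <- rep(c(TRUE, FALSE), c(30, 50))
  scores <- rnorm(80, mean = ifelse(truth, 1.2, 0))
  b1 <- auc_ci(scores, truth, method = "bootstrap", boot_n = 500, seed = 7)
  b2 <- auc_ci(scores, truth, method = "bootstrap", boot_n = 500, seed = 7)
  expect_identical(b1, b2)
  # perfectly separated classes pin the upper bound at 1
  sep <- c(rnorm(40, 10), rnorm(60, 0))
  tr <- rep(c(TRUE, FALSE), c(40, 60))
  expect_equal(auc_ci(sep, tr, method = "delong")[["high"]], 1)
})

test_that("Youden optimiser agrees with brute-force enumeration", {
  r <- optimal_cutoff_youden(c(10, 12, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$threshold, 10)
  expect_equal(r$j, 1)
  r2 <- optimal_cutoff_youden(rep(4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(r2$j, 0)
  expect_true(r2$tie)
  r3 <- optimal_cutoff_youden(c(3, 5, 7, 1, 2, 6), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r3$threshold, 3)
  expect_equal(r3$j, 2 / 3)
  set.seed(36)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- sample(round(rnorm(n), 1))
    truth <- random_truth(n)
    got <- optimal_cutoff_youden(scores, truth)
    expect_equal(got$j, youden_brute(scores, truth)$j)
    # J equals the maximum of tpr - fpr along the ROC curve
    rc <- roc_curve(scores, truth, ci_method = "none")
    expect_equal(got$j, max(rc$tpr - rc$fpr))
  }
})

test_that("integer-grid cut-off search stays on integers", {
  set.seed(37)
  scores <- rnorm(100, mean = rep(c(2, 0), c(40, 60)), sd = 1.5)
  truth <- rep(c(TRUE, FALSE), c(40, 60))
  r <- optimal_cutoff_youden(scores, truth, candidates = "integer")
  expect_true(r$threshold == round(r$threshold))
})
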