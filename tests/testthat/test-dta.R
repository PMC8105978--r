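test_that("contingency tables count the four joint outcomes and conserve totals", {
  ct <- build_contingency(c(TRUE, TRUE, FALSE, FALSE),
                          c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  ct2 <- build_contingency(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ct2$tp + ct2$fp, 0L)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:941, 1)
    scr <- runif(n) < 0.4; tru <- runif(n) < 0.2
    ct <- build_contingency(scr, tru)
    expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, n)
    expect_equal(ct$tp + ct$fn, sum(tru))
    expect_equal(ct$fp + ct$tn, sum(!tru))
  }
  expect_error(build_contingency(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("accuracy metrics reproduce the published female original-cut-off row", {
  m <- accuracy_metrics(contingency_table(tp = 38, fp = 27, fn = 43, tn = 371))
  expect_equal(round_half_up(100 * m$sensitivity, 2), 46.91)
  expect_equal(round_half_up(100 * m$specificity, 2), 93.22)
  expect_equal(round_half_up(100 * m$ppv, 0), 58)
  expect_equal(round_half_up(100 * m$npv, 0), 90)
  expect_equal(round_half_up(m$lr_pos, 2), 6.92)
  expect_equal(round_half_up(m$lr_neg, 2), 0.57)
})

test_that("degenerate and symmetric tables are handled explicitly", {
  m <- accuracy_metrics(contingency_table(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 0.5, specificity = 0.5, ppv = 0.5, npv = 0.5))
  expect_equal(unname(c(m$lr_pos, m$lr_neg, m$youden_j)), c(1, 1, 0))
  m0 <- accuracy_metrics(contingency_table(tp = 3, fp = 5, fn = 1, tn = 0))
  expect_equal(m0$specificity, 0)
  expect_true(is.nan(m0$lr_neg))
  expect_error(accuracy_metrics(contingency_table(tp = 0, fp = 2, fn = 0, tn = 3)),
               "sensitivity undefined")
  expect_error(accuracy_metrics(contingency_table(tp = 2, fp = 0, fn = 1, tn = 0)),
               "specificity undefined")
  expect_error(contingency_table(tp = -1, fp = 0, fn = 1, tn = 1), "nonnegative")
})

test_that("likelihood ratios and Youden index match published arithmetic", {
  expect_equal(round_half_up(likelihood_ratios(0.4691, 0.9322), 2),
               c(lr_pos = 6.92, lr_neg = 0.57))
  expect_equal(round_half_up(likelihood_ratios(0.6494, 0.8546), 2),
               c(lr_pos = 4.47, lr_neg = 0.41))
  lr <- likelihood_ratios(1, 1)
  expect_true(is.infinite(lr[["lr_pos"]]) && lr[["lr_neg"]] == 0)
  expect_true(is.nan(likelihood_ratios(0.5, 0)[["lr_neg"]]))
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_equal(youden(0.7531, 0.799), 0.5521)
  # identity LR+ * (1 - spec) = sens on random proportions
  set.seed(9)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1, 0, 0.999)
    expect_equal(likelihood_ratios(se, sp)[["lr_pos"]] * (1 - sp), se)
  }
})

test_that("count reconstruction finds unique tables or honestly reports none", {
  r <- reconstruct_counts(46.91, 93.22, n_pos = 81, n_neg = 398)
  expect_length(r, 1)
  expect_equal(unclass(r[[1]])[c("tp", "tn")], list(tp = 38L, tn = 371L))
  r2 <- reconstruct_counts(70.65, 81.35, n_pos = 92, n_neg = 370)
  expect_length(r2, 1)
  expect_equal(unclass(r2[[1]])[c("tp", "tn")], list(tp = 65L, tn = 301L))
  expect_length(reconstruct_counts(100, 100, n_pos = 10, n_neg = 10), 1)
  # the published male original row admits no integer table over its margins
  expect_length(reconstruct_counts(64.94, 85.46, n_pos = 92, n_neg = 370), 0)
})

test_that("metrics -> reconstruction round-trips random tables exactly", {
  set.seed(12)
  for (i in 1:25) {
    ct <- contingency_table(tp = sample(0:40, 1), fp = sample(0:40, 1),
                            fn = sample(1:40, 1), tn = sample(1:40, 1))
    m <- accuracy_metrics(ct)
    r <- reconstruct_counts(round_half_up(100 * m$sensitivity, 6),
                            round_half_up(100 * m$specificity, 6),
                            n_pos = ct$tp + ct$fn, n_neg = ct$fp + ct$tn,
                            decimals = 6)
    expect_length(r, 1)
    expect_identical(r[[1]], ct)
    # and every reconstructed table reproduces the printed inputs
    m2 <- accuracy_metrics(r[[1]])
    expect_equal(round_half_up(100 * m2$sensitivity, 6),
                 round_half_up(100 * m$sensitivity, 6))
  }
})

test_that("report formatting mirrors the mixed precision of published tables", {
  m <- accuracy_metrics(contingency_table(tp = 61, fp = 80, fn = 20, tn = 318))
  tab <- format_accuracy_report(list("Female sarcopenia / new cut-off" = m))
  expect_equal(tab$sensitivity, "75.31 %")
  expect_equal(tab$specificity, "79.9 %")  # trailing zero trimmed
  expect_equal(tab$ppv, "43 %")
  expect_equal(tab$npv, "94 %")
  expect_equal(tab$lr_pos, "3.75")
  expect_equal(tab$lr_neg, "0.31")
  perfect <- accuracy_metrics(contingency_table(tp = 5, fp = 0, fn = 0, tn = 5))
  tab2 <- format_accuracy_report(list(perfect = perfect))
  expect_equal(tab2$lr_pos, "∞")
  zero_spec <- accuracy_metrics(contingency_table(tp = 2, fp = 3, fn = 2, tn = 0))
  expect_equal(format_accuracy_report(list(x = zero_spec))$lr_neg, "NA")
})

test_that("rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(46.905, 2), 46.91)
})
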