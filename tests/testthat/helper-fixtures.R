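# shared fixtures: tiny cohorts built in code, brute-force oracles

make_cohort_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = rep_len(c("male", "female"), n),
    age = round(runif(n, 60, 90), 1),
    height = round(runif(n, 1.45, 1.80), 2),
    asmi = round(runif(n, 4.5, 9), 2),
    grip = round(runif(n, 12, 50), 1),
    gait_speed = round(runif(n, 0.6, 1.5), 2),
    cc = round(runif(n, 26, 42), 1),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  names(df) <- unname(cohort_schema())[match(names(df), names(cohort_schema()))]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# O(n_pos * n_neg) pairwise AUC, the independent oracle for both the
# trapezoidal and the rank-based Mann-Whitney implementations
auc_brute <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force Youden maximiser over all observed thresholds
youden_brute <- function(scores, truth) {
  cand <- sort(unique(scores), decreasing = TRUE)
  best <- list(j = -Inf, threshold = NA)
  for (t in c(Inf, cand)) {
    sens <- mean(scores[truth] >= t)
    spec <- mean(scores[!truth] < t)
    j <- sens + spec - 1
    # strictly-greater keeps the first (largest) threshold at ties; the
    # package breaks ties towards the smallest, so compare with tolerance
    if (j > best$j + 1e-12 || (abs(j - best$j) <= 1e-12)) {
      best <- list(j = j, threshold = t)
    }
  }
  best
}

random_truth <- function(n) {
  repeat {
    t <- runif(n) < 0.5
    if (any(t) && !all(t)) return(t)
  }
}
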