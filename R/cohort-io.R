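#' Default cohort column schema
#'
#' Maps the seven required participant fields (plus `id`) to CSV column
#' names. Override entries to read files with different headers, e.g.
#' `cohort_schema(grip = "grip_strength")`.
#'
#' @param ... named overrides, one per field.
#' @return named character vector field -> column name.
#' @export
cohort_schema <- function(...) {
  schema <- c(id = "id", sex = "sex", age = "age", height = "height_m",
              asmi = "asmi_kg_m2", grip = "grip_kg",
              gait_speed = "gait_speed_m_s", cc = "cc_cm")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) stop("unknown schema field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    schema[names(over)] <- over
  }
  schema
}

# per-record validation shared by read_cohort and the synthetic generator;
# returns list(cohort = valid rows, exclusions = data.frame(id, field, reason))
validate_cohort <- function(df) {
  n <- nrow(df)
  excl <- list()
  note <- function(i, field, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(
      id = as.character(df$id[i]), field = field, reason = reason,
      stringsAsFactors = FALSE)
  }
  keep <- rep(TRUE, n)
  sex_raw <- tolower(trimws(as.character(df$sex)))
  sex_raw[sex_raw == "m"] <- "male"; sex_raw[sex_raw == "f"] <- "female"
  bounds <- list(age = c(60, 120), height = c(1.0, 2.2), asmi = c(0, Inf),
                 grip = c(0, Inf), gait_speed = c(0, 3), cc = c(15, 60))
  for (i in seq_len(n)) {
    if (is.na(sex_raw[i]) || !(sex_raw[i] %in% c("male", "female"))) {
      keep[i] <- FALSE; note(i, "sex", "missing or unrecognised sex"); next
    }
    for (f in names(bounds)) {
      v <- suppressWarnings(as.numeric(df[[f]][i]))
      if (is.na(v) || !is.finite(v)) {
        keep[i] <- FALSE; note(i, f, "missing or unparseable value"); break
      }
      if (v <= 0) {
        keep[i] <- FALSE; note(i, f, "non-positive value"); break
      }
      if (v < bounds[[f]][1] || v > bounds[[f]][2]) {
        keep[i] <- FALSE
        note(i, f, sprintf("outside [%g, %g]", bounds[[f]][1], bounds[[f]][2]))
        break
      }
    }
  }
  out <- df[keep, , drop = FALSE]
  out$sex <- factor(sex_raw[keep], levels = c("male", "female"))
  for (f in c("age", "height", "asmi", "grip", "gait_speed", "cc")) {
    out[[f]] <- as.numeric(out[[f]])
  }
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), field = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(cohort = out, exclusions = exclusions)
}

#' Read a cohort CSV
#'
#' Reads a per-participant table (UTF-8 CSV, "." decimal separator, header
#' row) with sex, age, height, ASMI, grip strength, gait speed and calf
#' circumference, validates every record, and excludes invalid ones.
#' Exclusion is per record, with the offending field and reason logged; a
#' missing required column is fatal. Validation enforces the recruitment
#' age floor of 60 years and physiologic sanity bounds (height 1.0-2.2 m,
#' gait speed at most 3 m/s, calf circumference 15-60 cm, all measurements
#' strictly positive and finite).
#'
#' @param path CSV file path.
#' @param schema field -> column-name map from [cohort_schema()].
#' @return a data.frame of class `"sarc_cohort"` with columns `id`, `sex`,
#'   `age`, `height`, `asmi`, `grip`, `gait_speed`, `cc`; attributes
#'   `exclusions` (data.frame id/field/reason) and `n_excluded`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss)) {
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[unname(schema)], names(schema))
  if (!"id" %in% names(df) || all(df$id == "")) df$id <- seq_len(nrow(df))
  v <- validate_cohort(df)
  structure(v$cohort, class = c("sarc_cohort", "data.frame"),
            exclusions = v$exclusions, n_excluded = nrow(v$exclusions))
}

#' Write a cohort CSV
#'
#' Writes a cohort in the same dialect [read_cohort()] reads, so that a
#' validated cohort round-trips unchanged.
#'
#' @param cohort a cohort data.frame.
#' @param path output path.
#' @param schema field -> column-name map.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = cohort_schema()) {
  out <- cohort[names(schema)]
  names(out) <- unname(schema)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sarc_cohort <- function(x, ...) {
  cat(sprintf("cohort: %d participants (%d male, %d female), %d excluded on read\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              attr(x, "n_excluded") %||% 0L))
  NextMethod()
}

# age bands used throughout: <65, 65-69, 70-79, >=80
age_bands <- function(age) {
  cut(age, breaks = c(-Inf, 65, 70, 80, Inf), right = FALSE,
      labels = c("<65", "65-69", "70-79", ">=80"))
}

#' Descriptive cohort summary
#'
#' Produces a baseline-characteristics summary in the style of a
#' participant table: per-sex n, age-band counts and percentages, mean and
#' sample (n-1) standard deviation of each continuous measurement, and
#' sarcopenia counts and prevalence per sex and overall. Percentages are
#' rounded half-up to 2 decimal places; the SD of a single observation is
#' reported as `NA`.
#'
#' @param cohort a cohort data.frame (nonempty).
#' @param status a [classify_awgs2019()] result aligned row-for-row with
#'   `cohort`.
#' @return an object of class `"cohort_summary"`.
#' @export
summarize_cohort <- function(cohort, status) {
  stopifnot(nrow(cohort) > 0)
  if (nrow(status) != nrow(cohort)) {
    stop("status must align one-to-one with cohort rows", call. = FALSE)
  }
  sexes <- c("male", "female")
  cont <- c("height", "asmi", "grip", "gait_speed", "cc")
  per_sex <- lapply(sexes, function(s) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    sar <- status$sarcopenic[cohort$sex == s]
    bands <- table(age_bands(sub$age))
    list(n = nrow(sub),
         age_band_n = as.vector(bands),
         age_band_pct = round_half_up(100 * as.vector(bands) /
                                        max(nrow(sub), 1), 2),
         mean = vapply(cont, function(f) mean(sub[[f]]), numeric(1)),
         sd = vapply(cont, function(f)
           if (nrow(sub) > 1) stats::sd(sub[[f]]) else NA_real_, numeric(1)),
         sarcopenia_n = sum(sar),
         sarcopenia_pct = round_half_up(100 * sum(sar) / max(nrow(sub), 1), 2))
  })
  names(per_sex) <- sexes
  structure(list(
    per_sex = per_sex,
    band_labels = levels(age_bands(60)),
    n_total = nrow(cohort),
    sarcopenia_n = sum(status$sarcopenic),
    sarcopenia_pct = round_half_up(100 * sum(status$sarcopenic) / nrow(cohort), 2)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort summary: N = %d (male %d, female %d)\n", x$n_total,
              x$per_sex$male$n, x$per_sex$female$n))
  for (s in names(x$per_sex)) {
    p <- x$per_sex[[s]]
    cat(sprintf("%s (n = %d)\n", s, p$n))
    for (i in seq_along(x$band_labels)) {
      cat(sprintf("  age %-5s %4d (%.2f%%)\n", x$band_labels[i],
                  p$age_band_n[i], p$age_band_pct[i]))
    }
    for (f in names(p$mean)) {
      cat(sprintf("  %-10s %.2f +/- %s\n", f, p$mean[[f]],
                  ifelse(is.na(p$sd[[f]]), "NA", sprintf("%.2f", p$sd[[f]]))))
    }
    cat(sprintf("  sarcopenia %d (%.2f%%)\n", p$sarcopenia_n, p$sarcopenia_pct))
  }
  cat(sprintf("overall sarcopenia %d (%.2f%%)\n", x$sarcopenia_n,
              x$sarcopenia_pct))
  invisible(x)
}
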