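#' Ishii sarcopenia screening score
#'
#' Computes the sex-specific Ishii chart score from age, grip strength and
#' calf circumference. The score is a linear combination of the three
#' measurements, centred so that a 64-year-old with reference grip and calf
#' values scores 0; higher scores indicate higher sarcopenia risk.
#'
#' For males the score is
#' \deqn{0.62 (age - 64) - 3.09 (grip - 50) - 4.64 (CC - 42)}
#' and for females
#' \deqn{0.8 (age - 64) - 5.09 (grip - 34) - 3.28 (CC - 42).}
#' The value is returned at full floating-point precision; no rounding,
#' clamping or truncation is applied.
#'
#' @param sex character or factor, "male"/"female" ("M"/"F" accepted),
#'   recycled against the measurement vectors.
#' @param age age in years.
#' @param grip grip strength in kg.
#' @param cc calf circumference in cm.
#' @return numeric vector of scores (points; may be negative).
#' @examples
#' ishii_score("male", 80, 25, 32)   # 133.57
#' ishii_score("female", 75, 18, 30) # 129.60
#' @seealso [ishii_screen()], [cc_screen()]
#' @export
ishii_score <- function(sex, age, grip, cc) {
  sex <- normalize_sex(sex)
  n <- max(length(sex), length(age), length(grip), length(cc))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  grip <- rep_len(grip, n); cc <- rep_len(cc, n)
  male <- 0.62 * (age - 64) - 3.09 * (grip - 50) - 4.64 * (cc - 42)
  female <- 0.80 * (age - 64) - 5.09 * (grip - 34) - 3.28 * (cc - 42)
  ifelse(sex == "male", male, female)
}

#' Apply a cut-off to Ishii scores
#'
#' Dichotomises Ishii scores at a cut-off. The original chart cut-offs are
#' 105 points for males and 120 for females, with a score at or above the
#' cut-off screening positive (`convention = "ge"`). A strict `"gt"`
#' convention is also provided because "more than x points" phrasings
#' appear in the screening literature; reports should state which was used.
#'
#' @param score numeric vector of Ishii scores.
#' @param sex sex vector, used only to resolve `cutoff = "original"`.
#' @param cutoff numeric cut-off in points, or `"original"` (105 male / 120
#'   female).
#' @param convention `"ge"` (default; positive iff score >= cutoff) or
#'   `"gt"` (positive iff score > cutoff).
#' @return a data.frame of class `"screen_result"` with columns `score`,
#'   `positive`, `cutoff_used`, `convention`.
#' @examples
#' ishii_screen(120, "female", "original")        # positive at the boundary
#' ishii_screen(95, "male", 95, convention = "gt") # negative under gt
#' @export
ishii_screen <- function(score, sex, cutoff = "original", convention = c("ge", "gt")) {
  convention <- match.arg(convention)
  sex <- normalize_sex(sex)
  n <- max(length(score), length(sex))
  score <- rep_len(score, n); sex <- rep_len(sex, n)
  if (identical(cutoff, "original")) {
    cut <- ifelse(sex == "male", 105, 120)
  } else {
    stopifnot(is.numeric(cutoff))
    cut <- rep_len(cutoff, n)
  }
  pos <- if (convention == "ge") score >= cut else score > cut
  out <- data.frame(score = score, positive = pos, cutoff_used = cut,
                    convention = convention, stringsAsFactors = FALSE)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Calf-circumference screen
#'
#' Flags possible sarcopenia from calf circumference alone, positive at or
#' below 34 cm in males and 33 cm in females (the boundary is included).
#'
#' @param cc calf circumference in cm.
#' @param sex sex vector ("male"/"female"/"M"/"F").
#' @return logical vector, `TRUE` = screen positive.
#' @examples
#' cc_screen(c(34, 35), "male")    # TRUE FALSE
#' cc_screen(c(33.1, 20), "female") # FALSE TRUE
#' @export
cc_screen <- function(cc, sex) {
  sex <- normalize_sex(sex)
  n <- max(length(cc), length(sex))
  cc <- rep_len(cc, n); sex <- rep_len(sex, n)
  ifelse(sex == "male", cc <= 34, cc <= 33)
}
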