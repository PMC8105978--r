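# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used by most clinical papers (and SPSS), as opposed to the
#' IEC 60559 round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (>= 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- x * 10^digits
  # nudge absorbs representation error in values that are exact halves on paper
  sign(p) * floor(abs(p) + 0.5 + 1e-9) / 10^digits
}

# normalise sex coding: accepts male/female (any case), M/F; errors otherwise
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  bad <- !is.na(s) & !(s %in% c("male", "female"))
  if (any(bad)) {
    stop("unknown sex value(s): ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(s, levels = c("male", "female"))
}

stopifnot_flag <- function(x, nm) {
  if (!is.logical(x) || anyNA(x)) {
    stop(nm, " must be logical without missing values", call. = FALSE)
  }
  invisible(x)
}
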