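#' AWGS2019 diagnostic thresholds
#'
#' Returns the threshold set of the Asian Working Group for Sarcopenia 2019
#' consensus, optionally overridden. Low muscle mass is ASMI below
#' 7.0 kg/m2 (males) / 5.7 kg/m2 (females); low strength is grip below
#' 28 kg / 18 kg; low physical performance is gait speed below 1.0 m/s.
#' All comparisons downstream are strict `<`: a value exactly at the cut is
#' normal.
#'
#' @param asmi_cut_male,asmi_cut_female ASMI cuts, kg/m2.
#' @param grip_cut_male,grip_cut_female grip-strength cuts, kg.
#' @param gait_cut gait-speed cut, m/s (shared by both sexes).
#' @return a named list of class `"awgs_thresholds"`.
#' @examples
#' awgs_thresholds()
#' @export
awgs_thresholds <- function(asmi_cut_male = 7.0, asmi_cut_female = 5.7,
                            grip_cut_male = 28, grip_cut_female = 18,
                            gait_cut = 1.0) {
  th <- list(asmi_cut_male = asmi_cut_male, asmi_cut_female = asmi_cut_female,
             grip_cut_male = grip_cut_male, grip_cut_female = grip_cut_female,
             gait_cut = gait_cut)
  vals <- unlist(th)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all AWGS thresholds must be strictly positive and finite", call. = FALSE)
  }
  if (asmi_cut_male < asmi_cut_female || grip_cut_male < grip_cut_female) {
    warning("male ASMI/grip cuts below female cuts; check the configuration",
            call. = FALSE)
  }
  class(th) <- "awgs_thresholds"
  th
}

#' Classify sarcopenia by the AWGS2019 rule
#'
#' Applies the AWGS2019 case definition: sarcopenia is low muscle mass
#' (ASMI) together with low muscle strength (grip) or low physical
#' performance (gait speed). A severe flag (all three components low) is
#' also derived. Classification depends only on sex, ASMI, grip and gait
#' speed; every comparison is strict less-than.
#'
#' @param cohort a data.frame with columns `sex`, `asmi`, `grip`,
#'   `gait_speed` (a cohort from [read_cohort()] or [generate_cohort()]).
#' @param thresholds an [awgs_thresholds()] object.
#' @return a data.frame of class `"sarcopenia_status"` with logical columns
#'   `low_mass`, `low_strength`, `low_performance`, `sarcopenic`, `severe`,
#'   one row per cohort row.
#' @examples
#' d <- data.frame(sex = c("male", "female"), asmi = c(6.9, 5.7),
#'                 grip = c(27, 17), gait_speed = c(1.2, 0.8))
#' classify_awgs2019(d)
#' @export
classify_awgs2019 <- function(cohort, thresholds = awgs_thresholds()) {
  stopifnot(inherits(thresholds, "awgs_thresholds"))
  req <- c("sex", "asmi", "grip", "gait_speed")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sex <- normalize_sex(cohort$sex)
  male <- sex == "male"
  low_mass <- cohort$asmi <
    ifelse(male, thresholds$asmi_cut_male, thresholds$asmi_cut_female)
  low_strength <- cohort$grip <
    ifelse(male, thresholds$grip_cut_male, thresholds$grip_cut_female)
  low_performance <- cohort$gait_speed < thresholds$gait_cut
  out <- data.frame(
    low_mass = low_mass,
    low_strength = low_strength,
    low_performance = low_performance,
    sarcopenic = low_mass & (low_strength | low_performance),
    severe = low_mass & low_strength & low_performance
  )
  class(out) <- c("sarcopenia_status", "data.frame")
  out
}
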