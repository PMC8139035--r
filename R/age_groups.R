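#' Age bands and age-sex groups of the population partition
#'
#' The epidemiological inputs are stratified by sex and 17 five-year age
#' bands (0-4 through 75-79, then 80+), the standard GBD extraction layout.
#' Together the two sexes and 17 bands give the 34 groups that partition the
#' population; every epidemiology table must cover all 34 for each disorder.
#'
#' @return `age_bands()`: character vector of the 17 ordered band labels.
#'   `age_sex_groups()`: data frame with columns `sex` ("female"/"male") and
#'   `age_band`, one row per group (34 rows).
#' @examples
#' age_bands()
#' nrow(age_sex_groups())  # 34
#' @export
age_bands <- function() {
  c("0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34", "35-39",
    "40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74",
    "75-79", "80+")
}

#' @rdname age_bands
#' @export
age_sex_groups <- function() {
  data.frame(
    sex = rep(c("female", "male"), each = 17L),
    age_band = rep(age_bands(), times = 2L),
    stringsAsFactors = FALSE
  )
}

# Midpoint age of each band (80+ treated as 85), used by the synthetic
# generator's age gradients.
band_midpoints <- function() {
  c(seq(2.5, 77.5, by = 5), 85)
}
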