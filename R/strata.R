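#' @title Model stratification grid
#' @description The simulation grid is 15 five-year age bands (lower bounds
#'   25, 30, ..., 95) crossed with sex. Cohorts alive in 2019 are simulated in
#'   annual cycles until death or age 100 (closed cohort, no births or
#'   migration).
#' @name strata
NULL

# band lower bounds of the simulation grid
.age_lower <- seq(25L, 95L, by = 5L)

#' Sexes recognised by the model
#' @export
model_sexes <- function() c("male", "female")

#' CKD causes modelled as separate illness-death submodels
#'
#' Hypertensive CKD (`htn`), diabetic CKD (`dm`), CKD due to
#' glomerulonephritis (`gmn`) and CKD of other/unspecified causes (`other`).
#' @return character vector of cause codes
#' @export
ckd_causes <- function() c("htn", "dm", "gmn", "other")

#' Age-band labels of the simulation grid
#' @param lower integer vector of band lower bounds
#' @return labels such as `"25-29"`
#' @export
age_band_label <- function(lower) {
  stopifnot(all(lower %in% .age_lower))
  paste0(lower, "-", lower + 4L)
}

#' The full stratification grid
#'
#' @return data.frame with columns `age_group`, `age_lower`, `sex`
#'   (30 rows: 15 age bands x 2 sexes, sex-major order)
#' @export
model_strata <- function() {
  data.frame(
    age_group = rep(age_band_label(.age_lower), times = 2L),
    age_lower = rep(.age_lower, times = 2L),
    sex       = rep(model_sexes(), each = length(.age_lower)),
    stringsAsFactors = FALSE
  )
}

# band index 1..15 for an age in years (capped at the terminal band)
band_of_age <- function(age) pmin(length(.age_lower), (pmax(age, 25) - 25) %/% 5 + 1)

# evaluate code with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
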