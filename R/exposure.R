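#' Convert salt to sodium
#'
#' Uses the sodium mass fraction of NaCl (22.99 / 58.44 = 0.3934), so 1 g of
#' salt contains 393.4 mg of sodium (about 390 mg when rounded to the nearest
#' 10 mg, see [round_sodium()]).
#'
#' @param salt_g grams of salt (NaCl), non-negative
#' @return milligrams of sodium
#' @export
salt_to_sodium_mg <- function(salt_g) {
  if (any(salt_g < 0)) stop("salt_g must be non-negative")
  salt_g * 1000 * 0.3934
}

#' Round a sodium amount to the nearest 10 mg
#' @param sodium_mg milligrams of sodium
#' @export
round_sodium <- function(sodium_mg) 10 * round(sodium_mg / 10)

#' Define a sodium-reduction scenario
#'
#' @param name scenario label (unique within a run)
#' @param kind one of `"absolute_sodium_target_mg"` (population-weighted mean
#'   sodium driven to `magnitude` mg/day, every stratum scaled by the same
#'   relative factor), `"relative_reduction_fraction"` (each stratum reduced
#'   by the fraction `magnitude`), `"absolute_salt_reduction_g"` (each stratum
#'   reduced by `magnitude` grams of salt, converted at 393.4 mg sodium/g)
#' @param magnitude scenario size in the units implied by `kind`; a relative
#'   fraction must lie in \[0, 1) (0 gives a null scenario)
#' @param ramp_years years of equal annual decrements to reach the target
#'   (default 10; decrements are applied at cycle starts in years
#'   `start_year + 1 ... start_year + ramp_years`)
#' @param start_year baseline calendar year (default 2019)
#' @return object of class `sodium_scenario`
#' @export
scenario <- function(name, kind = c("absolute_sodium_target_mg",
                                    "relative_reduction_fraction",
                                    "absolute_salt_reduction_g"),
                     magnitude, ramp_years = 10L, start_year = 2019L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, ramp_years >= 1)
  if (kind == "relative_reduction_fraction" && (magnitude < 0 || magnitude >= 1))
    stop("relative reduction fraction must lie in [0, 1)")
  if (kind != "relative_reduction_fraction" && magnitude <= 0)
    stop("magnitude must be positive")
  structure(list(name = name, kind = kind, magnitude = magnitude,
                 ramp_years = as.integer(ramp_years),
                 start_year = as.integer(start_year)),
            class = "sodium_scenario")
}

#' The six built-in policy scenarios
#'
#' (i) the Australian Suggested Dietary Target (SDT), a population mean of
#' 2000 mg sodium (5 g salt) per day; (ii) the National Preventive Health
#' Strategy 2021-2030 (NPHS) target of a 30% average reduction; (iii) a 20%
#' and (iv) a 15% relative reduction; (v) a 1 g/day and (vi) a 2 g/day
#' absolute salt reduction. All ramp linearly over ten years from 2019.
#'
#' @return named list of `sodium_scenario` objects
#' @export
default_scenarios <- function() {
  list(
    sdt     = scenario("SDT 2000 mg", "absolute_sodium_target_mg", 2000),
    nphs30  = scenario("NPHS 30% reduction", "relative_reduction_fraction", 0.30),
    rel20   = scenario("20% reduction", "relative_reduction_fraction", 0.20),
    rel15   = scenario("15% reduction", "relative_reduction_fraction", 0.15),
    salt1g  = scenario("1 g salt reduction", "absolute_salt_reduction_g", 1),
    salt2g  = scenario("2 g salt reduction", "absolute_salt_reduction_g", 2)
  )
}

#' Linear sodium ramp for one stratum
#'
#' The primitive applied per stratum by [build_trajectory()]: a steady linear
#' reduction from `baseline_mg` to `target_mg` in `ramp_years` equal annual
#' decrements (applied at the starts of years 2 ... `ramp_years + 1` of the
#' series), flat at the target thereafter.
#'
#' @param baseline_mg baseline mean sodium, mg/day
#' @param target_mg target mean sodium, mg/day (must not exceed baseline)
#' @param ramp_years number of equal annual decrements
#' @param n_years length of the returned annual series (>= ramp_years + 1)
#' @return numeric vector of length `n_years`; element 1 is the baseline
#' @export
sodium_ramp <- function(baseline_mg, target_mg, ramp_years = 10L,
                        n_years = ramp_years + 1L) {
  if (target_mg > baseline_mg + 1e-9) stop("target above baseline: sodium increase scenarios are not supported")
  frac <- pmin(seq_len(n_years) - 1L, ramp_years) / ramp_years
  pmax(baseline_mg - frac * (baseline_mg - target_mg), 0)
}

# per-stratum sodium targets implied by a scenario (matrix [band, sex])
scenario_targets <- function(na, pop, scn, stratum_cap = FALSE) {
  switch(scn$kind,
    absolute_sodium_target_mg = {
      wmean <- sum(na * pop) / sum(pop)
      if (scn$magnitude > wmean + 1e-9)
        stop("target above baseline: sodium increase scenarios are not supported")
      if (stratum_cap) pmin(na, scn$magnitude) else na * (scn$magnitude / wmean)
    },
    relative_reduction_fraction = na * (1 - scn$magnitude),
    absolute_salt_reduction_g = pmax(na - salt_to_sodium_mg(scn$magnitude), 0)
  )
}

#' Build the annual sodium trajectory for a scenario
#'
#' Per-stratum linear interpolation from baseline to the scenario target over
#' `ramp_years` equal annual decrements, flat at the target thereafter. For an
#' absolute sodium target the stratum targets are scaled by a common relative
#' factor so the population-weighted mean hits the target (or, with
#' `stratum_cap = TRUE`, each stratum is capped at the target instead).
#'
#' @param bundle a `ckd_bundle`
#' @param scn a `sodium_scenario`
#' @param n_years length of the annual series (default: through 2094, when
#'   the youngest 2019 cohort reaches age 100)
#' @param stratum_cap see Description; only affects absolute sodium targets
#' @return array `[band, sex, year]` of mean sodium (mg/day) with calendar
#'   years as the third dimnames; class `sodium_trajectory`
#' @export
build_trajectory <- function(bundle, scn, n_years = 2094L - scn$start_year + 1L,
                             stratum_cap = FALSE) {
  B <- as_model_arrays(bundle)
  tgt <- scenario_targets(B$na, B$pop, scn, stratum_cap)
  years <- scn$start_year + seq_len(n_years) - 1L
  out <- array(NA_real_, c(nrow(B$na), 2, n_years),
               dimnames = list(rownames(B$na), model_sexes(), years))
  for (k in seq_len(nrow(B$na))) for (s in 1:2)
    out[k, s, ] <- sodium_ramp(B$na[k, s], tgt[k, s], scn$ramp_years, n_years)
  structure(out, baseline = B$na, target = tgt, scenario = scn,
            class = c("sodium_trajectory", "array"))
}

#' A systolic blood pressure distribution
#'
#' SBP within a stratum is modelled as a normal distribution.
#'
#' @param mean,sd mmHg; `sd` must be positive
#' @return object of class `bp_dist`
#' @export
bp_dist <- function(mean, sd) {
  if (sd <= 0) stop("sd must be positive")
  structure(list(mean = mean, sd = sd), class = "bp_dist")
}

#' Proportion of a cohort above the hypertension threshold
#'
#' @param bp a [bp_dist()]
#' @param threshold mmHg (default 140)
#' @return P(SBP > threshold) under the normal model
#' @export
hypertensive_fraction <- function(bp, threshold = 140) {
  stats::pnorm(threshold, bp$mean, bp$sd, lower.tail = FALSE)
}

#' Mean SBP reduction from a sodium reduction
#'
#' Scales the trial effects linearly in the sodium change relative to the
#' reference reduction (1720 mg/day, i.e. 4.4 g salt), weighting the
#' hypertensive and normotensive effects by the cohort's mass above and below
#' 140 mmHg. The shifted distribution keeps its sd; only the mean moves.
#'
#' @param delta_sodium_mg sodium reduction, mg/day (non-negative)
#' @param bp a [bp_dist()] (baseline distribution used for the split)
#' @param eff effect parameters, see [default_effect_params()]
#' @return mmHg reduction in mean SBP
#' @export
sbp_mean_shift <- function(delta_sodium_mg, bp, eff = default_effect_params()) {
  if (any(delta_sodium_mg < 0)) stop("delta_sodium_mg must be non-negative")
  p_hyp <- hypertensive_fraction(bp, eff$hyp_threshold)
  (delta_sodium_mg / eff$reference_sodium_mg) *
    (p_hyp * eff$effect_hyp + (1 - p_hyp) * eff$effect_norm)
}

# SBP mean shifts for every band/sex over the distinct ramp steps:
# matrix [band, sex, step] where step j corresponds to j-1 annual decrements
# (step 1 = baseline, step ramp_years+1 = full effect, constant thereafter).
shift_steps <- function(B, traj) {
  scn <- attr(traj, "scenario")
  nstep <- scn$ramp_years + 1L
  out <- array(0, c(nrow(B$na), 2, nstep))
  for (k in seq_len(nrow(B$na))) for (s in 1:2) {
    bp <- bp_dist(B$sbp_mean[k, s], B$sbp_sd[k, s])
    delta <- attr(traj, "baseline")[k, s] - traj[k, s, seq_len(nstep)]
    out[k, s, ] <- sbp_mean_shift(delta, bp, B$effects)
  }
  out
}
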