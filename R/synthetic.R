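#' Baseline systolic blood pressure distributions by age and sex
#'
#' The embedded baseline SBP table used by the generator: mean (sd) of
#' measured systolic blood pressure in mmHg for seven ten-year adult age
#' bands by sex, as estimated from the Australian National Health Survey
#' 2017-2018. The model's fifteen five-year bands reuse the value of the
#' ten-year band that contains them; bands above 85 reuse the 85+ values.
#'
#' @return data.frame with columns `age_band` (ten-year label), `sex`,
#'   `sbp_mean`, `sbp_sd`
#' @export
table1_fixture <- function() {
  bands <- c("25-34", "35-44", "45-54", "55-64", "65-74", "75-84", "85+")
  data.frame(
    age_band = rep(bands, times = 2),
    sex = rep(model_sexes(), each = length(bands)),
    sbp_mean = c(120.3, 121.3, 126.5, 132.4, 134.9, 136.5, 140.2,
                 108.5, 112.5, 119.6, 126.8, 133.6, 137.9, 140.8),
    sbp_sd   = c(13.5, 11.6, 17.9, 14.7, 21.3, 20.9, 33.3,
                 15.8, 15.7, 17.0, 20.6, 17.7, 17.0, 28.0),
    stringsAsFactors = FALSE
  )
}

# map a five-year band lower bound to its ten-year fixture band
.fixture_band <- function(age_lower) {
  ifelse(age_lower >= 85, "85+",
         paste0(10 * ((age_lower - 25) %/% 10) + 25,
                "-", 10 * ((age_lower - 25) %/% 10) + 34))
}

#' Generate a synthetic input bundle
#'
#' Produces a complete, internally consistent set of stratified model inputs
#' emulating the Australian data landscape: an adult (25+) population pyramid
#' of about 17 million; Gompertz all-cause mortality with an inflated terminal
#' band so survivorship effectively closes by age 100; age-increasing
#' incidence, prevalence and mortality for the four CKD causes; a midlife-
#' peaked, male-dominant sodium intake pattern rescaled so the population-
#' weighted mean is 3700 mg/day; baseline SBP distributions equal to the
#' embedded survey table ([table1_fixture()]); and per-cause CKD health
#' expenditure. Cause prevalence is obtained by forward-simulating the
#' illness-death process from age 25 under the generated incidence and case
#' fatality, which makes the bundle epidemiologically self-consistent
#' (cause mortality equals case fatality times prevalence).
#'
#' @param seed integer seed; identical seeds give identical bundles
#' @param realism `"smooth"` (default; mild seed-dependent scale jitter) or
#'   `"noisy"` (larger stratum-level perturbation with smooth age wiggle)
#' @return a validated `ckd_bundle`
#' @export
generate_bundle <- function(seed = 1L, realism = c("smooth", "noisy")) {
  realism <- match.arg(realism)
  with_seed(seed, .generate_bundle_impl(seed, realism))
}

.generate_bundle_impl <- function(seed, realism) {
  grid <- model_strata()
  nb <- length(.age_lower)
  mid <- .age_lower + 2.5
  x <- mid - 25
  jit <- function(n, sd) exp(stats::rnorm(n, 0, sd))
  sdj <- if (realism == "noisy") 0.05 else 0.01

  # population pyramid (persons per five-year band, both sexes combined)
  pop_band <- c(1850, 1900, 1800, 1550, 1650, 1500, 1500, 1350,
                1200, 1050, 750, 520, 340, 160, 45) * 1e3
  male_share <- 0.505 - 0.009 * (seq_len(nb) - 1)
  pop <- cbind(male = pop_band * male_share, female = pop_band * (1 - male_share))
  pop <- sweep(pop, 2, jit(2, sdj / 2), `*`)

  # Gompertz all-cause mortality; terminal band inflated to close the cohort
  acm <- cbind(male = 8.0e-4 * exp(0.092 * x) * jit(1, sdj),
               female = 4.2e-4 * exp(0.098 * x) * jit(1, sdj))
  acm[nb, ] <- acm[nb, ] * 1.8

  # background (non-CKD) YLD rate per person
  byld_bg <- cbind(male = 0.088 + 0.0021 * x, female = 0.094 + 0.0021 * x)

  # sodium: midlife-peaked, male > female; rescaled to a 3700 mg/day
  # population-weighted mean
  na <- cbind(male = 4300 - 28 * ((mid - 47.5) / 10)^2,
              female = 3250 - 24 * ((mid - 47.5) / 10)^2)
  na <- sweep(na, 2, jit(2, sdj / 2), `*`)
  na <- na * (3700 / (sum(na * pop) / sum(pop)))

  # SBP distributions fixed to the embedded survey baselines
  fx <- table1_fixture()
  fb <- .fixture_band(.age_lower)
  sbp_mean <- sbp_sd <- matrix(NA_real_, nb, 2, dimnames = list(NULL, model_sexes()))
  for (s in model_sexes()) {
    fxs <- fx[fx$sex == s, ]
    sbp_mean[, s] <- fxs$sbp_mean[match(fb, fxs$age_band)]
    sbp_sd[, s] <- fxs$sbp_sd[match(fb, fxs$age_band)]
  }

  # per-cause hazard curves (per person-year at band midpoints)
  inc_base <- list(htn = 4.2e-4 * exp(0.046 * x), dm = 3.6e-4 * exp(0.043 * x),
                   gmn = 3.2e-4 * exp(0.030 * x), other = 1.15e-3 * exp(0.036 * x))
  cf_base <- list(htn = 7e-4 * exp(0.050 * x), dm = 9e-4 * exp(0.050 * x),
                  gmn = 1.0e-3 * exp(0.045 * x), other = 5e-4 * exp(0.050 * x))
  inc_fem <- c(htn = 0.88, dm = 0.90, gmn = 1.00, other = 1.05)
  p0 <- c(htn = 0.003, dm = 0.003, gmn = 0.004, other = 0.012)
  dw_true <- c(htn = 0.10, dm = 0.13, gmn = 0.15, other = 0.08)
  cost_per_case <- c(htn = 900, dm = 1250, gmn = 1500, other = 650)

  causes <- list()
  yld_sum <- matrix(0, nb, 2, dimnames = list(NULL, model_sexes()))
  for (cause in ckd_causes()) {
    for (s in model_sexes()) {
      fs <- if (s == "female") inc_fem[[cause]] else 1
      i_k <- inc_base[[cause]] * fs * jit(1, sdj)
      f_k <- cf_base[[cause]] * (if (s == "female") 0.9 else 1) * jit(1, sdj)
      if (realism == "noisy") {
        ph <- stats::runif(1, 0, 2 * pi)
        i_k <- i_k * exp(0.02 * sin(seq_len(nb) / 2 + ph))
      }
      # forward illness-death simulation from age 25 -> self-consistent
      # prevalence (proportion of the alive, conditional on other-cause survival)
      pc <- numeric(nb)
      st <- c(S = 1 - p0[[cause]], C = p0[[cause]], Dc = 0)
      for (k in seq_len(nb)) {
        pc[k] <- st[["C"]] / (st[["S"]] + st[["C"]])
        for (cyc in 1:5) st <- disease_cycle(st, i_k[k], f_k[k])
      }
      cc <- grid[grid$sex == s, ]
      cc$cause <- cause
      cc$incidence <- i_k
      cc$prevalence <- pc
      cc$cause_mortality <- f_k * pc
      cc$yld <- dw_true[[cause]] * pc
      cc$cost_total <- cost_per_case[[cause]] * (1 + 0.004 * x) *
        jit(1, sdj) * pc * pop[, s]
      yld_sum[, s] <- yld_sum[, s] + cc$yld
      causes[[paste(cause, s)]] <- cc
    }
  }
  causes <- do.call(rbind, causes)
  rownames(causes) <- NULL

  d <- grid
  d$population <- as.vector(pop)
  d$acm_rate <- as.vector(acm)
  d$all_yld_rate <- as.vector(byld_bg + yld_sum)
  d$sodium_mg <- as.vector(na)
  d$sbp_mean <- as.vector(sbp_mean)
  d$sbp_sd <- as.vector(sbp_sd)

  new_bundle(d, causes, default_effect_params(),
             meta = list(seed = seed, realism = realism))
}
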