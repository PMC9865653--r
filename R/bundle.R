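#' Construct an input bundle
#'
#' An input bundle holds every stratified quantity the model consumes for one
#' run: population counts, all-cause mortality, all-cause YLD rates, mean
#' daily sodium intake, systolic blood pressure (SBP) distributions, and for
#' each CKD cause the incidence, prevalence, cause-specific mortality, YLD
#' rate and annual health expenditure. Bundles are normally produced by
#' [generate_bundle()] or [read_bundle()].
#'
#' @param data data.frame with one row per stratum (`age_group`, `age_lower`,
#'   `sex`) and columns `population`, `acm_rate` (all-cause mortality,
#'   person-year^-1), `all_yld_rate` (per-person YLD), `sodium_mg` (mg/day),
#'   `sbp_mean`, `sbp_sd` (mmHg).
#' @param causes data.frame in long form, one row per stratum x cause, with
#'   columns `age_group`, `age_lower`, `sex`, `cause`, `incidence`
#'   (person-year^-1), `prevalence` (proportion), `cause_mortality`
#'   (person-year^-1), `yld` (per-person), `cost_total` (AUD/year).
#' @param effects an effect-parameter list, see [default_effect_params()].
#' @param uncertainty list of dispersion parameters used by the PSA:
#'   `sodium_se_mg`, `sbp_mean_se_mmhg`, `cost_cv`.
#' @param meta list of provenance fields (at least `seed`, `realism`).
#' @param validate run [validate_bundle()] on the result?
#' @return object of class `ckd_bundle`
#' @export
new_bundle <- function(data, causes, effects, uncertainty = NULL, meta = list(),
                       validate = TRUE) {
  bundle <- structure(
    list(data = data, causes = causes, effects = effects,
         uncertainty = uncertainty %||% default_uncertainty(), meta = meta),
    class = "ckd_bundle"
  )
  if (validate) validate_bundle(bundle)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_uncertainty <- function() {
  list(sodium_se_mg = 75, sbp_mean_se_mmhg = 1.0, cost_cv = 0.10)
}

#' Default sodium-SBP effect and relative-risk parameters
#'
#' The sodium effect on SBP comes from meta-analysis of salt-reduction trials:
#' a 4.4 g/day salt reduction (about 1720 mg sodium) lowers SBP by 5.39
#' (95% CI 4.15-6.62) mmHg in hypertensives (SBP > 140 mmHg) and 2.42
#' (1.29-3.56) mmHg in normotensives. Relative risks of CKD per 10 mmHg of
#' SBP above a theoretical minimum risk exposure level (TMREL) of 115 mmHg
#' are cause-specific with lognormal uncertainty.
#'
#' @return list with elements `effect_hyp`, `effect_hyp_ci`, `effect_norm`,
#'   `effect_norm_ci`, `reference_sodium_mg`, `reference_salt_g`,
#'   `hyp_threshold`, `tmrel`, `rr_unit_mmhg` and `rr` (per-cause list of
#'   `central` and `ci`).
#' @export
default_effect_params <- function() {
  list(
    effect_hyp = 5.39, effect_hyp_ci = c(4.15, 6.62),
    effect_norm = 2.42, effect_norm_ci = c(1.29, 3.56),
    reference_salt_g = 4.4, reference_sodium_mg = 1720,
    hyp_threshold = 140, tmrel = 115, rr_unit_mmhg = 10,
    rr = list(
      htn   = list(central = 1.55, ci = c(1.40, 1.72)),
      dm    = list(central = 1.38, ci = c(1.25, 1.52)),
      gmn   = list(central = 1.30, ci = c(1.16, 1.45)),
      other = list(central = 1.42, ci = c(1.28, 1.58))
    )
  )
}

#' Validate an input bundle
#'
#' Checks the structural and epidemiological invariants: complete 15 x 2
#' stratum grid; all rates non-negative; prevalences in \[0,1\] summing to at
#' most 1 across causes; cause mortality no greater than all-cause mortality;
#' cause YLD no greater than all-cause YLD; positive sodium and SBP sd; and
#' effect-parameter constraints (hypertensive effect > normotensive effect > 0,
#' TMREL below the hypertension threshold, relative risks > 1).
#'
#' @param bundle a `ckd_bundle`
#' @return `TRUE` invisibly; otherwise an error listing every violation
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ckd_bundle"))
  d <- bundle$data
  cs <- bundle$causes
  eff <- bundle$effects
  errs <- character()
  add <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  grid <- model_strata()
  add(nrow(d) == nrow(grid) &&
        all(paste(d$age_lower, d$sex) %in% paste(grid$age_lower, grid$sex)) &&
        !anyDuplicated(paste(d$age_lower, d$sex)),
      "stratum grid must be exactly 15 age bands x 2 sexes")
  add(all(d$population > 0), "population must be positive")
  add(all(d$acm_rate >= 0), "acm_rate must be non-negative")
  add(all(d$all_yld_rate >= 0 & d$all_yld_rate <= 1),
      "all_yld_rate must lie in [0, 1]")
  add(all(d$sodium_mg > 0), "sodium_mg must be positive")
  add(all(d$sbp_sd > 0), "sbp_sd must be positive")

  add(setequal(unique(cs$cause), ckd_causes()) &&
        nrow(cs) == nrow(d) * length(ckd_causes()),
      "causes table must cover every stratum x cause exactly once")
  add(all(cs$incidence >= 0), "incidence must be non-negative")
  add(all(cs$prevalence >= 0 & cs$prevalence <= 1),
      "prevalence must lie in [0, 1]")
  add(all(cs$cause_mortality >= 0), "cause_mortality must be non-negative")
  add(all(cs$yld >= 0), "yld must be non-negative")
  add(all(cs$cost_total >= 0), "cost_total must be non-negative")

  key <- paste(cs$age_lower, cs$sex)
  dkey <- paste(d$age_lower, d$sex)
  psum <- tapply(cs$prevalence, key, sum)
  add(all(psum <= 1 + 1e-12), "per-stratum prevalences must sum to <= 1")
  acm <- d$acm_rate[match(key, dkey)]
  add(all(cs$cause_mortality <= acm + 1e-12),
      "cause_mortality must not exceed all-cause mortality")
  byld <- d$all_yld_rate[match(key, dkey)]
  add(all(cs$yld <= byld + 1e-12),
      "cause yld must not exceed all-cause yld")

  add(eff$effect_hyp > eff$effect_norm && eff$effect_norm > 0,
      "effect_hyp > effect_norm > 0 required")
  add(eff$tmrel < eff$hyp_threshold, "tmrel must be below hyp_threshold")
  add(all(vapply(eff$rr, function(r) r$central > 1, logical(1))),
      "all relative risks must exceed 1")

  if (length(errs)) stop("invalid bundle:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' @export
print.ckd_bundle <- function(x, ...) {
  wmean <- sum(x$data$sodium_mg * x$data$population) / sum(x$data$population)
  cat("<ckd_bundle>\n")
  cat(sprintf("  strata: %d (15 age bands x 2 sexes)\n", nrow(x$data)))
  cat(sprintf("  adult population: %s\n",
              format(round(sum(x$data$population)), big.mark = ",")))
  cat(sprintf("  population-weighted mean sodium: %.0f mg/day\n", wmean))
  cat(sprintf("  CKD causes: %s\n", paste(ckd_causes(), collapse = ", ")))
  if (!is.null(x$meta$seed))
    cat(sprintf("  generator seed: %s (realism: %s)\n",
                x$meta$seed, x$meta$realism %||% "?"))
  invisible(x)
}

# ---- internal array view -------------------------------------------------
# Reshapes a bundle into [band, sex] matrices and [band, sex, cause] arrays
# indexed k = 1..15, s = 1..2 (male, female), d = 1..4. All model internals
# run on this view.
as_model_arrays <- function(bundle) {
  d <- bundle$data
  cs <- bundle$causes
  nb <- length(.age_lower)
  sx <- model_sexes()
  cz <- ckd_causes()
  idx <- function(df) cbind(match(df$age_lower, .age_lower), match(df$sex, sx))
  m <- function(col) {
    out <- matrix(NA_real_, nb, 2, dimnames = list(age_band_label(.age_lower), sx))
    out[idx(d)] <- d[[col]]
    out
  }
  a <- function(col) {
    out <- array(NA_real_, c(nb, 2, 4),
                 dimnames = list(age_band_label(.age_lower), sx, cz))
    out[cbind(idx(cs), match(cs$cause, cz))] <- cs[[col]]
    out
  }
  list(
    pop = m("population"), acm = m("acm_rate"), byld = m("all_yld_rate"),
    na = m("sodium_mg"), sbp_mean = m("sbp_mean"), sbp_sd = m("sbp_sd"),
    inc = a("incidence"), prev = a("prevalence"), mort = a("cause_mortality"),
    yld = a("yld"), cost = a("cost_total"),
    effects = bundle$effects
  )
}

# ---- serialization -------------------------------------------------------

#' Write a bundle to a directory of CSV files
#'
#' One CSV per quantity (columns `age_group`, `sex`, `value`; per-cause
#' quantities get one file per cause) plus `metadata.json` holding the effect
#' parameters, uncertainty specification and generator provenance. Values are
#' written at full double precision so that [read_bundle()] round-trips
#' losslessly.
#'
#' @param bundle a `ckd_bundle`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- bundle$data
  w <- function(df, value, file) {
    out <- data.frame(age_group = df$age_group, sex = df$sex,
                      value = sprintf("%.17g", value))
    utils::write.csv(out, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  for (q in c("population", "acm_rate", "all_yld_rate", "sodium_mg",
              "sbp_mean", "sbp_sd"))
    w(d, d[[q]], paste0(q, ".csv"))
  for (cause in ckd_causes()) {
    cc <- bundle$causes[bundle$causes$cause == cause, ]
    for (q in c("incidence", "prevalence", "cause_mortality", "yld", "cost_total"))
      w(cc, cc[[q]], paste0(q, "_", cause, ".csv"))
  }
  meta <- list(effects = bundle$effects, uncertainty = bundle$uncertainty,
               meta = bundle$meta)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the CSV files and `metadata.json`
#' @return a validated `ckd_bundle`
#' @export
read_bundle <- function(dir) {
  r <- function(file) {
    df <- utils::read.csv(file.path(dir, file), colClasses =
                            c(age_group = "character", sex = "character",
                              value = "character"))
    df$value <- as.numeric(df$value)
    df
  }
  base <- r("population.csv")
  key <- function(df) paste(df$age_group, df$sex)
  d <- data.frame(age_group = base$age_group,
                  age_lower = as.integer(sub("-.*", "", base$age_group)),
                  sex = base$sex, stringsAsFactors = FALSE)
  for (q in c("population", "acm_rate", "all_yld_rate", "sodium_mg",
              "sbp_mean", "sbp_sd")) {
    df <- r(paste0(q, ".csv"))
    d[[q]] <- df$value[match(key(d), key(df))]
  }
  cl <- list()
  for (cause in ckd_causes()) {
    cc <- d[c("age_group", "age_lower", "sex")]
    cc$cause <- cause
    for (q in c("incidence", "prevalence", "cause_mortality", "yld", "cost_total")) {
      df <- r(paste0(q, "_", cause, ".csv"))
      cc[[q]] <- df$value[match(key(cc), key(df))]
    }
    cl[[cause]] <- cc
  }
  causes <- do.call(rbind, cl)
  rownames(causes) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  eff <- meta$effects
  eff$rr <- lapply(eff$rr, function(r) list(central = r$central,
                                            ci = as.numeric(r$ci)))
  new_bundle(d, causes, eff, uncertainty = meta$uncertainty,
             meta = meta$meta %||% list())
}
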