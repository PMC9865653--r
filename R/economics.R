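#' Annual per-capita CKD costs by stratum and cause
#'
#' Divides the total annual health spending for each CKD cause by the
#' corresponding prevalent cases (prevalence x population) in each stratum.
#'
#' @param bundle a `ckd_bundle`
#' @return data.frame `age_group`, `age_lower`, `sex`, `cause`,
#'   `per_capita_cost` (AUD per prevalent case per year; 0 where spending is 0)
#' @export
per_capita_costs <- function(bundle) {
  B <- as_model_arrays(bundle)
  arr <- cost_pc_array(B)
  grid <- model_strata()
  out <- do.call(rbind, lapply(ckd_causes(), function(cause) {
    g <- grid
    g$cause <- cause
    g$per_capita_cost <- as.vector(arr[, , cause])
    g
  }))
  rownames(out) <- NULL
  out
}

cost_pc_array <- function(B) {
  cases <- sweep(B$prev, c(1, 2), B$pop, `*`)
  bad <- B$cost > 0 & cases <= 0
  if (any(bad)) {
    ix <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("spending with zero prevalent cases in stratum %s/%s, cause %s",
                 dimnames(B$cost)[[1]][ix[1]], model_sexes()[ix[2]],
                 ckd_causes()[ix[3]]))
  }
  ifelse(cases > 0, B$cost / cases, 0)
}

#' Discount to present value
#'
#' @param amount AUD or HALYs (vectorised)
#' @param year calendar year the amount accrues in (vectorised)
#' @param rate annual discount rate (e.g. 0.03)
#' @param base_year first model year; amounts in the base year are undiscounted
#' @return present value at `base_year`
#' @export
discount <- function(amount, year, rate, base_year = 2019) {
  if (any(year < base_year)) stop("year must not precede base_year")
  amount / (1 + rate) ^ (year - base_year)
}

#' Healthcare-cost offsets from prevented CKD prevalence
#'
#' Multiplies the per-stratum, per-cause reduction in prevalent cases
#' (business-as-usual minus intervention, counted at each cycle start and
#' costed for the full year) by the annual per-capita cost, discounted to the
#' base year.
#'
#' @param bundle a `ckd_bundle`
#' @param disease combined [run_disease()] output for all four causes
#' @param lifetable output of [run_lifetable()] (supplies survivorship used
#'   to scale submodel proportions to population counts)
#' @param rate annual discount rate for costs (default 0.03)
#' @param base_year base year (default 2019)
#' @return data.frame per `year`, `sex`, `cause`: `cases_averted` and
#'   discounted `savings` (AUD)
#' @export
cost_offsets <- function(bundle, disease, lifetable, rate = 0.03,
                         base_year = 2019) {
  B <- as_model_arrays(bundle)
  cpc <- cost_pc_array(B)
  nest <- .disease_nest(disease)
  rows <- list()
  for (s in 1:2) {
    sex <- model_sexes()[s]
    for (k0 in seq_along(.age_lower)) {
      ag <- age_band_label(.age_lower[k0])
      cohort <- nest[[sex]][[ag]]
      if (is.null(cohort)) next
      T <- 100L - .age_lower[k0]
      band_t <- pmin(length(.age_lower), k0 + (seq_len(T) - 1L) %/% 5L)
      lt <- lifetable[lifetable$sex == sex & lifetable$age_group == ag, ]
      l0 <- lt$l[lt$arm == "bau"][order(lt$year[lt$arm == "bau"])]
      l1 <- lt$l[lt$arm == "int"][order(lt$year[lt$arm == "int"])]
      N <- B$pop[k0, s]
      years <- base_year + seq_len(T) - 1L
      for (cause in ckd_causes()) {
        a <- cohort[[cause]]
        pc0 <- a$bau$C / (a$bau$S + a$bau$C)
        pc1 <- a$int$C / (a$int$S + a$int$C)
        averted <- N * (l0 * pc0 - l1 * pc1)
        cc <- cpc[cbind(band_t, s, match(cause, ckd_causes()))]
        rows[[length(rows) + 1L]] <- data.frame(
          year = years, sex = sex, cause = cause, cases_averted = averted,
          savings = discount(averted * cc, years, rate, base_year),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(cases_averted, savings) ~ year + sex + cause,
                          out, sum)
  agg[order(agg$year, agg$sex, agg$cause), ]
}
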