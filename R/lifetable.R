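#' Cause-specific disability weights
#'
#' The crude disability weight per cause is the per-person cause YLD rate
#' divided by cause prevalence. It is corrected for disability from background
#' (non-CKD) health conditions so that the weight represents the marginal
#' disability averted per prevalent case prevented: with
#' `bYLD_other = all_yld_rate - sum of cause ylds`, the multiplicative
#' correction gives `dw_adj = dw_crude * (1 - bYLD_other)`; an alternative
#' subtractive form `dw_adj = max(0, dw_crude - bYLD_other)` is available.
#'
#' @param bundle a `ckd_bundle`
#' @param correction `"multiplicative"` (default) or `"subtractive"`
#' @return data.frame `age_group`, `age_lower`, `sex`, `cause`, `dw_crude`,
#'   `dw_adj`, `byld_other`
#' @export
disability_weights <- function(bundle, correction = c("multiplicative", "subtractive")) {
  correction <- match.arg(correction)
  B <- as_model_arrays(bundle)
  arr <- dw_arrays(B, correction)
  grid <- model_strata()
  out <- do.call(rbind, lapply(ckd_causes(), function(cause) {
    g <- grid
    g$cause <- cause
    g$dw_crude <- as.vector(arr$crude[, , cause])
    g$dw_adj <- as.vector(arr$adj[, , cause])
    g$byld_other <- as.vector(arr$byld_other)
    g
  }))
  rownames(out) <- NULL
  out
}

dw_arrays <- function(B, correction = "multiplicative") {
  if (any(B$yld > 0 & B$prev <= 0))
    stop("cause yld positive where prevalence is zero")
  crude <- ifelse(B$prev > 0, B$yld / B$prev, 0)
  if (any(crude > 1 + 1e-12))
    stop("crude disability weight exceeds 1: inconsistent yld/prevalence inputs")
  byld_other <- B$byld - apply(B$yld, c(1, 2), sum)
  byld_other <- pmax(byld_other, 0)
  adj <- if (correction == "multiplicative")
    sweep(crude, c(1, 2), 1 - byld_other, `*`)
  else pmax(sweep(crude, c(1, 2), byld_other, `-`), 0)
  list(crude = crude, adj = adj, byld_other = byld_other)
}

# lifetable for one cohort given per-cycle quantities.
# M0: BAU all-cause mortality rate per cycle; ddiff: per-cycle sum over causes
# of (BAU - intervention) cause-death flows; byld_t: background all-cause YLD
# by cycle; wdiff: per-cycle sum of dw_adj * (prevalence_bau - prevalence_int).
cohort_lifetable <- function(M0, ddiff, byld_t, wdiff) {
  M1 <- M0 - ddiff
  if (any(M1 < 0)) stop("negative all-cause mortality after cause adjustment")
  l0 <- c(1, cumprod(exp(-M0)))
  l1 <- c(1, cumprod(exp(-M1)))
  T <- length(M0)
  L0 <- (l0[1:T] + l0[2:(T + 1)]) / 2
  L1 <- (l1[1:T] + l1[2:(T + 1)]) / 2
  w0 <- 1 - byld_t
  w1 <- w0 + wdiff
  list(l0 = l0, l1 = l1, L0 = L0, L1 = L1, w0 = w0, w1 = w1, M0 = M0, M1 = M1)
}

# regroup a combined run_disease() frame (all four causes) into per-cohort
# per-arm vectors: list[[sex]][[age_group]][[cause]][[arm]]
.disease_nest <- function(disease) {
  need <- c("year", "age_group", "sex", "cause", "arm", "S", "C", "Dc",
            "incident_flow", "death_flow")
  stopifnot(all(need %in% names(disease)))
  out <- list()
  sp <- split(disease, paste(disease$sex, disease$age_group, disease$cause,
                             disease$arm, sep = "\r"))
  for (nm in names(sp)) {
    g <- sp[[nm]]
    g <- g[order(g$year), ]
    key <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    out[[key[1]]][[key[2]]][[key[3]]][[key[4]]] <-
      list(S = g$S, C = g$C, Dc = g$Dc, iflow = g$incident_flow,
           dflow = g$death_flow)
  }
  out
}

#' Build cohort lifetables from disease-submodel output
#'
#' Recomputes all-cause mortality in the intervention arm by subtracting the
#' per-cause reductions in death flows from business-as-usual mortality,
#' accumulates survivorship (`l`), person-years (`L`, trapezoid) and the
#' HALY weight `w` (1 minus all-cause YLD in the BAU arm; the intervention
#' arm adds the disability averted through lower CKD prevalence), and scales
#' by cohort population to HALYs. Cohorts are simulated to age 100.
#'
#' @param bundle a `ckd_bundle`
#' @param disease combined output of [run_disease()] for all four causes
#'   (both arms)
#' @param correction background-disability correction, see
#'   [disability_weights()]
#' @return tidy data.frame: `year`, `age_group` (2019 cohort band), `sex`,
#'   `arm`, `l`, `L`, `w`, `HALY`
#' @export
run_lifetable <- function(bundle, disease, correction = "multiplicative") {
  B <- as_model_arrays(bundle)
  dw <- dw_arrays(B, correction)$adj
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
      ddiff <- wdiff <- numeric(T)
      for (cause in ckd_causes()) {
        a <- cohort[[cause]]
        pc0 <- a$bau$C / (a$bau$S + a$bau$C)
        pc1 <- a$int$C / (a$int$S + a$int$C)
        ddiff <- ddiff + (a$bau$dflow - a$int$dflow)
        wdiff <- wdiff + dw[cbind(band_t, s, match(cause, ckd_causes()))] *
          (pc0 - pc1)
      }
      lt <- cohort_lifetable(B$acm[band_t, s], ddiff, B$byld[band_t, s], wdiff)
      N <- B$pop[k0, s]
      for (arm in c("bau", "int")) {
        L <- if (arm == "bau") lt$L0 else lt$L1
        w <- if (arm == "bau") lt$w0 else lt$w1
        l <- if (arm == "bau") lt$l0 else lt$l1
        rows[[length(rows) + 1L]] <- data.frame(
          year = 2019L + seq_len(T) - 1L, age_group = ag, sex = sex, arm = arm,
          l = l[seq_len(T)], L = L, w = w, HALY = N * L * w,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decompose total HALY gains by CKD cause
#'
#' The morbidity component of each cause is attributed directly
#' (averted prevalence x adjusted disability weight x person-years x cohort
#' population); the remaining, mortality-driven life-year gain is allocated
#' to causes in proportion to each cause's cumulative reduction in cause
#' deaths. Components sum to the total HALY gain by construction.
#'
#' @inheritParams run_lifetable
#' @param lifetable output of [run_lifetable()]
#' @return data.frame per cause: `morbidity_haly`, `mortality_haly`,
#'   `total_haly`, `share` (fraction of the total gain)
#' @export
decompose_haly_by_cause <- function(bundle, disease, lifetable,
                                    correction = "multiplicative") {
  B <- as_model_arrays(bundle)
  dw <- dw_arrays(B, correction)$adj
  nest <- .disease_nest(disease)
  total_gain <- sum(lifetable$HALY[lifetable$arm == "int"]) -
    sum(lifetable$HALY[lifetable$arm == "bau"])
  morb <- deaths_averted <- stats::setNames(numeric(4), ckd_causes())
  for (s in 1:2) {
    sex <- model_sexes()[s]
    for (k0 in seq_along(.age_lower)) {
      ag <- age_band_label(.age_lower[k0])
      cohort <- nest[[sex]][[ag]]
      if (is.null(cohort)) next
      T <- 100L - .age_lower[k0]
      band_t <- pmin(length(.age_lower), k0 + (seq_len(T) - 1L) %/% 5L)
      lt <- lifetable[lifetable$sex == sex & lifetable$age_group == ag, ]
      L1 <- lt$L[lt$arm == "int"][order(lt$year[lt$arm == "int"])]
      l0 <- lt$l[lt$arm == "bau"][order(lt$year[lt$arm == "bau"])]
      N <- B$pop[k0, s]
      for (cause in ckd_causes()) {
        a <- cohort[[cause]]
        pc0 <- a$bau$C / (a$bau$S + a$bau$C)
        pc1 <- a$int$C / (a$int$S + a$int$C)
        morb[cause] <- morb[cause] +
          sum(N * L1 * dw[cbind(band_t, s, match(cause, ckd_causes()))] *
                (pc0 - pc1))
        af0 <- a$bau$S + a$bau$C
        deaths_averted[cause] <- deaths_averted[cause] +
          sum(N * l0 * (a$bau$dflow - a$int$dflow) / af0)
      }
    }
  }
  mort_total <- total_gain - sum(morb)
  wts <- if (sum(deaths_averted) > 0) deaths_averted / sum(deaths_averted)
         else rep(0, 4)
  mort <- mort_total * wts
  data.frame(
    cause = ckd_causes(), morbidity_haly = unname(morb),
    mortality_haly = unname(mort), total_haly = unname(morb + mort),
    share = if (abs(total_gain) > 0) unname((morb + mort) / total_gain)
            else rep(0, 4),
    stringsAsFactors = FALSE)
}
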