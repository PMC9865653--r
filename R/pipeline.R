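#' Run the full PMSLT pipeline for one scenario
#'
#' Chains every stage: sodium trajectory, SBP shifts with the
#' hypertensive/normotensive split, potential impact fractions per cause,
#' the four illness-death submodels (business-as-usual and intervention arms
#' simulated simultaneously for every age-sex cohort to age 100), the
#' coupled lifetable, HALY accounting and discounted healthcare-cost offsets.
#'
#' @param bundle a `ckd_bundle`
#' @param scn a `sodium_scenario`
#' @param discount_haly annual discount rate for HALYs (default 0)
#' @param discount_cost annual discount rate for costs (default 0.03)
#' @param cf_method case-fatality derivation, `"ode_consistent"` (default)
#'   or `"ratio"`
#' @param stratum_cap see [build_trajectory()]
#' @param correction background-disability correction, see
#'   [disability_weights()]
#' @return object of class `scenario_result` with elements
#'   \describe{
#'     \item{summary}{data.frame per horizon (`"2030"`, `"lifetime"`) and sex
#'       (male, female, total): cumulative incident cases averted (absolute
#'       and % of BAU), CKD deaths averted (absolute and %), HALYs gained and
#'       discounted savings (AUD)}
#'     \item{by_cause}{data.frame per horizon and cause: incident cases and
#'       deaths averted, morbidity/mortality/total HALY components and share
#'       of the total gain}
#'     \item{annual}{data.frame per year and sex with both arms' cumulative
#'       building blocks (incident cases, cause deaths, HALYs, undiscounted
#'       savings)}
#'   }
#' @export
run_scenario <- function(bundle, scn, discount_haly = 0, discount_cost = 0.03,
                         cf_method = "ode_consistent", stratum_cap = FALSE,
                         correction = "multiplicative") {
  B <- as_model_arrays(bundle)
  cf <- cf_array(B, cf_method)
  traj <- build_trajectory(bundle, scn, stratum_cap = stratum_cap)
  pif <- compute_pif_array(bundle, traj)
  dw <- dw_arrays(B, correction)$adj
  cpc <- cost_pc_array(B)
  base_year <- scn$start_year
  nb <- length(.age_lower)
  ny <- 100L - .age_lower[1]              # annual cycles until the youngest
  years <- base_year + seq_len(ny) - 1L   # cohort reaches age 100

  tot_names <- c("inc0", "inc1", "dth0", "dth1", "haly0", "haly1")
  tot <- array(0, c(ny, 2, length(tot_names)),
               dimnames = list(years, model_sexes(), tot_names))
  byc_names <- c("inc_av", "dth_av", "morb_haly", "savings")
  byc <- array(0, c(ny, 2, 4, length(byc_names)),
               dimnames = list(years, model_sexes(), ckd_causes(), byc_names))

  for (s in 1:2) for (k0 in seq_len(nb)) {
    T <- 100L - .age_lower[k0]
    tt <- seq_len(T)
    band_t <- pmin(nb, k0 + (tt - 1L) %/% 5L)
    N <- B$pop[k0, s]
    sims <- lapply(seq_len(4), function(d) {
      list(bau = simulate_cohort_cause(B$prev[k0, s, d], k0, T, B$inc[, s, d],
                                       cf[, s, d], 0),
           int = simulate_cohort_cause(B$prev[k0, s, d], k0, T, B$inc[, s, d],
                                       cf[, s, d], pif[k0, s, d, ]))
    })
    ddiff <- wdiff <- numeric(T)
    pc <- list()
    for (d in seq_len(4)) {
      a <- sims[[d]]
      pc[[d]] <- list(bau = a$bau$C[tt] / (a$bau$S[tt] + a$bau$C[tt]),
                      int = a$int$C[tt] / (a$int$S[tt] + a$int$C[tt]))
      ddiff <- ddiff + (a$bau$dflow - a$int$dflow)
      wdiff <- wdiff + dw[cbind(band_t, s, d)] * (pc[[d]]$bau - pc[[d]]$int)
    }
    lt <- cohort_lifetable(B$acm[band_t, s], ddiff, B$byld[band_t, s], wdiff)
    tot[tt, s, "haly0"] <- tot[tt, s, "haly0"] + N * lt$L0 * lt$w0
    tot[tt, s, "haly1"] <- tot[tt, s, "haly1"] + N * lt$L1 * lt$w1
    for (d in seq_len(4)) {
      a <- sims[[d]]
      af0 <- a$bau$S[tt] + a$bau$C[tt]
      af1 <- a$int$S[tt] + a$int$C[tt]
      inc0 <- N * lt$l0[tt] * a$bau$iflow / af0
      inc1 <- N * lt$l1[tt] * a$int$iflow / af1
      dth0 <- N * lt$l0[tt] * a$bau$dflow / af0
      dth1 <- N * lt$l1[tt] * a$int$dflow / af1
      tot[tt, s, "inc0"] <- tot[tt, s, "inc0"] + inc0
      tot[tt, s, "inc1"] <- tot[tt, s, "inc1"] + inc1
      tot[tt, s, "dth0"] <- tot[tt, s, "dth0"] + dth0
      tot[tt, s, "dth1"] <- tot[tt, s, "dth1"] + dth1
      byc[tt, s, d, "inc_av"] <- byc[tt, s, d, "inc_av"] + (inc0 - inc1)
      byc[tt, s, d, "dth_av"] <- byc[tt, s, d, "dth_av"] + (dth0 - dth1)
      byc[tt, s, d, "morb_haly"] <- byc[tt, s, d, "morb_haly"] +
        N * lt$L1 * dw[cbind(band_t, s, d)] * (pc[[d]]$bau - pc[[d]]$int)
      byc[tt, s, d, "savings"] <- byc[tt, s, d, "savings"] +
        N * (lt$l0[tt] * pc[[d]]$bau - lt$l1[tt] * pc[[d]]$int) *
          cpc[cbind(band_t, s, d)]
    }
  }

  dfac_h <- (1 + discount_haly) ^ -(seq_len(ny) - 1L)
  dfac_c <- (1 + discount_cost) ^ -(seq_len(ny) - 1L)
  horizons <- list("2030" = seq_len(scn$ramp_years + 1L), lifetime = seq_len(ny))

  summary <- do.call(rbind, lapply(names(horizons), function(h) {
    idx <- horizons[[h]]
    per_sex <- function(sx) {
      inc0 <- sum(tot[idx, sx, "inc0"]); inc1 <- sum(tot[idx, sx, "inc1"])
      dth0 <- sum(tot[idx, sx, "dth0"]); dth1 <- sum(tot[idx, sx, "dth1"])
      haly <- sum((tot[idx, sx, "haly1"] - tot[idx, sx, "haly0"]) * dfac_h[idx])
      sav <- sum(apply(byc[idx, sx, , "savings", drop = FALSE], 1, sum) *
                   dfac_c[idx])
      data.frame(
        scenario = scn$name, horizon = h,
        sex = if (length(sx) == 2) "total" else model_sexes()[sx],
        incident_averted = inc0 - inc1,
        incident_averted_pct = 100 * (inc0 - inc1) / inc0,
        deaths_averted = dth0 - dth1,
        deaths_averted_pct = 100 * (dth0 - dth1) / dth0,
        haly_gained = haly, savings_aud = sav, stringsAsFactors = FALSE)
    }
    rbind(per_sex(1), per_sex(2), per_sex(1:2))
  }))

  by_cause <- do.call(rbind, lapply(names(horizons), function(h) {
    idx <- horizons[[h]]
    total_gain <- sum((tot[idx, , "haly1"] - tot[idx, , "haly0"]) * dfac_h[idx])
    morb <- vapply(seq_len(4), function(d)
      sum(sweep(byc[idx, , d, "morb_haly", drop = FALSE], 1,
                dfac_h[idx], `*`)), numeric(1))
    dth_av <- vapply(seq_len(4), function(d)
      sum(byc[idx, , d, "dth_av"]), numeric(1))
    inc_av <- vapply(seq_len(4), function(d)
      sum(byc[idx, , d, "inc_av"]), numeric(1))
    mort_total <- total_gain - sum(morb)
    wts <- if (sum(dth_av) > 0) dth_av / sum(dth_av) else rep(0, 4)
    haly <- morb + mort_total * wts
    data.frame(
      scenario = scn$name, horizon = h, cause = ckd_causes(),
      incident_averted = inc_av, deaths_averted = dth_av,
      morbidity_haly = morb, mortality_haly = mort_total * wts,
      total_haly = haly,
      share = if (abs(total_gain) > 0) haly / total_gain else rep(0, 4),
      stringsAsFactors = FALSE)
  }))

  annual <- do.call(rbind, lapply(1:2, function(sx) {
    data.frame(year = years, sex = model_sexes()[sx],
               incident_bau = tot[, sx, "inc0"],
               incident_int = tot[, sx, "inc1"],
               deaths_bau = tot[, sx, "dth0"], deaths_int = tot[, sx, "dth1"],
               haly_bau = tot[, sx, "haly0"], haly_int = tot[, sx, "haly1"],
               savings_undiscounted = apply(byc[, sx, , "savings"], 1, sum),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(by_cause) <- rownames(annual) <- NULL

  structure(
    list(scenario = scn, summary = summary, by_cause = by_cause,
         annual = annual,
         settings = list(discount_haly = discount_haly,
                         discount_cost = discount_cost,
                         cf_method = cf_method, correction = correction,
                         population_2019 = sum(B$pop))),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$scenario$name))
  tot <- x$summary[x$summary$sex == "total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf(
      "  %-8s incident averted %10.0f (%.1f%%) | deaths averted %8.0f (%.1f%%) | HALYs %10.0f | savings AUD %12.0f\n",
      tot$horizon[i], tot$incident_averted[i], tot$incident_averted_pct[i],
      tot$deaths_averted[i], tot$deaths_averted_pct[i],
      tot$haly_gained[i], tot$savings_aud[i]))
  invisible(x)
}

# headline metrics used by the PSA and the acceptance script
result_metrics <- function(res) {
  s <- res$summary[res$summary$sex == "total", ]
  g <- function(h, col) s[[col]][s$horizon == h]
  c(incident_averted_2030 = g("2030", "incident_averted"),
    incident_averted_lifetime = g("lifetime", "incident_averted"),
    deaths_averted_2030 = g("2030", "deaths_averted"),
    deaths_averted_lifetime = g("lifetime", "deaths_averted"),
    haly_2030 = g("2030", "haly_gained"),
    haly_lifetime = g("lifetime", "haly_gained"),
    savings_2030 = g("2030", "savings_aud"),
    savings_lifetime = g("lifetime", "savings_aud"))
}

#' Run every scenario of a configuration
#'
#' @param bundle a `ckd_bundle`
#' @param scenarios named list of `sodium_scenario`s (default:
#'   [default_scenarios()]); names must be unique
#' @param out_dir optional directory; if given, writes `results.csv`,
#'   `results_by_cause.csv`, `results.json` and `run.log`
#' @param ... passed to [run_scenario()]
#' @return object of class `results_table`: list with combined `summary` and
#'   `by_cause` data.frames and the per-scenario `results`
#' @export
run_all <- function(bundle, scenarios = default_scenarios(), out_dir = NULL,
                    ...) {
  stopifnot(!anyDuplicated(names(scenarios)))
  results <- lapply(scenarios, function(scn) run_scenario(bundle, scn, ...))
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  by_cause <- do.call(rbind, lapply(results, `[[`, "by_cause"))
  rownames(summary) <- rownames(by_cause) <- NULL
  out <- structure(list(summary = summary, by_cause = by_cause,
                        results = results),
                   class = "results_table")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(by_cause, file.path(out_dir, "results_by_cause.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary, by_cause = by_cause),
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    log <- c(sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("package version: %s",
                     as.character(utils::packageVersion("sodiumCKD"))),
             sprintf("bundle seed: %s", bundle$meta$seed %||% "external"),
             sprintf("scenarios: %s", paste(names(scenarios), collapse = ", ")),
             sprintf("settings: %s",
                     jsonlite::toJSON(results[[1]]$settings, auto_unbox = TRUE)))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.results_table <- function(x, ...) {
  cat("<results_table>\n")
  for (r in x$results) print(r)
  invisible(x)
}
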