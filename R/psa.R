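#' Lognormal parameters matching a 95% interval
#'
#' Parameterises a lognormal so its 2.5th and 97.5th quantiles equal the
#' given bounds: `meanlog = (log lower + log upper)/2`,
#' `sdlog = (log upper - log lower)/(2 z_0.975)`. A degenerate interval
#' (`lower == upper`) gives `sdlog = 0` (constant draws).
#'
#' @param lower,upper positive 95% CI bounds
#' @return list `meanlog`, `sdlog`
#' @export
lognormal_from_ci <- function(lower, upper) {
  if (upper < lower) stop("CI bounds inverted")
  stopifnot(lower > 0)
  list(meanlog = (log(lower) + log(upper)) / 2,
       sdlog = (log(upper) - log(lower)) / (2 * stats::qnorm(0.975)))
}

#' Normal standard deviation implied by a 95% interval
#' @param lower,upper 95% CI bounds
#' @return sd; 0 for a degenerate interval
#' @export
normal_sd_from_ci <- function(lower, upper) {
  if (upper < lower) stop("CI bounds inverted")
  (upper - lower) / (2 * stats::qnorm(0.975))
}

#' Gamma parameters matching a mean and standard deviation
#' @param mean,sd mean > 0; sd >= 0 (0 gives constant draws)
#' @return list `shape`, `rate` (`NULL` when degenerate)
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(shape = NULL, rate = NULL))
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Configure a probabilistic sensitivity analysis
#'
#' Captures the sampling distributions stated for the model inputs: sodium
#' intake (normal), SBP means (normal), relative risks (lognormal,
#' quantile-matched to their CIs), the sodium-BP effects (normal, from their
#' trial CIs) and costs (gamma, mean 1 multiplier with the bundle's cost CV).
#' One draw of each parameter applies to all strata (fully correlated across
#' age and sex), reflecting that these are survey- or meta-analysis-level
#' uncertainties. Draws are a deterministic function of `(seed, draw index)`.
#'
#' @param bundle a `ckd_bundle` (supplies CIs and dispersion settings)
#' @param n_draws number of Monte Carlo draws (default 2000)
#' @param seed RNG seed for the draw stream
#' @param scale multiplier applied to every dispersion parameter (0 makes all
#'   distributions degenerate: every draw equals the point estimate)
#' @return object of class `psa_config`
#' @export
psa_config <- function(bundle, n_draws = 2000L, seed = 1L, scale = 1) {
  stopifnot(n_draws >= 2, scale >= 0)
  eff <- bundle$effects
  unc <- bundle$uncertainty
  spec <- list(
    effect_hyp = list(mean = eff$effect_hyp,
                      sd = scale * normal_sd_from_ci(eff$effect_hyp_ci[1],
                                                     eff$effect_hyp_ci[2])),
    effect_norm = list(mean = eff$effect_norm,
                       sd = scale * normal_sd_from_ci(eff$effect_norm_ci[1],
                                                      eff$effect_norm_ci[2])),
    # centre each RR lognormal on its central value (the median); the CI
    # supplies the log-scale width, so degenerate draws equal the point
    # estimate and the 2.5/97.5 quantiles match the CI wherever the CI is
    # log-symmetric about the central value
    rr = lapply(eff$rr, function(r) {
      list(meanlog = log(r$central),
           sdlog = scale * lognormal_from_ci(r$ci[1], r$ci[2])$sdlog)
    }),
    sodium_se_mg = scale * unc$sodium_se_mg,
    sbp_se_mmhg = scale * unc$sbp_mean_se_mmhg,
    cost_cv = scale * unc$cost_cv
  )
  draw_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_draws))
  structure(list(n_draws = as.integer(n_draws), seed = seed, spec = spec,
                 draw_seeds = draw_seeds),
            class = "psa_config")
}

#' Draw one perturbed parameter set
#'
#' @param config a [psa_config()]
#' @param draw_index draw number in `1 ... n_draws`
#' @return named list: `effect_hyp`, `effect_norm`, `rr` (per-cause), additive
#'   `sodium_shift_mg` and `sbp_shift_mmhg`, and per-cause `cost_mult`
#' @export
draw_parameters <- function(config, draw_index) {
  stopifnot(draw_index >= 1, draw_index <= config$n_draws)
  sp <- config$spec
  with_seed(config$draw_seeds[draw_index], {
    gm <- gamma_from_mean_sd(1, max(sp$cost_cv, 0))
    list(
      effect_hyp = stats::rnorm(1, sp$effect_hyp$mean, sp$effect_hyp$sd),
      effect_norm = stats::rnorm(1, sp$effect_norm$mean, sp$effect_norm$sd),
      rr = vapply(sp$rr, function(r) stats::rlnorm(1, r$meanlog, r$sdlog),
                  numeric(1)),
      sodium_shift_mg = stats::rnorm(1, 0, sp$sodium_se_mg),
      sbp_shift_mmhg = stats::rnorm(1, 0, sp$sbp_se_mmhg),
      cost_mult = if (is.null(gm$shape)) stats::setNames(rep(1, 4), ckd_causes())
                  else stats::setNames(stats::rgamma(4, gm$shape, gm$rate),
                                       ckd_causes())
    )
  })
}

# apply one parameter draw to a bundle (with invariant-preserving clamps)
apply_draw <- function(bundle, draw) {
  b <- bundle
  b$data$sodium_mg <- pmax(b$data$sodium_mg + draw$sodium_shift_mg, 1)
  b$data$sbp_mean <- b$data$sbp_mean + draw$sbp_shift_mmhg
  eff <- b$effects
  eff$effect_hyp <- max(draw$effect_hyp, 1e-6)
  eff$effect_norm <- min(max(draw$effect_norm, 1e-6), eff$effect_hyp - 1e-9)
  for (cause in ckd_causes())
    eff$rr[[cause]]$central <- max(draw$rr[[cause]], 1 + 1e-9)
  b$effects <- eff
  for (cause in ckd_causes()) {
    sel <- b$causes$cause == cause
    b$causes$cost_total[sel] <- b$causes$cost_total[sel] * draw$cost_mult[[cause]]
  }
  b
}

#' Probabilistic sensitivity analysis for one scenario
#'
#' Reruns the full pipeline for each parameter draw and summarises the
#' headline outputs (incident cases and deaths averted, HALYs, savings; 2030
#' and lifetime horizons) as the mean and empirical 2.5th/97.5th percentiles.
#' Using the same `config` for several scenarios gives common random numbers
#' across scenarios. Failed draws are recorded and excluded; more than 1%
#' failures aborts.
#'
#' @param bundle a `ckd_bundle`
#' @param scn a `sodium_scenario`
#' @param config a [psa_config()]
#' @param cf_method case-fatality derivation used inside the PSA
#'   (default `"ratio"` for tractability)
#' @param ... further arguments to [run_scenario()]
#' @return object of class `psa_result`: `summary` data.frame (`metric`,
#'   `point`, `mean`, `lo`, `hi`), the `draws` matrix, and `n_failed`
#' @export
run_psa <- function(bundle, scn, config, cf_method = "ratio", ...) {
  point <- result_metrics(run_scenario(bundle, scn, cf_method = cf_method, ...))
  draws <- matrix(NA_real_, config$n_draws, length(point),
                  dimnames = list(NULL, names(point)))
  failed <- 0L
  for (j in seq_len(config$n_draws)) {
    pb <- apply_draw(bundle, draw_parameters(config, j))
    m <- tryCatch(result_metrics(run_scenario(pb, scn, cf_method = cf_method,
                                              ...)),
                  error = function(e) NULL)
    if (is.null(m)) failed <- failed + 1L else draws[j, ] <- m
  }
  if (failed > 0.01 * config$n_draws)
    stop(sprintf("PSA aborted: %d of %d draws failed", failed, config$n_draws))
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), type = 1)
  summary <- data.frame(
    metric = names(point), point = unname(point),
    mean = unname(colMeans(draws[ok, , drop = FALSE])),
    lo = unname(qs[1, ]), hi = unname(qs[2, ]),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, draws = draws, n_failed = failed,
                 scenario = scn, config = config),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s (%d draws, %d failed)\n",
              x$scenario$name, x$config$n_draws, x$n_failed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-28s %12.0f (95%% UI %12.0f to %12.0f)\n",
                s$metric[i], s$point[i], s$lo[i], s$hi[i]))
  invisible(x)
}
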