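test_that("salt-sodium conversion uses the NaCl mass fraction", {
  expect_equal(salt_to_sodium_mg(1), 393.4)
  expect_equal(round_sodium(salt_to_sodium_mg(1)), 390)
  expect_equal(salt_to_sodium_mg(0), 0)
  # 5 g by hand from molar masses: 5000 * 22.99 / 58.44
  expect_equal(salt_to_sodium_mg(5), 5000 * 22.99 / 58.44, tolerance = 2e-4)
  expect_error(salt_to_sodium_mg(-1), "non-negative")
})

test_that("trajectories ramp linearly and end exactly on target", {
  b <- test_bundle()
  for (key in c("sdt", "nphs30", "salt2g")) {
    scn <- default_scenarios()[[key]]
    tr <- build_trajectory(b, scn, n_years = 20)
    tgt <- attr(tr, "target")
    for (k in 1:15) for (s in 1:2) {
      v <- tr[k, s, ]
      expect_true(all(diff(v[1:11]) <= 1e-12))         # non-increasing ramp
      steps <- diff(v[1:11])
      expect_lt(max(abs(steps - steps[1])), 1e-9)      # equal decrements
      expect_lt(max(abs(v[11:20] - tgt[k, s])), 1e-9)  # flat at target
      expect_true(all(v >= 0))
    }
  }
})

test_that("an absolute sodium target is hit as a population-weighted mean", {
  b <- test_bundle()
  tr <- build_trajectory(b, default_scenarios()$sdt)
  pop <- matrix(b$data$population[order(match(b$data$sex, model_sexes()),
                                        b$data$age_lower)], 15, 2)
  wmean_final <- sum(attr(tr, "target") * pop) / sum(pop)
  expect_equal(wmean_final, 2000, tolerance = 1e-9)
  # all strata scaled by a common relative factor
  ratio <- attr(tr, "target") / attr(tr, "baseline")
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("null and invalid scenarios behave as specified", {
  b <- test_bundle()
  null_scn <- scenario("null", "relative_reduction_fraction", 0)
  tr <- build_trajectory(b, null_scn, n_years = 15)
  expect_true(all(abs(tr - c(attr(tr, "baseline"))) < 1e-12))
  expect_error(build_trajectory(b, scenario("up", "absolute_sodium_target_mg",
                                            9000)),
               "target above baseline")
  expect_error(scenario("bad", "relative_reduction_fraction", 1.2))
})

test_that("hypertensive fraction matches an independent normal-CDF oracle", {
  expect_equal(hypertensive_fraction(bp_dist(140, 17)), 0.5)
  # survey band men 25-34: 1 - Phi((140 - 120.3) / 13.5)
  expect_equal(hypertensive_fraction(bp_dist(120.3, 13.5)),
               tail_above(140, 120.3, 13.5), tolerance = 1e-8)
  expect_equal(round(hypertensive_fraction(bp_dist(120.3, 13.5)), 4), 0.0722)
  expect_lt(hypertensive_fraction(bp_dist(120, 1e-6)), 1e-12)
})

test_that("SBP shift weights the hypertensive and normotensive effects", {
  eff <- default_effect_params()
  # fully hypertensive cohort at the reference sodium reduction
  expect_equal(sbp_mean_shift(1720, bp_dist(200, 0.1), eff), 5.39,
               tolerance = 1e-9)
  expect_equal(sbp_mean_shift(0, bp_dist(130, 10), eff), 0)
  # half the reference reduction, mixed cohort, against the hand formula
  p <- tail_above(140, 130, 10)
  expect_equal(sbp_mean_shift(860, bp_dist(130, 10), eff),
               0.5 * (p * 5.39 + (1 - p) * 2.42), tolerance = 1e-7)
  expect_equal(round(sbp_mean_shift(860, bp_dist(130, 10), eff), 3), 1.446)
})

test_that("SBP shift is monotone in sodium change and hypertensive share", {
  eff <- default_effect_params()
  deltas <- seq(0, 2000, by = 250)
  shifts <- vapply(deltas, sbp_mean_shift, numeric(1), bp = bp_dist(130, 15),
                   eff = eff)
  expect_true(all(diff(shifts) > 0))
  means <- seq(110, 170, by = 10)  # higher mean => larger p_hyp
  shifts <- vapply(means, function(m)
    sbp_mean_shift(860, bp_dist(m, 15), eff), numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("scenario ramps lower every stratum mean and keep sds fixed", {
  b <- test_bundle()
  tr <- build_trajectory(b, default_scenarios()$sdt)
  eff <- b$effects
  for (s in model_sexes()) {
    d <- b$data[b$data$sex == s, ]
    d <- d[order(d$age_lower), ]
    si <- match(s, model_sexes())
    for (k in 1:15) {
      delta <- attr(tr, "baseline")[k, si] - tr[k, si, 11]
      shift <- sbp_mean_shift(delta, bp_dist(d$sbp_mean[k], d$sbp_sd[k]), eff)
      expect_gt(shift, 0)          # post-shift mean strictly lower
      expect_lt(shift, d$sbp_mean[k])
    }
  }
})
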