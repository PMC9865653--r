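test_that("generated bundles satisfy every input invariant", {
  for (realism in c("smooth", "noisy")) {
    b <- test_bundle(1L, realism)
    expect_true(validate_bundle(b))
    d <- b$data
    cs <- b$causes
    expect_identical(nrow(d), 30L)
    expect_true(all(cs$prevalence >= 0 & cs$prevalence <= 1))
    psum <- tapply(cs$prevalence, paste(cs$age_lower, cs$sex), sum)
    expect_true(all(psum <= 1))
    acm <- d$acm_rate[match(paste(cs$age_lower, cs$sex),
                            paste(d$age_lower, d$sex))]
    expect_true(all(cs$cause_mortality <= acm))
  }
})

test_that("age gradients are monotone non-decreasing up to the terminal band", {
  b <- test_bundle()
  for (s in model_sexes()) {
    d <- b$data[b$data$sex == s, ]
    expect_true(all(diff(d$acm_rate[order(d$age_lower)]) >= 0))
    for (cause in ckd_causes()) {
      cc <- b$causes[b$causes$sex == s & b$causes$cause == cause, ]
      expect_true(all(diff(cc$prevalence[order(cc$age_lower)]) >= 0))
    }
  }
})

test_that("identical seeds reproduce bundles; distinct seeds differ", {
  b1 <- generate_bundle(11L)
  b2 <- generate_bundle(11L)
  b3 <- generate_bundle(12L)
  expect_identical(b1, b2)
  expect_false(identical(b1$data$acm_rate, b3$data$acm_rate))
})

test_that("population-weighted mean sodium is 3700 mg/day", {
  b <- generate_bundle(7L)
  # independent summation over the raw table
  wm <- with(b$data, sum(sodium_mg * population) / sum(population))
  expect_lt(abs(wm - 3700), 50)
})

test_that("baseline SBP table holds the published survey values", {
  fx <- table1_fixture()
  men2534 <- fx[fx$sex == "male" & fx$age_band == "25-34", ]
  expect_equal(men2534$sbp_mean, 120.3)
  expect_equal(men2534$sbp_sd, 13.5)
  women85 <- fx[fx$sex == "female" & fx$age_band == "85+", ]
  expect_equal(women85$sbp_mean, 140.8)
  expect_equal(women85$sbp_sd, 28.0)
  expect_true(all(fx$sbp_sd > 0))
})

test_that("bundle SBP equals the fixture mapped onto five-year bands", {
  b <- test_bundle()
  fx <- table1_fixture()
  for (s in model_sexes()) {
    d <- b$data[b$data$sex == s, ]
    fxs <- fx[fx$sex == s, ]
    # ten-year bands cover two five-year bands; 85+ covers the top three
    expect_equal(d$sbp_mean[d$age_lower == 25],
                 fxs$sbp_mean[fxs$age_band == "25-34"])
    expect_equal(d$sbp_mean[d$age_lower == 30],
                 fxs$sbp_mean[fxs$age_band == "25-34"])
    expect_equal(d$sbp_mean[d$age_lower == 95],
                 fxs$sbp_mean[fxs$age_band == "85+"])
    expect_equal(d$sbp_sd[d$age_lower == 80],
                 fxs$sbp_sd[fxs$age_band == "75-84"])
  }
})

test_that("write_bundle/read_bundle round-trips at full precision", {
  b <- test_bundle(5L, "noisy")
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  for (col in setdiff(names(b$data), c("age_group", "sex")))
    expect_identical(b2$data[[col]], b$data[[col]])
  ord <- function(cs) cs[order(cs$cause, cs$sex, cs$age_lower), ]
  c1 <- ord(b$causes); c2 <- ord(b2$causes)
  for (col in c("incidence", "prevalence", "cause_mortality", "yld",
                "cost_total"))
    expect_identical(c2[[col]], c1[[col]])
  expect_equal(b2$effects, b$effects)
})
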