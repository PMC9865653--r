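test_that("one annual cycle matches the closed form and conserves mass", {
  st <- c(S = 1, C = 0, Dc = 0)
  expect_equal(disease_cycle(st, 0, 0), st)
  # hand-checked constant-hazard solution
  out <- disease_cycle(st, 0.02, 0.1)
  expect_equal(round(out[["S"]], 5), 0.98020)
  expect_equal(round(out[["C"]], 5), 0.01884)
  # conservation on random valid states
  withr::with_seed(3, {
    for (rep in 1:25) {
      p <- stats::runif(3)
      st <- stats::setNames(p / sum(p), c("S", "C", "Dc"))
      out <- disease_cycle(st, stats::runif(1, 0, 0.5), stats::runif(1, 0, 0.5))
      expect_lt(abs(sum(out) - 1), 1e-12)
      expect_true(all(out >= -1e-15))
    }
  })
  expect_error(disease_cycle(c(S = 0.7, C = 0.7, Dc = -0.4), 0.1, 0.1),
               "invalid disease state")
})

test_that("the closed-form cycle agrees with RK4 integration, including i = f", {
  withr::with_seed(8, {
    i <- stats::runif(10, 0, 0.3)
    f <- stats::runif(10, 0, 0.3)
  })
  i <- c(i, 0.05); f <- c(f, 0.05)   # equal-hazard limit branch
  ora <- rk4_cycle(rep(1, 11), rep(0, 11), i, f, dt = 1e-3)
  for (j in seq_along(i)) {
    out <- disease_cycle(c(S = 1, C = 0, Dc = 0), i[j], f[j])
    expect_lt(abs(out[["S"]] - ora$S[j]), 1e-6)
    expect_lt(abs(out[["C"]] - ora$C[j]), 1e-6)
  }
})

test_that("zero remission: prevalent cases never return to healthy", {
  # with no incidence the healthy pool is untouched and C only decays
  out <- disease_cycle(c(S = 0.6, C = 0.3, Dc = 0.1), 0, 0.2)
  expect_equal(out[["S"]], 0.6)
  expect_lt(out[["C"]], 0.3)
})

test_that("ratio case fatality divides cause mortality by prevalence", {
  b <- test_bundle()
  cf <- derive_case_fatality(b, method = "ratio")
  cs <- b$causes
  key <- function(df) paste(df$age_lower, df$sex, df$cause)
  m <- cs[match(key(cf), key(cs)), ]
  expect_equal(cf$f, ifelse(m$cause_mortality > 0,
                            m$cause_mortality / m$prevalence, 0))
  # degenerate inputs error with the stratum named
  bad <- b
  sel <- bad$causes$age_lower == 50 & bad$causes$sex == "male" &
    bad$causes$cause == "dm"
  bad$causes$prevalence[sel] <- 0
  expect_error(derive_case_fatality(bad, method = "ratio"), "50")
})

test_that("ode-consistent derivation recovers a known case fatality", {
  b <- test_bundle()
  f_true <- 0.05
  # forward-simulate observed prevalence under the bundle incidence and a
  # constant case fatality, then invert
  for (s in model_sexes()) {
    sel <- b$causes$sex == s & b$causes$cause == "htn"
    cc <- b$causes[sel, ]
    i_band <- cc$incidence[order(cc$age_lower)]
    pc <- simulate_prevalence(i_band, rep(f_true, 15), 0.003)
    b$causes$prevalence[sel] <- pc[match(cc$age_lower, seq(25, 95, 5))]
    b$causes$cause_mortality[sel] <- f_true * b$causes$prevalence[sel]
    b$causes$yld[sel] <- 0.1 * b$causes$prevalence[sel]
  }
  cf <- derive_case_fatality(b, method = "ode_consistent")
  got <- cf$f[cf$cause == "htn"]
  expect_true(all(abs(got - f_true) / f_true < 0.05))
})

test_that("ode-consistent fatality reproduces observed prevalence under no intervention", {
  b <- test_bundle()
  dis <- run_disease(b, 0, "other", cf_method = "ode_consistent")
  # follow the youngest male cohort across bands; compare modelled prevalence
  # at each band entry with the observed input prevalence (ages 30-90)
  g <- dis[dis$arm == "bau" & dis$sex == "male" & dis$age_group == "25-29", ]
  g <- g[order(g$year), ]
  pc <- g$C / (g$S + g$C)
  obs <- b$causes[b$causes$sex == "male" & b$causes$cause == "other", ]
  obs <- obs$prevalence[order(obs$age_lower)]
  for (k in 2:14) {  # band entered after 5 * (k - 1) cycles
    expect_lt(abs(pc[5 * (k - 1) + 1] - obs[k]) / obs[k], 0.10)
  }
})

test_that("disease arms respond to the PIF as specified", {
  b <- test_bundle()
  dis0 <- run_disease(b, 0, "htn")
  ord <- function(x) x[order(x$sex, x$age_group, x$year), ]
  bau <- ord(dis0[dis0$arm == "bau", ])
  int <- ord(dis0[dis0$arm == "int", ])
  for (col in c("S", "C", "Dc", "incident_flow", "death_flow"))
    expect_identical(bau[[col]], int[[col]])
  # constant PIF of 0.1 scales the incidence hazard by exactly 0.9 in year 1
  dis <- run_disease(b, c(0.1, 0.1), "htn")
  g <- dis[dis$sex == "female" & dis$age_group == "40-44", ]
  y1 <- g[g$year == 2019, ]
  haz <- function(arm) -log(1 - y1$incident_flow[y1$arm == arm] /
                              y1$S[y1$arm == arm])
  expect_equal(haz("int") / haz("bau"), 0.9, tolerance = 1e-10)
  # positive PIF: intervention prevalence and cause deaths below BAU always
  tr <- build_trajectory(b, default_scenarios()$sdt)
  pif <- compute_pif_array(b, tr)
  dis <- run_disease(b, pif, "dm")
  wide <- merge(dis[dis$arm == "bau", ], dis[dis$arm == "int", ],
                by = c("year", "age_group", "sex"), suffixes = c("0", "1"))
  expect_true(all(wide$C1 <= wide$C0 + 1e-15))
  post <- wide[wide$year > 2019, ]
  expect_true(all(post$death_flow1 <= post$death_flow0 + 1e-15))
})
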