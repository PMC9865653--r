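test_that("disability weights divide cause YLD by prevalence, background-corrected", {
  b <- test_bundle()
  dw <- disability_weights(b)
  cs <- b$causes
  key <- function(df) paste(df$age_lower, df$sex, df$cause)
  m <- cs[match(key(dw), key(cs)), ]
  expect_equal(dw$dw_crude, m$yld / m$prevalence)
  # independent recomputation of the multiplicative correction
  d <- b$data
  dkey <- paste(d$age_lower, d$sex)
  ysum <- tapply(cs$yld, paste(cs$age_lower, cs$sex), sum)
  b_other <- d$all_yld_rate[match(paste(dw$age_lower, dw$sex), dkey)] -
    as.numeric(ysum[paste(dw$age_lower, dw$sex)])
  expect_equal(dw$dw_adj, dw$dw_crude * (1 - b_other), tolerance = 1e-12)
  expect_true(all(dw$dw_adj <= dw$dw_crude & dw$dw_adj >= 0 & dw$dw_crude <= 1))
  # zero background leaves the crude weight untouched
  b0 <- b
  ycs <- tapply(b0$causes$yld, paste(b0$causes$age_lower, b0$causes$sex), sum)
  b0$data$all_yld_rate <- as.numeric(ycs[paste(b0$data$age_lower, b0$data$sex)])
  dw0 <- disability_weights(b0)
  expect_equal(dw0$dw_adj, dw0$dw_crude, tolerance = 1e-12)
  # inconsistent inputs (crude weight above 1) are rejected
  bad <- b
  bad$data$all_yld_rate <- pmin(bad$data$all_yld_rate * 50, 1)
  bad$causes$yld <- pmin(bad$causes$yld * 50, 1)
  expect_error(disability_weights(bad), "exceeds 1")
})

test_that("identical arms give identical lifetables and zero HALY gain", {
  b <- test_bundle()
  dis <- do.call(rbind, lapply(ckd_causes(), function(cz) run_disease(b, 0, cz)))
  lt <- run_lifetable(b, dis)
  expect_equal(sum(lt$HALY[lt$arm == "int"]) - sum(lt$HALY[lt$arm == "bau"]), 0)
  # person-years are the trapezoid of consecutive survivorships
  g <- lt[lt$arm == "bau" & lt$sex == "male" & lt$age_group == "60-64", ]
  g <- g[order(g$year), ]
  T <- nrow(g)
  expect_equal(g$L[-T], (g$l[-T] + g$l[-1]) / 2, tolerance = 1e-12)
  expect_true(all(diff(g$l) <= 0) && all(g$l >= 0) && all(g$l <= 1))
  expect_true(all(g$w >= 0 & g$w <= 1))
})

test_that("constant-mortality person-years match the closed-form annuity", {
  b <- test_bundle()
  M <- 0.01
  b$data$acm_rate <- M
  # keep cause mortality consistent with the flattened all-cause rate
  b$causes$cause_mortality <- pmin(b$causes$cause_mortality, M / 8)
  dis <- do.call(rbind, lapply(ckd_causes(), function(cz) run_disease(b, 0, cz)))
  lt <- run_lifetable(b, dis)
  g <- lt[lt$arm == "bau" & lt$sex == "female" & lt$age_group == "90-94", ]
  T <- nrow(g)  # ten cycles to age 100
  expect_identical(T, 10L)
  # sum of trapezoid person-years under l(t) = e^(-Mt), geometric series
  expected <- (1 + exp(-M)) / 2 * (1 - exp(-M * T)) / (1 - exp(-M))
  expect_equal(sum(g$L), expected, tolerance = 1e-10)
})

test_that("HALY decomposition attributes gains to the perturbed cause only", {
  b <- test_bundle()
  pif <- array(0, c(15, 2, 4, 2))
  pif[, , 1, 2] <- 0.2   # perturb hypertensive CKD only
  dis <- do.call(rbind, lapply(ckd_causes(), function(cz)
    run_disease(b, pif, cz)))
  lt <- run_lifetable(b, dis)
  dec <- decompose_haly_by_cause(b, dis, lt)
  total <- sum(lt$HALY[lt$arm == "int"]) - sum(lt$HALY[lt$arm == "bau"])
  expect_gt(total, 0)
  expect_equal(dec$share[dec$cause == "htn"], 1, tolerance = 1e-9)
  expect_equal(sum(dec$total_haly), total, tolerance = 1e-6 * abs(total))
})

test_that("equal perturbation of identical submodels splits HALYs 25% each", {
  b <- test_bundle()
  # symmetric toy bundle: all four causes share the hypertensive-CKD inputs
  tmpl <- b$causes[b$causes$cause == "htn", ]
  b$causes <- do.call(rbind, lapply(ckd_causes(), function(cz) {
    x <- tmpl; x$cause <- cz; x
  }))
  b$data$all_yld_rate <- b$data$all_yld_rate  # background unchanged
  validate_bundle(b)
  dis <- do.call(rbind, lapply(ckd_causes(), function(cz)
    run_disease(b, c(0, 0.15), cz)))
  lt <- run_lifetable(b, dis)
  dec <- decompose_haly_by_cause(b, dis, lt)
  expect_equal(dec$share, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sum(dec$total_haly),
               sum(lt$HALY[lt$arm == "int"]) - sum(lt$HALY[lt$arm == "bau"]),
               tolerance = 1e-9)
})
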