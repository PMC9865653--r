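# shared fixtures and independent numerical oracles

# memoised default test bundle (generation is cheap but used everywhere)
.test_env <- new.env()
test_bundle <- function(seed = 42L, realism = "smooth") {
  key <- paste0("b", seed, realism)
  if (is.null(.test_env[[key]]))
    .test_env[[key]] <- generate_bundle(seed, realism)
  .test_env[[key]]
}

# RK4 integration of the illness-death ODEs dS = -iS, dC = iS - fC over one
# year; vectorised over states so many (i, f) pairs integrate at once
rk4_cycle <- function(S, C, i, f, dt = 1e-4) {
  deriv <- function(S, C) list(dS = -i * S, dC = i * S - f * C)
  n <- round(1 / dt)
  for (step in seq_len(n)) {
    k1 <- deriv(S, C)
    k2 <- deriv(S + dt / 2 * k1$dS, C + dt / 2 * k1$dC)
    k3 <- deriv(S + dt / 2 * k2$dS, C + dt / 2 * k2$dC)
    k4 <- deriv(S + dt * k3$dS, C + dt * k3$dC)
    S <- S + dt / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
    C <- C + dt / 6 * (k1$dC + 2 * k2$dC + 2 * k3$dC + k4$dC)
  }
  list(S = S, C = C)
}

# Monte-Carlo potential impact fraction with common random numbers; z is a
# standard-normal sample reused across arms (and grid points, if supplied)
mc_pif <- function(mean0, sd0, mean1, sd1, rr, z) {
  a0 <- mean(relative_risk_at(mean0 + sd0 * z, rr))
  a1 <- mean(relative_risk_at(mean1 + sd1 * z, rr))
  (a0 - a1) / a0
}

# normal upper-tail probability by quadrature of the density (independent of
# pnorm-based code paths)
tail_above <- function(threshold, mean, sd) {
  stats::integrate(function(x) exp(-(x - mean)^2 / (2 * sd^2)) /
                     (sd * sqrt(2 * pi)),
                   threshold, mean + 12 * sd, rel.tol = 1e-12)$value
}

# forward-simulate band-start prevalences under known hazards, as the
# generator does, for case-fatality round-trip tests
simulate_prevalence <- function(i_band, f_band, p_init) {
  nb <- length(i_band)
  pc <- numeric(nb)
  st <- c(S = 1 - p_init, C = p_init, Dc = 0)
  for (k in seq_len(nb)) {
    pc[k] <- st[["C"]] / (st[["S"]] + st[["C"]])
    for (cyc in 1:5) st <- disease_cycle(st, i_band[k], f_band[k])
  }
  pc
}
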