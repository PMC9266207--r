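test_that("conductance transform follows Ohm's law around reversal", {
  expect_equal(conductance(-130, 0, 65), 2.0)
  expect_equal(conductance(0, -20, 65), 0)
  expect_error(conductance(-5, 65, 65), "undefined")
})

test_that("reversal potential interpolates exact crossings and rejects flat relations", {
  expect_equal(estimate_reversal(c(60, 65, 70), c(-5, 0, 5)), 65)
  expect_equal(estimate_reversal(c(-20, 0, 20, 40, 60, 70),
                                 c(-800, -1000, -600, -300, -50, 10)),
               70 - 10 * 10 / 60, tolerance = 1e-9)
  # all-inward, monotone decreasing: no rising limb to extrapolate
  expect_error(estimate_reversal(c(-20, 0, 20), c(-100, -200, -300)),
               "no reversal")
})

test_that("reversal estimated from a simulated I-V lands on E_Na", {
  ss <- run_protocol(iv_protocol(-100), nav_preset("WT"),
                     macroscopic_params(gbar = 90, E_Na = 68))
  pk <- measure_peak(ss)
  expect_equal(estimate_reversal(pk$command, pk$peak), 68, tolerance = 1)
})

test_that("activation fit recovers noiseless Boltzmann parameters exactly", {
  V <- seq(-80, 40, by = 5)
  G <- 12 / (1 + exp((-15 - V) / 6))
  fit <- fit_activation(V, G)
  expect_equal(fit$V50, -15, tolerance = 1e-6)
  expect_equal(fit$k, 6, tolerance = 1e-6)
  expect_equal(fit$amplitude, 12, tolerance = 1e-6)
  expect_identical(predict(fit, fit$V50), 0.5)   # midpoint by construction
  expect_error(fit_activation(V[1:3], G[1:3]), "at least 5")
})

test_that("availability fit recovers noiseless parameters with descending slope", {
  V <- seq(-130, 0, by = 10)
  avail <- 1 / (1 + exp((-67 - V) / -7))
  fit <- fit_inactivation(V, avail)
  expect_equal(fit$V50, -67, tolerance = 1e-6)
  expect_equal(fit$k, -7, tolerance = 1e-6)
  expect_lt(fit$k, 0)
})

test_that("simulated curves put availability left of activation and anchor at 1", {
  wt <- nav_preset("WT")
  act <- analyze_iv(run_protocol(iv_protocol(-100), wt))$activation
  ssi <- analyze_ssi(run_protocol(ssi_protocol(), wt))
  expect_lt(ssi$inactivation$V50, act$V50)
  most_hyper <- ssi$availability$avail[which.min(ssi$availability$V)]
  expect_equal(most_hyper, 1, tolerance = 0.02)
})

test_that("mutant activation midpoints shift in the reported directions", {
  v50 <- vapply(c("WT", "WT+CN21", "R639C", "R850Q"), function(cn)
    analyze_iv(run_protocol(iv_protocol(-100), nav_preset(cn)))$activation$V50, 1)
  expect_lt(v50[["R850Q"]], v50[["WT"]])     # premature opening
  expect_lt(v50[["R639C"]], v50[["WT"]])     # hyperpolarised activation
  expect_gt(v50[["WT+CN21"]], v50[["WT"]])   # CaMKII inhibition right-shifts
})

test_that("biexponential decay fit recovers constructed time constants", {
  t <- seq(0, 52, by = 0.02)
  tr <- -900 * exp(-(t - 3) / 1.2) - 150 * exp(-(t - 3) / 8) - 4
  fit <- fit_decay(t, tr, step_start = 2, step_end = 52)
  expect_equal(fit$tau_fast, 1.2, tolerance = 0.01)
  expect_equal(fit$tau_slow, 8, tolerance = 0.01)
  expect_lte(fit$tau_fast, fit$tau_slow)

  # samples before the 1 ms exclusion never reach the fit
  garbled <- tr
  garbled[t < 3] <- 5000
  fit2 <- fit_decay(t, garbled, step_start = 2, step_end = 52)
  expect_equal(fit2$tau_fast, fit$tau_fast, tolerance = 1e-8)

  expect_error(fit_decay(t[1:10], tr[1:10], 2, 2.05), "too short")
})

test_that("a mono-exponential decay collapses onto one component", {
  t <- seq(0, 40, by = 0.05)
  tr <- -500 * exp(-t / 3) - 2
  fit <- fit_decay(t, tr, step_start = -1, step_end = 40)
  one_component <- abs(fit$A_slow) < 1e-4 * abs(fit$A_fast) ||
    abs(fit$tau_slow - fit$tau_fast) < 1e-3 * fit$tau_fast
  expect_true(one_component)
  taus <- c(fit$tau_fast, fit$tau_slow)
  expect_equal(taus[which.max(abs(c(fit$A_fast, fit$A_slow)))], 3,
               tolerance = 0.01)
})

test_that("recovery fit recovers a noiseless time constant exactly", {
  gap <- exp(seq(log(0.5), log(100), length.out = 12))
  frac <- 1 - exp(-gap / 12.5)
  fit <- fit_recovery(gap, frac)
  expect_equal(fit$tau, 12.5, tolerance = 1e-6)
  expect_equal(fit$offset + fit$amplitude, 1, tolerance = 1e-6)  # full recovery
  expect_error(fit_recovery(gap[1:3], frac[1:3]), "at least 4")
})

test_that("simulated recovery is monotone and well fitted", {
  res <- analyze_recovery(run_protocol(recovery_protocol(), nav_preset("WT")))
  expect_true(all(diff(res$fractions$frac) > 0))
  expect_gt(res$recovery$tau, 0)
  expect_lt(res$recovery$residual_norm, 0.05)
})

test_that("current density normalises to capacitance and splits consistently", {
  expect_equal(current_density(-2258, 10), -225.8)
  expect_equal(current_density(0, 7.3), 0)
  pk <- data.frame(command = c(-10, 0), peak = c(-800, -1000))
  whole <- current_density(pk, 10)
  half <- current_density(data.frame(command = pk$command, peak = pk$peak / 2), 5)
  expect_equal(whole$density, half$density)
  expect_error(current_density(pk, 0), "positive")
})

test_that("percent change and midpoint shift reproduce their definitions", {
  expect_equal(percent_change(-100, -100), 0)
  expect_equal(percent_change(-200, -50), 75)
  expect_equal(percent_change(-200, -300), -50)   # negative = increase
  expect_error(percent_change(0, -5), "non-zero")
  f <- fit_activation(seq(-60, 20, 5), 1 / (1 + exp((-25 - seq(-60, 20, 5)) / 5)))
  expect_equal(midpoint_shift(f, f), 0)
  expect_equal(midpoint_shift(-6.94, -13.07), 6.13)
})
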