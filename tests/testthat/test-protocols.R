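test_that("I-V protocol matches the recording configuration", {
  p <- iv_protocol(-100)
  expect_length(p$sweeps, 29)                      # -80 to +60 in 5 mV steps
  expect_equal(p$command[1], -80)
  expect_equal(p$command[29], 60)
  durs <- vapply(p$sweeps, function(s) s$duration[2], 1)
  expect_true(all(durs == 50))
  expect_equal(iv_protocol(-80)$holding, -80)      # fluoride-free variant
})

test_that("steady-state inactivation protocol matches the configuration", {
  p <- ssi_protocol()
  pre <- vapply(p$sweeps, function(s) s$duration[1], 1)
  expect_true(all(pre == 500))
  expect_equal(min(p$command), -130)
  expect_equal(max(p$command), 40)
  test_seg <- p$sweeps[[1]][2, ]
  expect_equal(test_seg$level, 0)
  expect_equal(test_seg$duration, 20)
})

test_that("recovery protocol uses -80 mV gaps and 0 mV test pulses", {
  p <- recovery_protocol()
  expect_length(p$command, 12)
  for (s in p$sweeps) {
    expect_equal(s$level, c(0, -80, 0))
    expect_equal(s$duration[3], 20)
  }
  expect_equal(p$command, sort(p$command))
})

test_that("protocol construction validates input", {
  expect_error(voltage_protocol(-80, list(data.frame(level = 0, duration = -1)), 0))
  expect_error(voltage_protocol(-80, list(), numeric(0)))
})

test_that("run_protocol is deterministic and density scales currents exactly", {
  p <- quick_iv()
  wt <- nav_preset("WT")
  s1 <- run_protocol(p, wt)
  s2 <- run_protocol(p, wt)
  expect_identical(s1$current, s2$current)

  scaled <- update_rates(wt, density_scale = 0.300)
  s3 <- run_protocol(p, scaled)
  for (i in seq_along(s1$current))
    expect_equal(s3$current[[i]], 0.300 * s1$current[[i]], tolerance = 1e-12)
})

test_that("simulated I-V currents are single peaked, inward below reversal", {
  for (cn in all_conditions()) {
    ss <- run_protocol(quick_iv(), nav_preset(cn))
    pk <- measure_peak(ss)
    expect_true(all(pk$peak <= 1e-9))   # all steps lie below E_Na = +68
  }
})

test_that("wild-type peak current is maximal near 0 mV", {
  ss <- run_protocol(iv_protocol(-100), nav_preset("WT"))
  pk <- measure_peak(ss)
  vmax <- pk$command[which.max(abs(pk$peak))]
  expect_true(vmax >= -20 && vmax <= 10)
})

test_that("peak measurement returns constructed values and honours windows", {
  p <- voltage_protocol(-80, list(data.frame(level = c(-80, 0),
                                             duration = c(2, 10))),
                        command = 0, dt = 0.1, measure_segment = 2L)
  tm <- seq(0, 12, by = 0.1)
  mk <- function(cur) structure(
    list(time = list(tm), current = list(cur), popen = NULL, command = 0,
         protocol = p, dt = 0.1, condition = NULL,
         segment_ends = list(c(2, 12)), capacitance = NULL, seed = NULL),
    class = "sweep_set")

  zero <- mk(rep(0, length(tm)))
  expect_equal(measure_peak(zero)$peak, 0)

  inj <- rep(0, length(tm)); inj[tm >= 3 & tm <= 3.2] <- -200
  expect_equal(measure_peak(mk(inj))$peak, -200)

  # a sample inside the first 0.05 ms after the edge must be ignored
  spiked <- inj; spiked[which(tm >= 2)[1]] <- -999
  expect_equal(measure_peak(mk(spiked))$peak, -200)

  expect_error(measure_peak(zero, segment = 3L), "protocol mismatch")
})

test_that("persistent current averages exactly the final 5 ms", {
  p <- voltage_protocol(-80, list(data.frame(level = c(-80, 0),
                                             duration = c(2, 50))),
                        command = 0, dt = 0.5, measure_segment = 2L)
  tm <- seq(0, 52, by = 0.5)
  cur <- rep(-100, length(tm))
  cur[tm >= 47 - 1e-9] <- -2          # last 5 ms of the step sit at -2 pA
  ss <- structure(list(time = list(tm), current = list(cur), popen = NULL,
                       command = 0, protocol = p, dt = 0.5, condition = NULL,
                       segment_ends = list(c(2, 52)), capacitance = NULL,
                       seed = NULL), class = "sweep_set")
  expect_equal(measure_persistent(ss)$persistent, -2)

  short <- voltage_protocol(-80, list(data.frame(level = c(-80, 0),
                                                 duration = c(2, 3))),
                            command = 0, dt = 0.5, measure_segment = 2L)
  ss_short <- structure(list(time = list(seq(0, 5, 0.5)),
                             current = list(rep(-1, 11)), popen = NULL,
                             command = 0, protocol = short, dt = 0.5,
                             condition = NULL, segment_ends = list(c(2, 5)),
                             capacitance = NULL, seed = NULL),
                        class = "sweep_set")
  expect_error(measure_persistent(ss_short), "shorter than")
})

test_that("simulated persistent current is far smaller than the peak", {
  ss <- run_protocol(iv_protocol(-100, steps = 0), nav_preset("WT"))
  pk <- measure_peak(ss)$peak
  ps <- measure_persistent(ss)$persistent
  expect_lt(abs(ps), 0.05 * abs(pk))
  expect_lt(ps, 0)   # same (inward) sign, non-zero plateau
})

test_that("zero-gap limit of the recovery protocol is the end-of-pulse availability", {
  r <- nav_preset("WT")
  p <- recovery_protocol(gaps = c(1e-6, 5, 50), dt = 0.05)
  ss <- run_protocol(p, r)
  fr <- abs(measure_peak(ss)$peak) / abs(measure_peak(ss, segment = 1L)$peak)
  expect_lt(fr[1], 0.1)              # essentially no recovery with no gap
  expect_true(all(diff(fr) > 0))     # monotone recovery with gap duration
})
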