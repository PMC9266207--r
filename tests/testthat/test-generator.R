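test_that("generator has the scheme's topology and conserves probability", {
  # edge mask of the 13-state scheme (C1..C5, O, OB, I1..I6)
  adj <- matrix(FALSE, 13, 13)
  for (n in 1:4) {
    adj[n, n + 1] <- adj[n + 1, n] <- TRUE          # closed tier
    adj[7 + n, 8 + n] <- adj[8 + n, 7 + n] <- TRUE  # inactivated tier
  }
  adj[5, 6] <- adj[6, 5] <- TRUE                    # C5 <-> O
  adj[12, 13] <- adj[13, 12] <- TRUE                # I5 <-> I6
  adj[6, 7] <- adj[7, 6] <- TRUE                    # O <-> OB
  for (n in 1:5) adj[n, 7 + n] <- adj[7 + n, n] <- TRUE
  adj[6, 13] <- adj[13, 6] <- TRUE                  # O <-> I6

  for (cn in all_conditions()) for (V in c(-100, -40, 20)) {
    Q <- build_generator(V, nav_preset(cn))
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    off <- Q; diag(off) <- 0
    expect_true(all(off[!adj] == 0))   # zero exactly where there is no edge
    expect_true(all(off[adj] >= 0))
  }
})

test_that("wild-type base rates appear unscaled at 0 mV", {
  Q <- build_generator(0, nav_preset("WT"))
  expect_equal(Q["C5", "O"], 150)   # gamma
  expect_equal(Q["C4", "C5"], 150)  # alpha0 * exp(0)
  expect_equal(Q["C1", "C2"], 4 * 150)
  expect_equal(Q["O", "I6"], 0.75)  # Oon
  # with epsilon = 0 the column into the blocked state is empty
  expect_true(all(Q[-7, "OB"] == 0))
})

test_that("generator rejects invalid input", {
  expect_error(build_generator(NaN, nav_preset("WT")), "finite")
  expect_error(build_generator(c(0, 1), nav_preset("WT")), "finite")
  expect_error(build_generator(0, list(alpha0 = 1)))
})

test_that("steady state agrees with 10 s fixed-voltage integration", {
  for (cn in all_conditions()) for (V in c(-120, -80, -40, 0, 40)) {
    r <- nav_preset(cn)
    p <- steady_state(V, r)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    occ <- integrate_occupancy(p * 0 + c(1, rep(0, 12)),
                               data.frame(level = V, duration = 1e4),
                               r, dt = 100)
    p_long <- unlist(occ[nrow(occ), -(1:2)])
    expect_lt(max(abs(p_long - p)), 1e-6)
  }
})

test_that("channel is shut at strong hyperpolarisation", {
  p <- steady_state(-120, nav_preset("WT"))
  expect_lt(p["O"], 1e-4)
})

test_that("matrix-exponential propagation matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  r <- nav_preset("WT")
  p0 <- steady_state(-100, r)
  occ <- integrate_occupancy(p0, data.frame(level = 0, duration = 50), r,
                             dt = 0.025)
  Q <- build_generator(0, r)
  rhs <- function(t, p, parms) list(as.numeric(p %*% Q))
  sol <- deSolve::lsoda(p0, times = c(0, 10, 50), func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  for (k in 2:3) {
    row <- which(abs(occ$time - sol[k, 1]) < 1e-9)
    expect_lt(max(abs(unlist(occ[row, -(1:2)]) - sol[k, -1])), 1e-6)
  }
})

test_that("closed-tier reduction equilibrates to the subunit binomial", {
  r <- closed_tier_rates()
  V <- -20
  p0 <- c(1, rep(0, 12))
  occ <- integrate_occupancy(p0, data.frame(level = V, duration = 5000),
                             r, dt = 50)
  p_end <- unlist(occ[nrow(occ), -(1:2)])
  a <- r$alpha0 * exp(V / r$k_alpha)
  b <- r$beta0 * exp(-V / r$k_beta)
  expect_equal(unname(p_end[1:5]), dbinom(0:4, 4, a / (a + b)),
               tolerance = 1e-8)
  expect_equal(unname(sum(p_end[6:13])), 0)
})

test_that("steady state errors on a disconnected scheme", {
  # closed and inactivated tiers both absorbing-free but mutually unreachable
  expect_error(steady_state(-20, closed_tier_rates()))
})

test_that("rectangle loops are in detailed balance when tiers are coupled", {
  # the four C/I rectangles balance whenever alpha*beta_i == alpha_i*beta
  for (r in list(nav_preset("WT"), balanced_rates(0.7), balanced_rates(1.3))) {
    for (V in c(-70, -10)) {
      Q <- build_generator(V, r)
      for (n in 1:4) {
        pr <- loop_products(Q, n)
        expect_equal(pr[["cw"]], pr[["ccw"]], tolerance = 1e-12)
      }
    }
  }
  # the C5-O-I6-I5 loop balances for every condition, by construction of
  # the allosteric scaling
  for (cn in all_conditions()) {
    Q <- build_generator(-30, nav_preset(cn))
    cw <- Q[5, 6] * Q[6, 13] * Q[13, 12] * Q[12, 5]
    ccw <- Q[5, 12] * Q[12, 13] * Q[13, 6] * Q[6, 5]
    expect_equal(cw, ccw, tolerance = 1e-12)
  }
})

test_that("occupancy stays conserved and OB stays empty along a protocol", {
  r <- nav_preset("R850Q")
  p0 <- steady_state(-100, r)
  occ <- integrate_occupancy(p0, data.frame(level = c(-100, 0, -80, 0),
                                            duration = c(5, 50, 20, 20)),
                             r, dt = 0.025)
  expect_lt(max(abs(rowSums(occ[, -(1:2)]) - 1)), 1e-8)
  expect_true(all(occ$OB == 0))
})

test_that("a stationary start stays constant under integration", {
  r <- nav_preset("WT")
  p0 <- steady_state(-60, r)
  occ <- integrate_occupancy(p0, data.frame(level = -60, duration = 20), r)
  drift <- apply(abs(sweep(as.matrix(occ[, -(1:2)]), 2, p0)), 1, max)
  expect_lt(max(drift), 1e-8)
})

test_that("halving the sample interval leaves the trajectory unchanged", {
  # per-segment matrix-exponential stepping is exact for piecewise-constant
  # voltage, so refinement changes only the sampling, not the solution
  r <- nav_preset("WT")
  p0 <- steady_state(-100, r)
  seg <- data.frame(level = c(-100, 0), duration = c(2, 50))
  o1 <- integrate_occupancy(p0, seg, r, dt = 0.025)
  o2 <- integrate_occupancy(p0, seg, r, dt = 0.0125)
  expect_lt(max(abs(unlist(o1[nrow(o1), -(1:2)]) -
                    unlist(o2[nrow(o2), -(1:2)]))), 1e-6)
})

test_that("a depolarising step yields one early peak then a small plateau", {
  r <- nav_preset("WT")
  p0 <- steady_state(-100, r)
  occ <- integrate_occupancy(p0, data.frame(level = 0, duration = 50), r)
  po <- occ$O
  k <- which.max(po)
  expect_lt(occ$time[k], 2)                 # transient peaks early
  expect_gt(po[k], 10 * mean(po[occ$time >= 45]))  # then decays
  expect_gt(mean(po[occ$time >= 45]), 0)    # persistent component remains
  # monotone rise to the single peak
  expect_true(all(diff(po[seq_len(k)]) >= -1e-12))
})

test_that("macroscopic current follows the driving force and density", {
  expect_equal(channel_current(0, 0, macroscopic_params()), 0)
  expect_equal(channel_current(0.5, 68, macroscopic_params(E_Na = 68)), 0)
  po <- c(0, 0.2, 0.7, 0.4)
  i1 <- channel_current(po, -10, macroscopic_params(gbar = 80), 1)
  i03 <- channel_current(po, -10, macroscopic_params(gbar = 80), 0.300)
  expect_equal(i03, 0.300 * i1, tolerance = 1e-14)
  expect_true(all(i1[po > 0] < 0))  # inward below reversal
  expect_error(channel_current(1.5, 0, macroscopic_params()), "popen")
})

test_that("integrate_occupancy rejects a malformed start", {
  r <- nav_preset("WT")
  expect_error(integrate_occupancy(rep(0.5, 13),
                                   data.frame(level = 0, duration = 1), r),
               "summing to 1")
  expect_error(integrate_occupancy(steady_state(-80, r),
                                   data.frame(level = 0, duration = -1), r))
})
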