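# Shared fixtures built in code at test time.

# Coarse I-V protocol for fast simulation-backed tests (10 mV increments).
quick_iv <- function(holding = -100)
  iv_protocol(holding, steps = seq(-80, 60, by = 10))

# A rate set whose inactivated tier is proportional to the closed tier
# (alpha*beta_i == alpha_i*beta), so every rectangle loop is balanced.
balanced_rates <- function(scale = 0.7)
  nav_rates(alpha0 = 120, beta0 = 4, alpha_i0 = 120 * scale,
            beta_i0 = 4 * scale, Oon = 0.9, Ooff = 0.004,
            Con = 0.004, Coff = 0.6)

# Closed-tier-only reduction: no inactivation, no opening. Occupancy started
# in the closed tier stays there and equilibrates to a binomial over the
# number of activated subunits.
closed_tier_rates <- function()
  nav_rates(Con = 0, Coff = 0, Oon = 0, Ooff = 0, gamma0 = 0, delta0 = 0,
            epsilon = 0, zeta0 = 0)

# Product of edge rates around the four C/I rectangles (clockwise vs
# counterclockwise), used by the detailed-balance tests.
loop_products <- function(Q, n) {
  cw <- Q[n, n + 1] * Q[n + 1, 8 + n] * Q[8 + n, 7 + n] * Q[7 + n, n]
  ccw <- Q[n, 7 + n] * Q[7 + n, 8 + n] * Q[8 + n, n + 1] * Q[n + 1, n]
  c(cw = cw, ccw = ccw)
}

all_conditions <- function() nav_condition_names()

het_names <- function()
  list(WT = het_composition("WT"),
       `WT+CN21` = het_composition("WT", TRUE),
       R639C = het_composition("R639C"),
       `R639C+CN21` = het_composition("R639C", TRUE),
       R850Q = het_composition("R850Q"),
       `R850Q+CN21` = het_composition("R850Q", TRUE))
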