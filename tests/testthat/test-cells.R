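# Apoptosis switches, trigger dynamics and cell-density kinetics.

p <- model_parameters()
ip <- to_internal_units(p)

test_that("bistable rate takes its closed-form boundary values", {
  expect_equal(bistable_rhs(0, 0, p), 27 / 101, tolerance = 1e-12)
  expect_equal(bistable_rhs(0, 5, p), 27 / 101, tolerance = 1e-12)
  expect_equal(bistable_rhs(1, 0, p), -0.459 / 1.01, tolerance = 1e-12)
  expect_equal(bistable_rhs(1, 7, p), -0.459 / 1.01, tolerance = 1e-12)
  # positive at 0 and negative at 1 forces at least one interior root
  expect_gt(bistable_rhs(0, 0, p), 0)
  expect_lt(bistable_rhs(1, 0, p), 0)
})

test_that("monostable rate has the closed-form Hill fixed point", {
  expect_equal(monostable_rhs(0.4, 0, p), -p$k_mono * 0.4)
  Rstar <- function(cI) cI^10 / (1 + cI^10)
  expect_equal(monostable_rhs(Rstar(1), 1, p), 0, tolerance = 1e-12)
  expect_equal(Rstar(1), 0.5)
  expect_equal(Rstar(2), 1024 / 1025, tolerance = 1e-12)
  expect_equal(monostable_rhs(Rstar(2), 2, p), 0, tolerance = 1e-12)
  # homogeneous denominator form coincides at kh = 1
  ph <- model_parameters(hill_denominator = "homogeneous")
  expect_equal(monostable_rhs(0.3, 1.7, ph), monostable_rhs(0.3, 1.7, p))
})

test_that("trigger species fixed points sit where the threshold demands", {
  expect_equal(r1_rhs(0, 0, p), 0)
  # sustained full upstream signal: R1* = kf/(kf+kr) above the threshold
  R1star <- p$kf / (p$kf + p$kr)
  expect_equal(R1star, 0.961538, tolerance = 1e-6)
  expect_equal(r1_rhs(R1star, 1, p), 0, tolerance = 1e-12)
  expect_gt(R1star, p$R1_th)
  # minimum sustained R that can ever reach the threshold
  R_min <- p$R1_th * p$kr / ((1 - p$R1_th) * p$kf)
  expect_equal(R_min, 0.36)
  expect_equal(r1_rhs(p$R1_th, R_min, p), 0, tolerance = 1e-12)
})

test_that("bistable root structure: three roots at rest, one under drug", {
  ss0 <- bistable_steady_states(0, p)
  expect_equal(nrow(ss0), 3)
  expect_identical(ss0$stable, c(TRUE, FALSE, TRUE))
  # independent fine sign-change scan agrees on the root locations
  f <- function(R) bistable_rhs(R, 0, p)
  Rg <- seq(0, 1, by = 1e-5)
  v <- f(Rg)
  brute <- Rg[which(v[-1] * v[-length(v)] < 0)]
  expect_equal(ss0$R, brute, tolerance = 1e-4)
  # far above the saddle input only the high state survives
  ss5 <- bistable_steady_states(5, p)
  expect_equal(nrow(ss5), 1)
  expect_true(ss5$stable)
  expect_gt(ss5$R, 0.5)
  # root count stays odd across the input range
  for (cI in seq(0, 3, by = 0.25))
    expect_true(nrow(bistable_steady_states(cI, p)) %% 2 == 1)
})

test_that("saddle-node input threshold has its defining property", {
  cstar <- switch_input_threshold(p)
  expect_equal(nrow(bistable_steady_states(cstar * 0.99, p)), 3)
  expect_equal(nrow(bistable_steady_states(cstar * 1.01, p)), 1)
  # stronger input coupling lowers the threshold
  cstar2 <- switch_input_threshold(model_parameters(q = 0.6))
  expect_lt(cstar2, cstar)
  # decoupled input has no bifurcation to find
  expect_error(switch_input_threshold(model_parameters(q = 0)),
               "q = 0")
})

test_that("growth gating is reversible for bistable, latched for monostable", {
  cs <- list(R1 = c(0, 0.95, 0.5), triggered = c(FALSE, FALSE, FALSE))
  # no signal anywhere: full growth, no latches
  eg <- effective_growth(list(R1 = c(0, 0, 0), triggered = rep(FALSE, 3)),
                         "monostable", p)
  expect_equal(eg$a1_eff, rep(p$a1, 3))
  expect_false(any(eg$triggered))
  # monostable: crossing latches permanently even after R1 falls back
  eg1 <- effective_growth(cs, "monostable", p)
  expect_equal(eg1$a1_eff, c(p$a1, 0, p$a1))
  cs2 <- list(R1 = c(0, 0.2, 0.5), triggered = eg1$triggered)
  eg2 <- effective_growth(cs2, "monostable", p)
  expect_equal(eg2$a1_eff, c(p$a1, 0, p$a1))     # stays gated
  # bistable: the gate follows R1
  eg3 <- effective_growth(cs, "bistable", p)
  expect_equal(eg3$a1_eff, c(p$a1, 0, p$a1))
  eg4 <- effective_growth(cs2, "bistable", p)
  expect_equal(eg4$a1_eff, rep(p$a1, 3))         # released
})

test_that("logistic kinetics: carrying capacity and collapse under gating", {
  expect_equal(logistic_rhs(0, p$a1, p), 0)
  ct_star <- (p$a1 - p$a2) / p$b                  # 1e5 cells/mm^3 units
  expect_equal(ct_star * 1e5, 1.003086e6, tolerance = 1e-6)
  expect_equal(logistic_rhs(ct_star, p$a1, p), 0, tolerance = 1e-12)
  # gated growth: strictly negative rate for any positive density
  for (ct in c(0.01, 1, 10, 50))
    expect_lt(logistic_rhs(ct, 0, p), 0)
})

test_that("switch species stay inside the unit interval (invariant box)", {
  for (cI in c(0, 0.5, 1, 3, 10)) {
    expect_gte(bistable_rhs(0, cI, p), 0)
    expect_lte(bistable_rhs(1, cI, p), 0)
    expect_gte(monostable_rhs(0, cI, p), 0)
    expect_lte(monostable_rhs(1, cI, p), 0)
    expect_gte(r1_rhs(0, 1, p), 0)
    expect_lte(r1_rhs(1, cI / 10, p), 0)
  }
  # integrated trajectories respect the box under strong forcing
  st <- list(c_E = 5, c_I = 8, R = 0, R1 = 0, c_t = 0)
  out <- advance_reactions(st, 12 * 3600, ip, switch_kind = "bistable")
  expect_true(out$R >= 0 && out$R <= 1)
  expect_true(out$R1 >= 0 && out$R1 <= 1)
})

test_that("resting cells relax to the low state, not the high one", {
  st <- list(c_E = 0, c_I = 0, R = 0, R1 = 0, c_t = ip$c_t0)
  out <- advance_reactions(st, 24 * 3600, ip, switch_kind = "bistable")
  low <- bistable_steady_states(0, p)$R[1]
  expect_equal(out$R, low, tolerance = 1e-3)
  expect_lt(out$R1, p$R1_th)
})

test_that("bistable response is hysteretic, monostable is not", {
  # slow triangular ramp of the drug input, integrated on the rate laws
  ramp <- c(seq(0, 3, length.out = 120), seq(3, 0, length.out = 120))
  integrate_switch <- function(rhs_fun) {
    R <- 0; out <- numeric(length(ramp))
    dt_h <- 0.5                               # hours per ramp increment
    for (k in seq_along(ramp)) {
      for (s in 1:20) R <- min(max(R + dt_h / 20 * rhs_fun(R, ramp[k], p), 0), 1)
      out[k] <- R
    }
    out
  }
  Rb <- integrate_switch(bistable_rhs)
  up <- Rb[1:120]; down <- rev(Rb[121:240])
  expect_gt(mean(abs(up - down)), 0.05)       # open hysteresis loop
  expect_gt(Rb[240], 0.5)                     # stays on the high branch
  Rm <- integrate_switch(monostable_rhs)
  upm <- Rm[1:120]; downm <- rev(Rm[121:240])
  expect_lt(mean(abs(upm - downm)), mean(abs(up - down)))
  expect_lt(Rm[240], 0.2)                     # returns to rest
})
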