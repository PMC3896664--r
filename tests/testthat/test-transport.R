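# Pulse input, transmural flux, membrane exchange and compartment steppers.

ip <- to_internal_units(model_parameters())

test_that("pulse inlet concentration is a right-continuous rectangle", {
  pl <- pulse_input(1, 1.5)
  expect_equal(inlet_concentration(pl, 0.5 * 3600), 1)
  expect_equal(inlet_concentration(pl, 2 * 3600), 0)
  expect_equal(inlet_concentration(pl, 1.5 * 3600), 0)   # off at t = T
  expect_equal(inlet_concentration(pl, 0), 1)            # on at t = 0
  seg <- pulse_input(segments = data.frame(S = 0.5, start_h = 0, T_h = 4))
  expect_equal(inlet_concentration(seg, 3.9 * 3600), 0.5)
  expect_equal(inlet_concentration(seg, 4.1 * 3600), 0)
  expect_error(pulse_input(S = -1), "S")
  expect_error(pulse_input(segments = data.frame(S = c(1, 1),
                                                 start_h = c(0, 1),
                                                 T_h = c(2, 1))), "overlap")
})

test_that("log-mean concentration has the right limits and continuity", {
  expect_equal(log_mean_conc(0, 0), 0)
  expect_equal(log_mean_conc(1, 0.5), 0.5 / log(2), tolerance = 1e-12)
  expect_equal(log_mean_conc(0.7, 0.7), 0.7)             # equal-argument limit
  # monotone, jump-free behaviour across the regularisation branches
  x <- 10^seq(-14, 0, by = 0.25)
  v <- log_mean_conc(rep(1, length(x)), x)
  expect_true(all(diff(v) >= -1e-9))
  expect_lt(v[1], 0.05)                                  # tends to 0
  # symmetric in its arguments
  expect_equal(log_mean_conc(0.3, 0.9), log_mean_conc(0.9, 0.3))
})

test_that("Kedem-Katchalsky flux combines permeability and drag", {
  expect_equal(kedem_katchalsky_flux(0, 0, ip$P_wall, 1e-7), 0)
  J <- kedem_katchalsky_flux(1, 0.5, ip$P_wall, 1e-7, 0)
  expect_equal(J, 0.5 * ip$P_wall + (0.5 / log(2)) * 1e-7, tolerance = 1e-12)
  # equal concentrations: pure solvent drag at the common value
  cc <- 0.8
  expect_equal(kedem_katchalsky_flux(cc, cc, ip$P_wall, 2e-7, 0.25),
               2e-7 * 0.75 * cc, tolerance = 1e-12)
  # diffusive part is antisymmetric under argument swap
  a <- kedem_katchalsky_flux(1, 0.25, ip$P_wall, 0)
  b <- kedem_katchalsky_flux(0.25, 1, ip$P_wall, 0)
  expect_equal(a, -b)
})

test_that("membrane exchange has the Michaelis-Menten structure", {
  ex <- membrane_exchange(0, 0, ip)
  expect_equal(ex$uptake, 0)
  expect_equal(ex$dcI_dt, 0)
  # half saturation of the influx arm
  expect_equal(membrane_exchange(ip$k1, 0, ip)$uptake, ip$V1 / 2)
  # equilibrium at c_I = (k2/k1) c_E when V1 = V2
  cI_eq <- ip$k2 / ip$k1                                 # c_E = 1
  expect_equal(cI_eq, 6.256, tolerance = 1e-4)
  expect_equal(membrane_exchange(1, cI_eq, ip)$uptake, 0, tolerance = 1e-12)
})

test_that("intracellular drug relaxes monotonically to its equilibrium", {
  # constant extracellular exposure: c_t = 0 removes the sink so c_E stays 1
  st <- list(c_E = 1, c_I = 0, R = 0, R1 = 0, c_t = 0)
  path <- numeric(30)
  for (k in seq_len(30)) {
    st <- advance_reactions(st, 3600, ip, switch_kind = "bistable")
    path[k] <- st$c_I
  }
  expect_true(all(diff(path) > 0))
  expect_equal(path[30], ip$k2 / ip$k1, tolerance = 1e-3)
  expect_equal(st$c_E, 1)
})

test_that("vascular stepper conserves drug with a sealed wall", {
  p0 <- model_parameters(L_p = 0, P_wall = 0)
  ip0 <- to_internal_units(p0)
  g <- build_grid(ip0, nr_i = 4, nz = 24, refinement = 1)
  fl <- solve_flow(g, ip0)
  pl <- pulse_input(1, 1.5)
  st <- drug_state(g)
  inflow <- outflow <- 0
  dt <- 0.02                                   # resolves the 0.16 s transit
  for (n in 1:400) {
    st <- step_vascular(st, fl, pl, dt, g, ip0)
    fx <- attr(st, "fluxes")
    inflow <- inflow + fx$inflow; outflow <- outflow + fx$outflow
    expect_equal(fx$wall, 0)
  }
  mass <- sum(st$c_v) * g$vol_lumen
  expect_equal((mass + outflow) / inflow, 1, tolerance = 1e-3)
  expect_true(all(st$c_v >= 0))
  # zero inlet, zero state stays identically zero
  st0 <- drug_state(g)
  st0 <- step_vascular(st0, fl, pulse_input(0, 1), 1, g, ip0)
  expect_identical(st0$c_v, numeric(g$nz))
})

test_that("interstitial stepper conserves drug in a closed domain", {
  p0 <- model_parameters(L_p = 0, P_wall = 0, V1 = 0, V2 = 0)
  ip0 <- to_internal_units(p0)
  g <- build_grid(ip0, nr_i = 24, nz = 8, refinement = 2)
  fl <- solve_flow(g, ip0)
  st <- drug_state(g)
  st$c_E[3:6, 3:5] <- 2                        # arbitrary interior blob
  m0 <- sum(st$c_E * g$vol_r)
  ct <- matrix(ip0$c_t0, g$nr, g$nz)
  for (n in 1:50) st <- step_interstitial(st, fl, ct, 30, g, ip0)
  expect_equal(sum(st$c_E * g$vol_r) / m0, 1, tolerance = 1e-3)
  expect_true(all(st$c_E >= 0))
  expect_identical(st$c_I, matrix(0, g$nr, g$nz))  # exchange disabled
  # diffusion spreads the blob: peak decreases, support grows
  expect_lt(max(st$c_E), 2)
  expect_gt(st$c_E[1, 1], 0)
})

test_that("after the pulse the wall flux reverses where tissue exceeds blood", {
  res <- baseline_run("bistable")
  ts <- vapply(res$snapshots, `[[`, numeric(1), "t")
  k <- which(ts == 2 * 3600)                   # 0.5 h after the pulse end
  snap <- res$snapshots[[k]]
  Js <- kedem_katchalsky_flux(snap$c_v, snap$c_E[1, ], res$internal$P_wall,
                              res$flow$J_F, res$internal$sigma_f)
  expect_true(any(snap$c_E[1, ] > snap$c_v))
  expect_true(any(Js < 0))                     # drug returns to the blood
})

test_that("extracellular concentration rises, peaks, then falls inland", {
  res <- baseline_run("bistable")
  j <- res$j_mid
  i <- findInterval(res$internal$R_C + 1e-4, res$grid$r_f)  # 100 um inland
  trace <- vapply(res$snapshots, function(s) s$c_E[i, j], numeric(1))
  pk <- which.max(trace)
  expect_gt(pk, 1)
  expect_lt(pk, length(trace))
  expect_gt(trace[pk], trace[1])
  expect_gt(trace[pk], trace[length(trace)])
})
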