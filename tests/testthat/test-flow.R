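# Steady vascular-interstitial flow.

ip <- to_internal_units(model_parameters())
ip0 <- to_internal_units(model_parameters(L_p = 0))   # impermeable wall

test_that("Starling flux is linear, signed and vanishes at equal pressure", {
  expect_identical(starling_flux(1000, 1000, 2e-10), 0)
  L_p <- 2.8e-8 / 133.322                       # m/(mmHg s) -> m/(Pa s)
  expect_equal(starling_flux(10 * 133.322, 0, L_p), 2.8e-7, tolerance = 1e-12)
  expect_lt(starling_flux(100, 200, 2e-10), 0)  # reabsorption
})

test_that("Peclet number is L*u/D with guarded diffusivity", {
  expect_equal(peclet(0.01, 6.249e-2, 1.578e-10), 3.96e6, tolerance = 1e-3)
  expect_identical(peclet(0.01, 0, 1.578e-10), 0)
  expect_equal(peclet(1e-4, 2.5e-7, 1.578e-10), 0.158, tolerance = 1e-2)
  expect_error(peclet(0.01, 0.1, 0), "diffusivity")
})

test_that("impermeable wall recovers the Poiseuille closed form", {
  g <- build_grid(ip0, nr_i = 16, nz = 24, refinement = 2)
  fl <- solve_flow(g, ip0)
  u_exact <- (ip0$P_A - ip0$P_V) * ip0$R_C^2 / (8 * ip0$mu * ip0$L)
  expect_equal(u_exact, 6.249e-2, tolerance = 1e-3)
  expect_equal(fl$u_v_mean, rep(u_exact, g$nz), tolerance = 1e-12)
  # P_v exactly linear in z
  expect_equal(diff(fl$P_v), rep(diff(fl$P_v)[1], g$nz - 1),
               tolerance = 1e-10)
  expect_equal(fl$P_v[1], ip0$P_A - (ip0$P_A - ip0$P_V) * g$z_c[1] / g$L,
               tolerance = 1e-12)
  expect_identical(fl$J_F, numeric(g$nz))
  expect_equal(fl$P_i, matrix(ip0$P_0, g$nr, g$nz))
  expect_equal(max(abs(fl$u_r)), 0)
  expect_equal(max(abs(fl$u_z)), 0)
})

test_that("darcy_velocity matches the radial log-profile closed form", {
  # manufactured 1D radial Darcy solution with prescribed wall influx q:
  # P(r) = P_0 + (q R_C / K) ln(R_T / r), u_r(r) = q R_C / r
  g <- build_grid(ip, nr_i = 128, nz = 1, refinement = 1)
  q <- 2e-7
  P <- matrix(ip$P_0 + (q * ip$R_C / ip$K) * log(ip$R_T / g$r_c), g$nr, 1)
  vel <- darcy_velocity(P, ip$K, g, P_0 = ip$P_0, J_F = q)
  u_exact <- q * ip$R_C / g$r_f
  interior <- 2:g$nr
  relerr <- abs(vel$u_r[interior, 1] - u_exact[interior]) / u_exact[interior]
  expect_lt(max(relerr), 2e-3)                  # second-order accurate
  # outer Dirichlet face reproduces the analytic value at matching accuracy
  expect_equal(vel$u_r[g$nr + 1, 1], u_exact[g$nr + 1], tolerance = 1e-2)
})

test_that("darcy_velocity on trivial pressure fields", {
  g <- build_grid(ip, nr_i = 12, nz = 8, refinement = 1)
  # uniform pressure: all velocities vanish
  vel <- darcy_velocity(matrix(ip$P_0, g$nr, g$nz), ip$K, g, P_0 = ip$P_0)
  expect_equal(max(abs(vel$u_r)), 0)
  expect_equal(max(abs(vel$u_z)), 0)
  # pressure linear in z only: uniform u_z = -K * slope, interior u_r = 0
  slope <- 5e4                                  # Pa/m
  P <- matrix(rep(1000 + slope * g$z_c, each = g$nr), g$nr, g$nz)
  vel <- darcy_velocity(P, ip$K, g)
  expect_equal(vel$u_z[, 2:g$nz], matrix(-ip$K * slope, g$nr, g$nz - 1),
               tolerance = 1e-12)
  expect_equal(max(abs(vel$u_r[2:g$nr, ])), 0)
})

test_that("baseline coupled flow reproduces the reported field structure", {
  g <- build_grid(ip, nr_i = 64, nz = 24, refinement = 4)
  fl <- solve_flow(g, ip)
  # filtration velocity of order 1e-7 m/s
  expect_equal(floor(log10(mean(fl$J_F))), -7)
  # vascular pressure strictly decreasing along the flow
  expect_true(all(diff(fl$P_v) < 0))
  expect_true(all(fl$P_v <= ip$P_A & fl$P_v >= ip$P_V))
  # wall interstitial pressure: sharp near-inlet rise, then gradual decline
  jmax <- which.max(fl$P_i[1, ])
  expect_lte(jmax, g$nz / 4)
  expect_gt(jmax, 1)
  expect_true(all(diff(fl$P_i[1, jmax:g$nz]) < 0))
  # transmural velocity: sharp fall near the inlet, then gradual decline
  expect_equal(which.max(fl$J_F), 1)
  dJ <- diff(fl$J_F)
  expect_true(all(dJ < 0))
  expect_gt(abs(dJ[1]), 2 * abs(dJ[5]))
  # Starling consistency at every wall face
  expect_equal(fl$J_F, starling_flux(fl$P_v, fl$P_i[1, ], ip$L_p),
               tolerance = 1e-6)
  # fixed-point residual decreases monotonically
  expect_true(all(diff(fl$resid_hist) < 0))
})

test_that("baseline flow conserves water globally and cell by cell", {
  g <- build_grid(ip, nr_i = 48, nz = 16, refinement = 3)
  fl <- solve_flow(g, ip)
  # global: lumen flow lost equals total filtration
  lost <- fl$Q_f[1] - fl$Q_f[g$nz + 1]
  filtered <- sum(fl$J_F * g$A_wall_seg)
  expect_equal(lost, filtered, tolerance = 5e-3)
  # local: discrete divergence of u_i vanishes in every interstitial cell
  Fr <- fl$u_r * g$A_rf                          # (nr+1) x nz
  Fz <- fl$u_z * g$A_zf                          # nr x (nz+1)
  div <- (Fr[-1, ] - Fr[-(g$nr + 1), ]) + (Fz[, -1] - Fz[, -(g$nz + 1)])
  expect_lt(max(abs(div)) / max(abs(Fr)), 1e-6)
})
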