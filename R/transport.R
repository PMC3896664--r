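# Three-compartment drug transport.
#
# Vascular concentration c_v lives on the 1D lumen line (cross-section
# averages), extracellular c_E and intracellular c_I on the interstitial
# annulus.  The transmural solute flux is the Kedem-Katchalsky combination of
# diffusive permeability and convective drag with a log-mean concentration.
# Time stepping uses operator splitting: (1) implicit diffusion + implicit
# wall-exchange diffusive part (sparse linear solve, factorised once),
# (2) explicit first-order upwind Darcy advection + explicit K-K convective
# part, (3) pointwise local reaction ODEs (membrane exchange, signalling,
# cell density) with sub-stepped RK4.

#' Pulse injection input
#'
#' A single rectangular pulse of normalised intensity `S` and duration
#' `T_h` hours starting at t = 0, or a multi-segment schedule.
#'
#' @param S normalised inlet intensity (>= 0).
#' @param T_h infusion duration (h, > 0).
#' @param segments optional data frame with columns `S`, `start_h`, `T_h`
#'   describing non-overlapping segments; overrides `S`/`T_h`.
#' @return object of class `tds_pulse`.
#' @export
pulse_input <- function(S = 1, T_h = 1.5, segments = NULL) {
  if (is.null(segments)) {
    if (S < 0) stop("pulse intensity S must be >= 0")
    if (T_h <= 0) stop("infusion time T must be > 0")
    segments <- data.frame(S = S, start_s = 0, T_s = T_h * 3600)
  } else {
    stopifnot(all(c("S", "start_h", "T_h") %in% names(segments)))
    if (any(segments$S < 0) || any(segments$T_h <= 0))
      stop("segments need S >= 0 and T > 0")
    segments <- segments[order(segments$start_h), ]
    ends <- segments$start_h + segments$T_h
    if (nrow(segments) > 1 &&
        any(segments$start_h[-1] < ends[-nrow(segments)] - 1e-12))
      stop("pulse segments must not overlap")
    segments <- data.frame(S = segments$S, start_s = segments$start_h * 3600,
                           T_s = segments$T_h * 3600)
  }
  structure(list(segments = segments), class = "tds_pulse")
}

#' Inlet concentration of a pulse schedule at time t
#'
#' The inlet boundary value is `S` while the pulse is on (t in
#' `[start, start + T)`, right-continuous at switch times) and 0 otherwise.
#'
#' @param pulse a `tds_pulse`.
#' @param t time (s), vectorised.
#' @return normalised concentration at the vessel inlet.
#' @export
inlet_concentration <- function(pulse, t) {
  stopifnot(inherits(pulse, "tds_pulse"))
  out <- numeric(length(t))
  for (k in seq_len(nrow(pulse$segments))) {
    seg <- pulse$segments[k, ]
    on <- t >= seg$start_s & t < seg$start_s + seg$T_s
    out[on] <- seg$S
  }
  out
}

#' Regularised log-mean concentration
#'
#' (c1 - c2)/ln(c1/c2) with continuous limits: both arguments below `eps`
#' give 0; nearly equal arguments give the arithmetic limit; one vanishing
#' argument uses `eps` as the floor inside the logarithm (flux then tends to
#' zero with the vanishing side, as physically required).
#'
#' @param c1,c2 non-negative concentrations (vectorised).
#' @param eps regularisation floor (normalised units).
#' @return log-mean values.
#' @export
log_mean_conc <- function(c1, c2, eps = 1e-12) {
  c1 <- pmax(c1, 0); c2 <- pmax(c2, 0)
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  hi <- pmax(c1, c2); lo <- pmin(c1, c2)
  out <- numeric(n)
  both0 <- hi <= eps
  near <- !both0 & (hi - lo) <= 1e-8 * hi
  one0 <- !both0 & !near & lo <= eps
  gen <- !(both0 | near | one0)
  out[near] <- 0.5 * (c1[near] + c2[near])
  out[one0] <- (hi[one0] - lo[one0]) / log(hi[one0] / eps)
  out[gen] <- (c1[gen] - c2[gen]) / log(c1[gen] / c2[gen])
  out
}

#' Kedem-Katchalsky transmural solute flux
#'
#' Diffusive permeability term plus convective drag with reflection
#' coefficient and log-mean concentration.  Positive = lumen to
#' interstitium.  The diffusive part is antisymmetric in the two wall
#' concentrations.
#'
#' @param c_v_w vascular concentration at the wall (normalised).
#' @param c_E_w extracellular concentration at the wall (normalised).
#' @param P_wall diffusive permeability (m/s).
#' @param J_F filtration velocity (m/s).
#' @param sigma_f solute reflection coefficient in [0, 1].
#' @return flux in normalised concentration times m/s (vectorised).
#' @export
kedem_katchalsky_flux <- function(c_v_w, c_E_w, P_wall, J_F, sigma_f = 0) {
  P_wall * (c_v_w - c_E_w) +
    J_F * (1 - sigma_f) * log_mean_conc(c_v_w, c_E_w)
}

#' Michaelis-Menten transmembrane exchange
#'
#' Net per-cell uptake rate: saturable influx driven by extracellular drug
#' minus saturable efflux driven by intracellular drug.  The intracellular
#' balance is dc_I/dt = this rate; the extracellular sink is the cell
#' density times the same expression (converted to extracellular
#' concentration units).
#'
#' @param c_E extracellular concentration (normalised, vectorised).
#' @param c_I intracellular concentration (normalised, vectorised).
#' @param ip internal parameters.
#' @return list with `uptake` (per-cell net rate, intracellular reference
#'   units/s) and `dcI_dt` (equal to `uptake`).
#' @export
membrane_exchange <- function(c_E, c_I, ip) {
  rate <- ip$V1 * c_E / (c_E + ip$k1) - ip$V2 * c_I / (c_I + ip$k2)
  list(uptake = rate, dcI_dt = rate)
}

#' Empty drug state on a grid
#'
#' All compartments start at zero (pre-injection initial condition).
#'
#' @param grid a `tds_grid`.
#' @param t initial time (s).
#' @return object of class `tds_drug_state` with `c_v` (length nz), `c_E`,
#'   `c_I` (nr x nz matrices), `t`.
#' @export
drug_state <- function(grid, t = 0) {
  structure(list(c_v = numeric(grid$nz),
                 c_E = matrix(0, grid$nr, grid$nz),
                 c_I = matrix(0, grid$nr, grid$nz), t = t),
            class = "tds_drug_state")
}

# ---- internal operator assembly -------------------------------------------

# Lumen implicit operator entries (dc/dt = -A c + s), local indices 1..nz.
# Includes conservative upwind advection (implicit) and axial diffusion;
# wall-exchange diagonal added by callers that treat it implicitly.
.lumen_triplets <- function(grid, ip, u_f) {
  nz <- grid$nz
  Vl <- grid$vol_lumen; Al <- grid$A_lumen
  di <- numeric(nz)
  # advection (u_f >= 0 enforced by the flow solver)
  di <- di + u_f[2:(nz + 1)] * Al / Vl
  ii <- jj <- integer(0); xx <- numeric(0)
  if (nz > 1) {
    ii <- 2:nz; jj <- 1:(nz - 1); xx <- -u_f[2:nz] * Al / Vl
    # axial diffusion between lumen segments
    G <- ip$D_v * Al / grid$dz / Vl
    di[1:(nz - 1)] <- di[1:(nz - 1)] + G
    di[2:nz] <- di[2:nz] + G
    ii <- c(ii, 1:(nz - 1), 2:nz); jj <- c(jj, 2:nz, 1:(nz - 1))
    xx <- c(xx, rep(-G, 2 * (nz - 1)))
  }
  # inlet Dirichlet face: advective + diffusive, c_in enters via rhs
  G_in <- ip$D_v * Al / (grid$dz / 2) / Vl
  di[1] <- di[1] + G_in
  # rhs coefficient multiplying c_in(t)
  rhs_in_coef <- u_f[1] * Al / Vl + G_in
  list(i = c(seq_len(nz), ii), j = c(seq_len(nz), jj), x = c(di, xx),
       rhs_in_coef = rhs_in_coef, G_in = G_in * Vl)  # G_in also in m^3/s
}

# Interstitial implicit diffusion entries, local indices 1..nr*nz
# (column-major, radial index fastest).  Edge faces carry zero total flux.
.interstitial_triplets <- function(grid, ip) {
  nr <- grid$nr; nz <- grid$nz
  vol <- grid$vol_r
  ii <- jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nr * nz)
  # radial interior faces
  if (nr > 1) {
    G_r <- ip$D_E * grid$A_rf[2:nr] / (grid$r_c[2:nr] - grid$r_c[1:(nr - 1)])
    Ir <- rep(2:nr, times = nz); Jr <- rep(seq_len(nz), each = nr - 1)
    a <- (Jr - 1) * nr + Ir - 1; b <- a + 1
    g <- rep(G_r, times = nz)
    ii <- c(ii, a, b); jj <- c(jj, b, a)
    xx <- c(xx, -g / vol[Ir - 1], -g / vol[Ir])
    diag_acc <- diag_acc + as.numeric(Matrix::sparseMatrix(
      i = c(a, b), j = rep(1L, 2 * length(a)),
      x = c(g / vol[Ir - 1], g / vol[Ir]), dims = c(nr * nz, 1)))
  }
  # axial interior faces
  if (nz > 1) {
    G_z <- ip$D_E * grid$A_zf / grid$dz
    Iz <- rep(seq_len(nr), times = nz - 1); Jz <- rep(2:nz, each = nr)
    a <- (Jz - 2) * nr + Iz; b <- (Jz - 1) * nr + Iz
    g <- rep(G_z, times = nz - 1)
    ii <- c(ii, a, b); jj <- c(jj, b, a)
    xx <- c(xx, -g / vol[Iz], -g / vol[Iz])
    diag_acc <- diag_acc + as.numeric(Matrix::sparseMatrix(
      i = c(a, b), j = rep(1L, 2 * length(a)),
      x = c(g / vol[Iz], g / vol[Iz]), dims = c(nr * nz, 1)))
  }
  list(i = c(seq_len(nr * nz), ii), j = c(seq_len(nr * nz), jj),
       x = c(diag_acc, xx))
}

# Coupled lumen + interstitium implicit operator M = I + dt*A with the wall
# diffusive exchange P*(c_v - c_E) implicit on both sides (antisymmetric
# flux => exactly conservative).  Returns the LU factor and bookkeeping.
.coupled_operator <- function(grid, ip, flow, dt) {
  nr <- grid$nr; nz <- grid$nz
  N <- nz + nr * nz
  lt <- .lumen_triplets(grid, ip, flow$u_f)
  it <- .interstitial_triplets(grid, ip)
  ii <- c(lt$i, it$i + nz); jj <- c(lt$j, it$j + nz); xx <- c(lt$x, it$x)
  # wall exchange, implicit diffusive part
  PAw <- ip$P_wall * grid$A_wall_seg
  lum <- seq_len(nz)
  wall <- nz + (lum - 1) * nr + 1
  Vl <- grid$vol_lumen; V1c <- grid$vol_r[1]
  ii <- c(ii, lum, lum, wall, wall)
  jj <- c(jj, lum, wall, wall, lum)
  xx <- c(xx, rep(PAw / Vl, nz), rep(-PAw / Vl, nz),
          rep(PAw / V1c, nz), rep(-PAw / V1c, nz))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  M <- Matrix::Diagonal(N) + dt * A
  list(lu = Matrix::lu(M), rhs_in_coef = lt$rhs_in_coef, G_in = lt$G_in,
       lum_idx = lum, wall_idx = wall, N = N)
}

# Explicit upwind advection tendency for c_E (interior faces only; wall and
# outer/end faces carry no advective solute flux here: the wall solute flux
# is the Kedem-Katchalsky term and edge faces have zero total flux).
.advect_interstitial <- function(cE, u_r, u_z, grid) {
  nr <- grid$nr; nz <- grid$nz
  vol <- grid$vol_r
  dcdt <- matrix(0, nr, nz)
  if (nr > 1) {
    ui <- u_r[2:nr, , drop = FALSE]
    Fr <- grid$A_rf[2:nr] *
      (pmax(ui, 0) * cE[1:(nr - 1), , drop = FALSE] +
         pmin(ui, 0) * cE[2:nr, , drop = FALSE])
    dcdt[1:(nr - 1), ] <- dcdt[1:(nr - 1), , drop = FALSE] - Fr / vol[1:(nr - 1)]
    dcdt[2:nr, ] <- dcdt[2:nr, , drop = FALSE] + Fr / vol[2:nr]
  }
  if (nz > 1) {
    uz <- u_z[, 2:nz, drop = FALSE]
    Fz <- grid$A_zf *
      (pmax(uz, 0) * cE[, 1:(nz - 1), drop = FALSE] +
         pmin(uz, 0) * cE[, 2:nz, drop = FALSE])
    dcdt[, 1:(nz - 1)] <- dcdt[, 1:(nz - 1), drop = FALSE] - Fz / vol
    dcdt[, 2:nz] <- dcdt[, 2:nz, drop = FALSE] + Fz / vol
  }
  dcdt
}

# Advective CFL bound for the explicit interstitial advection.
.advective_cfl_dt <- function(grid, flow) {
  nr <- grid$nr; nz <- grid$nz
  rate <- matrix(0, nr, nz)   # total outflow rate / volume per cell
  if (nr > 1) {
    ui <- abs(u <- flow$u_r[2:nr, , drop = FALSE])
    A <- grid$A_rf[2:nr] * ui
    rate[1:(nr - 1), ] <- rate[1:(nr - 1), , drop = FALSE] +
      A / grid$vol_r[1:(nr - 1)]
    rate[2:nr, ] <- rate[2:nr, , drop = FALSE] + A / grid$vol_r[2:nr]
  }
  if (nz > 1) {
    uz <- abs(flow$u_z[, 2:nz, drop = FALSE])
    A <- grid$A_zf * uz
    rate[, 1:(nz - 1)] <- rate[, 1:(nz - 1), drop = FALSE] + A / grid$vol_r
    rate[, 2:nz] <- rate[, 2:nz, drop = FALSE] + A / grid$vol_r
  }
  mx <- max(rate)
  if (mx == 0) Inf else 1 / mx
}

# ---- standalone single-compartment steppers (module surface) ---------------

#' Advance the vascular compartment one time step
#'
#' Semi-implicit update of the 1D cross-section-averaged lumen
#' concentration: implicit conservative upwind advection and axial
#' diffusion, inlet Dirichlet pulse, advective outflow at the outlet, and
#' the distributed wall sink (Kedem-Katchalsky flux against a frozen
#' extracellular wall concentration; the vascular side of the diffusive
#' part is implicit).
#'
#' @param state a `tds_drug_state`.
#' @param flow a `tds_flow`.
#' @param pulse a `tds_pulse`.
#' @param dt time step (s).
#' @param grid a `tds_grid`.
#' @param ip internal parameters.
#' @return updated `tds_drug_state`; attribute `"fluxes"` holds the step's
#'   inlet inflow, outlet outflow and wall mass transfer (normalised
#'   concentration times m^3).
#' @export
step_vascular <- function(state, flow, pulse, dt, grid, ip) {
  nz <- grid$nz
  Vl <- grid$vol_lumen
  lt <- .lumen_triplets(grid, ip, flow$u_f)
  PAw <- ip$P_wall * grid$A_wall_seg
  di_extra <- rep(PAw / Vl, nz)
  A <- Matrix::sparseMatrix(i = c(lt$i, seq_len(nz)),
                            j = c(lt$j, seq_len(nz)),
                            x = c(lt$x, di_extra), dims = c(nz, nz))
  M <- Matrix::Diagonal(nz) + dt * A
  cEw <- state$c_E[1, ]
  c_in <- inlet_concentration(pulse, state$t)
  conv <- flow$J_F * (1 - ip$sigma_f) * log_mean_conc(state$c_v, cEw)
  s <- numeric(nz)
  s[1] <- lt$rhs_in_coef * c_in
  s <- s + (PAw * cEw - conv * grid$A_wall_seg) / Vl
  c_new <- as.numeric(Matrix::solve(M, state$c_v + dt * s))
  inflow <- dt * (flow$u_f[1] * grid$A_lumen * c_in +
                    lt$G_in * (c_in - c_new[1]))
  outflow <- dt * flow$u_f[nz + 1] * grid$A_lumen * c_new[nz]
  wall <- dt * sum((ip$P_wall * (c_new - cEw) + conv) * grid$A_wall_seg)
  out <- state
  out$c_v <- c_new
  out$t <- state$t + dt
  attr(out, "fluxes") <- list(inflow = inflow, outflow = outflow, wall = wall)
  out
}

#' Advance the interstitial compartments one time step
#'
#' Operator-split update of c_E (implicit axisymmetric diffusion with the
#' wall Kedem-Katchalsky influx semi-implicit on the extracellular side,
#' explicit upwind Darcy advection, zero-total-flux outer boundaries)
#' followed by the pointwise membrane-exchange ODE for c_I (sub-stepped
#' RK4 against the live cell density).
#'
#' @param state a `tds_drug_state` (its `c_v` is the frozen vascular field).
#' @param flow a `tds_flow`.
#' @param c_t cell density field (nr x nz, 1e5 cells/mm^3 units).
#' @param dt time step (s).
#' @param grid a `tds_grid`.
#' @param ip internal parameters.
#' @param convection logical; FALSE drops Darcy advection and the
#'   convective Kedem-Katchalsky term.
#' @return updated `tds_drug_state`; attribute `"fluxes"` holds the wall
#'   influx mass and the net cellular uptake mass for the step.
#' @export
step_interstitial <- function(state, flow, c_t, dt, grid, ip,
                              convection = TRUE) {
  nr <- grid$nr; nz <- grid$nz
  it <- .interstitial_triplets(grid, ip)
  PAw <- ip$P_wall * grid$A_wall_seg
  V1c <- grid$vol_r[1]
  wall_idx <- (seq_len(nz) - 1) * nr + 1
  A <- Matrix::sparseMatrix(i = c(it$i, wall_idx), j = c(it$j, wall_idx),
                            x = c(it$x, rep(PAw / V1c, nz)),
                            dims = c(nr * nz, nr * nz))
  M <- Matrix::Diagonal(nr * nz) + dt * A
  cE <- state$c_E
  s <- matrix(0, nr, nz)
  conv_flux <- if (convection)
    flow$J_F * (1 - ip$sigma_f) * log_mean_conc(state$c_v, cE[1, ])
  else numeric(nz)
  s[1, ] <- (PAw * state$c_v + conv_flux * grid$A_wall_seg) / V1c
  if (convection)
    s <- s + .advect_interstitial(cE, flow$u_r, flow$u_z, grid)
  cE_new <- matrix(as.numeric(Matrix::solve(M, as.numeric(cE + dt * s))),
                   nr, nz)
  if (min(cE_new) < -1e-10)
    stop("negative extracellular concentration: scheme failure (min = ",
         signif(min(cE_new), 3), ")")
  cE_new[cE_new < 0] <- 0
  wall_mass <- dt * sum((ip$P_wall * (state$c_v - cE_new[1, ]) + conv_flux) *
                          grid$A_wall_seg)
  # pointwise membrane exchange (frozen c_t)
  rx <- .exchange_substep(cE_new, state$c_I, c_t, dt, ip)
  out <- state
  out$c_E <- rx$c_E
  out$c_I <- rx$c_I
  out$t <- state$t + dt
  attr(out, "fluxes") <- list(wall = wall_mass, uptake = rx$uptake_mass(grid))
  out
}

# RK4 sub-stepped membrane exchange only (no signalling/growth), used by the
# standalone interstitial stepper.
.exchange_substep <- function(cE, cI, c_t, dt, ip) {
  lam <- max(c_t) * ip$V1 * ip$uptake_conv / ip$k1 + ip$V2 / ip$k2
  n_sub <- max(1L, ceiling(dt * lam / 0.8))
  h <- dt / n_sub
  up_cum <- cE * 0
  rhs <- function(e, i) {
    r <- ip$V1 * e / (e + ip$k1) - ip$V2 * i / (i + ip$k2)
    list(de = -c_t * r * ip$uptake_conv, di = r, du = c_t * r * ip$uptake_conv)
  }
  for (s in seq_len(n_sub)) {
    k1 <- rhs(cE, cI)
    k2 <- rhs(cE + h / 2 * k1$de, cI + h / 2 * k1$di)
    k3 <- rhs(cE + h / 2 * k2$de, cI + h / 2 * k2$di)
    k4 <- rhs(cE + h * k3$de, cI + h * k3$di)
    cE <- pmax(cE + h / 6 * (k1$de + 2 * k2$de + 2 * k3$de + k4$de), 0)
    cI <- pmax(cI + h / 6 * (k1$di + 2 * k2$di + 2 * k3$di + k4$di), 0)
    up_cum <- up_cum + h / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
  }
  list(c_E = cE, c_I = cI,
       uptake_mass = function(grid) sum(up_cum * grid$vol_r))
}
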