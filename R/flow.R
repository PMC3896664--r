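# Steady coupled vascular-interstitial flow.
#
# The vessel is modelled as 1D Poiseuille flow with distributed leakage:
#   dQ/dz = -2 pi R_C J_F(z),   dP_v/dz = -8 mu Q / (pi R_C^4),
#   P_v(0) = P_A, P_v(L) = P_V,
# justified by Re = rho u R_C / mu ~ 1.6 and aspect ratio R_C/L = 0.01.
# The interstitium obeys Darcy's law, div(K grad P_i) = 0, with the wall
# filtration J_F as a Neumann flux and ambient Dirichlet pressure P_0 on the
# outer radius and both end annuli.  The two are coupled through Starling's
# law J_F = L_p (P_v - P_i) and iterated to a fixed point.

#' Starling transmural filtration velocity
#'
#' Osmotic contributions are negligible in solid tumours, so the law reduces
#' to a hydrostatic pressure difference.  Positive = lumen to interstitium.
#'
#' @param P_v_local vascular pressure (Pa).
#' @param P_i_local interstitial pressure (Pa).
#' @param L_p vascular hydraulic conductivity (m/(Pa s)).
#' @return filtration velocity (m/s), vectorised.
#' @export
starling_flux <- function(P_v_local, P_i_local, L_p) {
  L_p * (P_v_local - P_i_local)
}

#' Peclet number
#'
#' Ratio of convective to diffusive transport rates over a characteristic
#' length.
#'
#' @param length characteristic length (m).
#' @param speed representative velocity (m/s).
#' @param diffusivity diffusion coefficient (m^2/s), must be > 0.
#' @return dimensionless L*u/D.
#' @export
peclet <- function(length, speed, diffusivity) {
  if (any(diffusivity <= 0)) stop("diffusivity must be positive")
  length * speed / diffusivity
}

# Sparse Darcy pressure operator for the interstitial annulus (assembled
# once per grid; SPD conductance Laplacian).  Returns list(A, dir_coef)
# where A P = b, b = wall_influx + dir_coef * P_0 (Dirichlet contributions).
.darcy_operator <- function(grid, K) {
  nr <- grid$nr; nz <- grid$nz
  N <- nr * nz
  # radial interior faces: conductance g_r[i] between rings i-1 and i
  g_r <- K * grid$A_rf[2:nr] / (grid$r_c[2:nr] - grid$r_c[1:(nr - 1)])
  Ir <- rep(2:nr, times = nz); Jr <- rep(seq_len(nz), each = nr - 1)
  a_r <- (Jr - 1) * nr + Ir - 1; b_r <- a_r + 1
  x_r <- rep(g_r, times = nz)
  # axial interior faces: conductance g_z[i] between (i,j-1) and (i,j)
  if (nz > 1) {
    g_z <- K * grid$A_zf / grid$dz
    Iz <- rep(seq_len(nr), times = nz - 1); Jz <- rep(2:nz, each = nr)
    a_z <- (Jz - 2) * nr + Iz; b_z <- (Jz - 1) * nr + Iz
    x_z <- rep(g_z, times = nz - 1)
  } else {
    a_z <- b_z <- integer(0); x_z <- numeric(0)
  }
  a <- c(a_r, a_z); b <- c(b_r, b_z); g <- c(x_r, x_z)
  # diagonal accumulation (duplicates summed by sparseMatrix)
  diag_acc <- as.numeric(Matrix::sparseMatrix(
    i = c(a, b), j = rep(1L, 2 * length(a)), x = c(g, g), dims = c(N, 1)))
  dir_coef <- numeric(N)
  # outer Dirichlet face (r = R_T)
  g_out <- K * grid$A_rf[nr + 1] / (grid$r_f[nr + 1] - grid$r_c[nr])
  out_idx <- (seq_len(nz) - 1) * nr + nr
  diag_acc[out_idx] <- diag_acc[out_idx] + g_out
  dir_coef[out_idx] <- dir_coef[out_idx] + g_out
  # end annuli Dirichlet faces (z = 0 and z = L)
  g_end <- K * grid$A_zf / (grid$dz / 2)
  for (j in unique(c(1L, nz))) {
    eidx <- (j - 1) * nr + seq_len(nr)
    diag_acc[eidx] <- diag_acc[eidx] + g_end
    dir_coef[eidx] <- dir_coef[eidx] + g_end
  }
  A <- Matrix::sparseMatrix(i = c(a, b, seq_len(N)),
                            j = c(b, a, seq_len(N)),
                            x = c(-g, -g, diag_acc), dims = c(N, N))
  list(A = A, dir_coef = dir_coef)
}

# 1D Poiseuille-with-leakage vessel solve for a given J_F(z).
# Returns P_v at centres, Q at faces, mean velocity per segment.
.vessel_solve <- function(grid, ip, J_F) {
  nz <- grid$nz
  leak <- J_F * grid$A_wall_seg                 # m^3/s lost per segment
  cl <- c(0, cumsum(leak))                      # cumulative leak at faces
  alpha <- 8 * ip$mu / (pi * ip$R_C^4)
  # P(L) = P_A - alpha * sum_j Q_seg_j dz = P_V with Q_seg_j = Q0 - cl[j] - leak_j/2
  Q0 <- ((ip$P_A - ip$P_V) / (alpha * grid$dz) +
           sum(cl[seq_len(nz)] + leak / 2)) / nz
  Q_f <- Q0 - cl
  if (any(Q_f < 0))
    stop("vessel flow reversal (negative Q): leakage exceeds perfusion")
  Q_seg <- (Q_f[-1] + Q_f[-(nz + 1)]) / 2
  # P_v at cell centres: Q piecewise linear in z
  cumQ_face <- c(0, cumsum(Q_seg) * grid$dz)    # integral of Q to each face
  Q_mid_first_half <- (Q_f[seq_len(nz)] + Q_seg) / 2
  cumQ_center <- cumQ_face[seq_len(nz)] + Q_mid_first_half * grid$dz / 2
  P_v <- ip$P_A - alpha * cumQ_center
  list(P_v = P_v, Q_f = Q_f, Q_seg = Q_seg,
       u_f = Q_f / grid$A_lumen, u_seg = Q_seg / grid$A_lumen)
}

#' Darcy velocities from an interstitial pressure field
#'
#' Face-normal velocities -K dP/dx on interior faces; boundary faces take
#' their boundary-condition values (wall: prescribed filtration velocity
#' `J_F`; outer/end faces: Dirichlet ghost at ambient pressure `P_0`).
#'
#' @param P_i interstitial pressure, matrix `nr x nz` (Pa).
#' @param K tissue hydraulic conductivity (m^2/(Pa s)).
#' @param grid a `tds_grid`.
#' @param P_0 ambient pressure (Pa).
#' @param J_F wall filtration velocity per z segment (m/s); default 0.
#' @return list `u_r` ((nr+1) x nz, positive outward) and `u_z`
#'   (nr x (nz+1), positive toward increasing z).
#' @export
darcy_velocity <- function(P_i, K, grid, P_0 = 0, J_F = NULL) {
  nr <- grid$nr; nz <- grid$nz
  stopifnot(is.matrix(P_i), nrow(P_i) == nr, ncol(P_i) == nz)
  if (is.null(J_F)) J_F <- numeric(nz)
  u_r <- matrix(0, nr + 1, nz)
  u_r[1, ] <- J_F
  if (nr > 1)
    u_r[2:nr, ] <- -K * (P_i[2:nr, , drop = FALSE] -
                           P_i[1:(nr - 1), , drop = FALSE]) /
      (grid$r_c[2:nr] - grid$r_c[1:(nr - 1)])
  u_r[nr + 1, ] <- -K * (P_0 - P_i[nr, ]) / (grid$r_f[nr + 1] - grid$r_c[nr])
  u_z <- matrix(0, nr, nz + 1)
  u_z[, 1] <- -K * (P_i[, 1] - P_0) / (grid$dz / 2)
  if (nz > 1)
    u_z[, 2:nz] <- -K * (P_i[, 2:nz, drop = FALSE] -
                           P_i[, 1:(nz - 1), drop = FALSE]) / grid$dz
  u_z[, nz + 1] <- -K * (P_0 - P_i[, nz]) / (grid$dz / 2)
  list(u_r = u_r, u_z = u_z)
}

#' Solve the steady coupled vascular-interstitial flow problem
#'
#' Fixed-point iteration on the wall filtration velocity: (1) vessel
#' two-point boundary problem (Poiseuille with distributed leakage) given
#' J_F; (2) Darcy pressure solve given J_F as wall Neumann flux; (3)
#' Starling update J_F <- L_p (P_v - P_i,wall) with under-relaxation.
#'
#' @param grid a `tds_grid`.
#' @param ip internal parameters.
#' @param tol relative fixed-point tolerance on J_F.
#' @param max_iter iteration cap.
#' @param relax under-relaxation factor on J_F updates.
#' @return object of class `tds_flow`: vascular pressure `P_v` (Pa, per z
#'   centre), face flows `Q_f`, mean axial velocity `u_v_mean` per segment,
#'   filtration `J_F` per wall face, interstitial pressure `P_i` (nr x nz),
#'   Darcy face velocities `u_r`, `u_z`, and the iteration residual history.
#' @export
solve_flow <- function(grid, ip, tol = 1e-8, max_iter = 200, relax = 0.5) {
  stopifnot(inherits(grid, "tds_grid"), inherits(ip, "tds_internal"))
  if (tol <= 0) stop("tol must be positive")
  nr <- grid$nr; nz <- grid$nz
  if (ip$L_p > 0) {
    op <- .darcy_operator(grid, ip$K)
    ch <- Matrix::Cholesky(op$A, LDL = FALSE)
  }
  J_F <- numeric(nz)
  resid_hist <- numeric(0)
  P_i <- matrix(ip$P_0, nr, nz)
  vess <- .vessel_solve(grid, ip, J_F)
  for (it in seq_len(max_iter)) {
    vess <- .vessel_solve(grid, ip, J_F)
    if (ip$L_p > 0) {
      b <- op$dir_coef * ip$P_0
      wall_idx <- (seq_len(nz) - 1) * nr + 1
      b[wall_idx] <- b[wall_idx] + J_F * grid$A_wall_seg
      P_i <- matrix(as.numeric(Matrix::solve(ch, b)), nr, nz)
    }
    J_new <- starling_flux(vess$P_v, P_i[1, ], ip$L_p)
    resid <- max(abs(J_new - J_F)) / max(max(abs(J_new)), 1e-300)
    resid_hist <- c(resid_hist, resid)
    J_F <- J_F + relax * (J_new - J_F)
    if (resid < tol) break
  }
  if (resid_hist[length(resid_hist)] >= tol && ip$L_p > 0 &&
      length(resid_hist) >= max_iter)
    stop("flow fixed point did not converge; last residual = ",
         signif(resid_hist[length(resid_hist)], 3))
  vess <- .vessel_solve(grid, ip, J_F)
  vel <- darcy_velocity(P_i, ip$K, grid, P_0 = ip$P_0, J_F = J_F)
  structure(list(
    P_v = vess$P_v, Q_f = vess$Q_f, u_v_mean = vess$u_seg, u_f = vess$u_f,
    J_F = J_F, P_i = P_i, u_r = vel$u_r, u_z = vel$u_z,
    iterations = length(resid_hist), resid_hist = resid_hist
  ), class = "tds_flow")
}

#' @method print tds_flow
#' @export
print.tds_flow <- function(x, ...) {
  cat("<tds_flow> steady flow field\n")
  cat("  P_v:", signif(max(x$P_v), 4), "->", signif(min(x$P_v), 4), "Pa;",
      "mean J_F =", signif(mean(x$J_F), 4), "m/s\n")
  cat("  fixed point:", x$iterations, "iterations, final residual",
      signif(x$resid_hist[length(x$resid_hist)], 3), "\n")
  invisible(x)
}
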