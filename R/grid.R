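# Axisymmetric (r, z) finite-volume discretisation.
#
# The interstitial annulus R_C <= r <= R_T is resolved by nr_i cells with
# radial spacing geometrically clustered toward the vessel wall (steep
# concentration boundary layers live there); z is uniform.  The vessel lumen
# is represented by its axial line of cross-section averages (one 1D cell per
# z segment), consistent with the reduced Poiseuille-with-leakage flow model.

#' Build the axisymmetric computational grid
#'
#' Cell-centred finite-volume layout.  Radial cell widths grow geometrically
#' away from the wall with `Delta r_max / Delta r_min = refinement`; the
#' smallest cell is adjacent to the wall.
#'
#' @param ip internal parameters ([to_internal_units()]).
#' @param nr_i number of radial interstitial cells (>= 8 for production
#'   runs; smaller values are accepted for analytic fixtures).
#' @param nz number of axial cells.
#' @param refinement wall-clustering factor (>= 1; 1 = uniform).
#' @return object of class `tds_grid` with coordinates (m), per-radius cell
#'   volumes and face areas, and lumen segment geometry.
#' @export
build_grid <- function(ip, nr_i = 240, nz = 100, refinement = 3) {
  stopifnot(inherits(ip, "tds_internal"))
  if (nr_i < 2 || nz < 1) stop("non-positive or degenerate cell counts")
  if (refinement < 1) stop("refinement must be >= 1")
  span <- ip$R_T - ip$R_C
  if (refinement == 1) {
    dr <- rep(span / nr_i, nr_i)
  } else {
    g <- refinement^(1 / (nr_i - 1))
    dr1 <- span * (g - 1) / (g^nr_i - 1)
    dr <- dr1 * g^(seq_len(nr_i) - 1)
  }
  r_f <- ip$R_C + c(0, cumsum(dr))
  r_f[nr_i + 1] <- ip$R_T            # exact outer radius
  r_c <- 0.5 * (r_f[-1] + r_f[-(nr_i + 1)])
  dz <- ip$L / nz
  z_f <- seq(0, ip$L, length.out = nz + 1)
  z_c <- 0.5 * (z_f[-1] + z_f[-(nz + 1)])

  vol_r <- pi * (r_f[-1]^2 - r_f[-(nr_i + 1)]^2) * dz  # per cell, any z
  A_rf  <- 2 * pi * r_f * dz          # radial face areas (length nr_i+1)
  A_zf  <- pi * (r_f[-1]^2 - r_f[-(nr_i + 1)]^2)  # axial face area per ring

  structure(list(
    nr = nr_i, nz = nz, refinement = refinement,
    r_c = r_c, r_f = r_f, dr = diff(r_f),
    z_c = z_c, z_f = z_f, dz = dz,
    vol_r = vol_r, A_rf = A_rf, A_zf = A_zf,
    # lumen (1D axial line of cross-section averages)
    A_lumen = pi * ip$R_C^2,
    vol_lumen = pi * ip$R_C^2 * dz,
    A_wall_seg = 2 * pi * ip$R_C * dz,  # wall area per z segment
    R_C = ip$R_C, R_T = ip$R_T, L = ip$L
  ), class = "tds_grid")
}

#' Total interstitial volume of a grid
#' @param grid a `tds_grid`.
#' @return volume in m^3.
#' @export
grid_volume <- function(grid) sum(grid$vol_r) * grid$nz

#' Echo grid coordinates as a data frame (debugging aid)
#' @param grid a `tds_grid`.
#' @return data frame of radial cell centres, widths and ring volumes.
#' @export
grid_echo <- function(grid) {
  data.frame(i = seq_len(grid$nr), r_center_m = grid$r_c,
             dr_m = grid$dr, ring_volume_m3 = grid$vol_r)
}

#' @method print tds_grid
#' @export
print.tds_grid <- function(x, ...) {
  cat("<tds_grid>", x$nr, "x", x$nz, "(r x z) interstitial cells,",
      "refinement", x$refinement, "\n")
  cat("  r in [", x$R_C, ",", x$R_T, "] m; wall dr =",
      signif(x$dr[1], 4), "m; dz =", signif(x$dz, 4), "m\n")
  invisible(x)
}
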