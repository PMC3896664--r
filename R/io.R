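# Text exports: CSV profiles/tables and legacy ASCII VTK structured grids.

#' Write flow-field summaries as CSV
#'
#' Writes `flow_axial.csv` (z, P_v, J_F, mean velocity) and `P_i.csv`
#' (long-format interstitial pressure).
#'
#' @param flow a `tds_flow`.
#' @param grid a `tds_grid`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_flow_csv <- function(flow, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "flow_axial.csv")
  utils::write.csv(data.frame(z_m = grid$z_c, P_v_Pa = flow$P_v,
                              J_F_m_per_s = flow$J_F,
                              u_v_mean_m_per_s = flow$u_v_mean),
                   f1, row.names = FALSE)
  f2 <- file.path(dir, "P_i.csv")
  utils::write.csv(data.frame(r_m = rep(grid$r_c, grid$nz),
                              z_m = rep(grid$z_c, each = grid$nr),
                              P_i_Pa = as.numeric(flow$P_i)),
                   f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Write radial profiles at z/L = 0.5 as CSV
#'
#' One file per snapshot with columns r_m, c_E, c_I, R, R1, c_t.
#'
#' @param result a `tds_result`.
#' @param dir output directory.
#' @param z_frac axial position as fraction of L.
#' @return invisibly, the written file paths.
#' @export
write_profiles_csv <- function(result, dir, z_frac = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- which.min(abs(result$grid$z_c - z_frac * result$grid$L))
  paths <- character(0)
  for (s in result$snapshots) {
    fn <- file.path(dir, sprintf("profiles_z%.2f_t%06.0fs.csv", z_frac, s$t))
    utils::write.csv(data.frame(r_m = result$grid$r_c,
                                c_E = s$c_E[, j], c_I = s$c_I[, j],
                                R = s$R[, j], R1 = s$R1[, j],
                                c_t = s$c_t[, j]),
                     fn, row.names = FALSE)
    paths <- c(paths, fn)
  }
  invisible(paths)
}

#' Write a field snapshot as a legacy ASCII VTK structured grid
#'
#' Axisymmetric fields are written on the (r, z) plane as a 2D
#' STRUCTURED_GRID with point data c_E, c_I, c_t, R1.
#'
#' @param result a `tds_result`.
#' @param path output `.vtk` file.
#' @param snapshot snapshot index (default: last).
#' @return invisibly, `path`.
#' @export
write_vtk <- function(result, path, snapshot = NULL) {
  if (is.null(snapshot)) snapshot <- length(result$snapshots)
  s <- result$snapshots[[snapshot]]
  g <- result$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("tumordrugsim fields t=%g s", s$t),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", g$nr, g$nz),
               sprintf("POINTS %d double", g$nr * g$nz)), con)
  pts <- cbind(rep(g$r_c, g$nz), rep(g$z_c, each = g$nr), 0)
  utils::write.table(format(pts, digits = 10, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("POINT_DATA %d", g$nr * g$nz), con)
  for (fld in c("c_E", "c_I", "c_t", "R1")) {
    writeLines(c(sprintf("SCALARS %s double 1", fld),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(s[[fld]]), digits = 10), con)
  }
  invisible(path)
}

#' Write an experiment table as CSV
#'
#' @param table a `tds_experiment` data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_experiment_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
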