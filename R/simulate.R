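# Full-run orchestration and in-silico experiment drivers.
#
# A run solves the steady flow problem once, then advances drug transport
# and cellular dynamics together: per global step the coupled lumen +
# interstitium linear operator (implicit diffusion and implicit wall
# diffusive exchange) is solved with explicit upwind advection and explicit
# convective wall drag in the right-hand side, followed by the pointwise
# reaction step (membrane exchange, apoptosis signalling, gated logistic
# density).  Every step the global drug balance
#   lumen + extracellular + cumulative cellular uptake + cumulative outflow
#   - cumulative inflow
# is audited; a breach above 1% of the cumulative inflow aborts the run.

.default_numerics <- function() {
  c(.numerics_defaults(),
    list(frac = 0.9, onset_frac = 0.99, flow_tol = 1e-8))
}

.merge_numerics <- function(numerics) {
  defs <- .default_numerics()
  if (is.null(numerics)) return(defs)
  unknown <- setdiff(names(numerics), names(defs))
  if (length(unknown))
    stop("unknown numerics key(s): ", paste(unknown, collapse = ", "))
  defs[names(numerics)] <- numerics
  defs
}

#' Run a full coupled simulation
#'
#' Steady flow is solved first (velocity fields are independent of drug and
#' density); then transport and cellular dynamics are advanced to `t_end_h`
#' under the pulse schedule.  Deterministic: no random numbers anywhere.
#'
#' @param params a `tds_params` parameter set.
#' @param numerics named list overriding numerical settings: `nr_i`, `nz`,
#'   `refinement`, `dt_s`, `t_end_h`, `output_every_s`, `frac` (width
#'   threshold fraction), `onset_frac` (density decline defining death
#'   onset), `flow_tol`.
#' @param switch_kind override of `params$switch_kind`.
#' @param pulse a `tds_pulse`; default is the single pulse described by
#'   `params$pulse_S`, `params$pulse_T_h`.
#' @param convection logical; FALSE disables interstitial Darcy advection
#'   and the convective part of the transmural flux (diffusion-only
#'   comparison runs).
#' @param freeze_ct logical; TRUE freezes the cell density seen by the
#'   extracellular sink at its initial value (disables the
#'   transport-density feedback; the density field still evolves for
#'   read-out).
#' @param verbose print step-level progress to stderr.
#' @return object of class `tds_result`: snapshot list, mass-balance
#'   ledger, per-snapshot width metrics, flow field, grid, resolved
#'   parameters and provenance.
#' @export
run_simulation <- function(params, numerics = list(), switch_kind = NULL,
                           pulse = NULL, convection = TRUE,
                           freeze_ct = FALSE, verbose = FALSE) {
  stopifnot(inherits(params, "tds_params"))
  num <- .merge_numerics(numerics)
  ip <- to_internal_units(params)
  kind <- if (is.null(switch_kind)) ip$switch_kind else
    match.arg(switch_kind, c("bistable", "monostable"))
  if (is.null(pulse)) pulse <- pulse_input(ip$pulse_S, ip$pulse_T / 3600)
  t_end <- num$t_end_h * 3600
  if (t_end < max(pulse$segments$start_s + pulse$segments$T_s))
    stop("t_end must cover the pulse schedule")
  dt <- num$dt_s
  nsteps <- max(1L, round(t_end / dt))

  grid <- build_grid(ip, num$nr_i, num$nz, num$refinement)
  flow <- solve_flow(grid, ip, tol = num$flow_tol)
  if (convection) {
    dt_cfl <- .advective_cfl_dt(grid, flow)
    if (dt > dt_cfl)
      stop("advective CFL violation: dt = ", dt, " s exceeds ",
           signif(dt_cfl, 3), " s; reduce dt_s below that value")
  }
  op <- .coupled_operator(grid, ip, flow, dt)
  nr <- grid$nr; nz <- grid$nz
  Vl <- grid$vol_lumen
  Aw <- grid$A_wall_seg
  vol_r <- grid$vol_r

  c_v <- numeric(nz)
  c_E <- matrix(0, nr, nz); c_I <- matrix(0, nr, nz)
  cs <- cell_state(grid, ip)
  R <- cs$R; R1 <- cs$R1; ct <- cs$c_t; latch <- cs$triggered

  inflow_cum <- outflow_cum <- m_I_cum <- 0
  led_t <- led_res <- numeric(nsteps)
  led_mlum <- led_mE <- led_mI <- led_in <- led_out <- numeric(nsteps)
  snapshots <- list()
  snap_every <- max(1L, round(num$output_every_s / dt))
  R1_max <- 0
  death_onset <- NA_real_
  j_mid <- max(1L, round(nz / 2))

  take_snapshot <- function(t) {
    list(t = t, c_v = c_v, c_E = c_E, c_I = c_I, R = R, R1 = R1,
         c_t = ct, triggered = latch)
  }
  snapshots[[1]] <- take_snapshot(0)

  for (n in seq_len(nsteps)) {
    t0 <- (n - 1) * dt
    c_in <- inlet_concentration(pulse, t0)
    conv_flux <- if (convection)
      flow$J_F * (1 - ip$sigma_f) * log_mean_conc(c_v, c_E[1, ])
    else numeric(nz)
    s_lum <- numeric(nz)
    s_lum[1] <- op$rhs_in_coef * c_in
    s_lum <- s_lum - conv_flux * Aw / Vl
    s_E <- matrix(0, nr, nz)
    s_E[1, ] <- conv_flux * Aw / vol_r[1]
    if (convection)
      s_E <- s_E + .advect_interstitial(c_E, flow$u_r, flow$u_z, grid)
    b <- c(c_v + dt * s_lum, as.numeric(c_E) + dt * as.numeric(s_E))
    x <- as.numeric(Matrix::solve(op$lu, b))
    c_v <- x[seq_len(nz)]
    c_E <- matrix(x[-seq_len(nz)], nr, nz)
    mn <- min(c_v, c_E)
    if (mn < -1e-9)
      stop("negative concentration at step ", n, " (t = ", t0,
           " s): min = ", signif(mn, 3), "; scheme failure")
    c_v[c_v < 0] <- 0; c_E[c_E < 0] <- 0

    inflow_cum <- inflow_cum + dt * (flow$u_f[1] * grid$A_lumen * c_in +
                                       op$G_in * (c_in - c_v[1]))
    outflow_cum <- outflow_cum +
      dt * flow$u_f[nz + 1] * grid$A_lumen * c_v[nz]

    rx <- .advance_reactions(c_E, c_I, R, R1,
                             if (freeze_ct) matrix(ip$c_t0, nr, nz) else ct,
                             latch, dt, ip, kind, freeze_ct = FALSE)
    c_E <- rx$c_E; c_I <- rx$c_I; R <- rx$R; R1 <- rx$R1
    latch <- rx$triggered
    if (freeze_ct) {
      # density still evolves for read-out, gated by the same signalling
      gate <- if (kind == "monostable") !latch else R1 < ip$R1_th
      a1_eff <- ip$a1 * gate
      ct <- pmax(ct + dt * ((a1_eff - ip$a2) * ct - ip$b * ct^2), 0)
    } else {
      ct <- rx$c_t
    }
    m_I_cum <- m_I_cum + sum(rx$uptake * vol_r)

    m_lum <- sum(c_v) * Vl
    m_E <- sum(c_E * vol_r)
    resid <- (m_lum + m_E + m_I_cum + outflow_cum - inflow_cum) /
      max(inflow_cum, 1e-300)
    led_t[n] <- n * dt; led_res[n] <- resid
    led_mlum[n] <- m_lum; led_mE[n] <- m_E; led_mI[n] <- m_I_cum
    led_in[n] <- inflow_cum; led_out[n] <- outflow_cum
    if (inflow_cum > 0 && abs(resid) > 0.01)
      stop("mass balance breach at step ", n, ": relative residual = ",
           signif(resid, 3))

    R1_max <- max(R1_max, max(R1))
    if (is.na(death_onset) && min(ct) < num$onset_frac * ip$c_t0)
      death_onset <- n * dt
    if (n %% snap_every == 0 || n == nsteps)
      snapshots[[length(snapshots) + 1]] <- take_snapshot(n * dt)
    if (verbose && n %% 100 == 0)
      message("step ", n, "/", nsteps, " t=", n * dt, "s residual=",
              signif(resid, 3))
  }

  ledger <- data.frame(t_s = led_t, m_lumen = led_mlum, m_extracell = led_mE,
                       m_intracell_cum = led_mI, inflow_cum = led_in,
                       outflow_cum = led_out, residual_rel = led_res)
  widths <- vapply(snapshots, function(s)
    death_region_width(s$c_t[, j_mid], grid, ip$c_t0, num$frac), numeric(1))
  metrics <- data.frame(t_s = vapply(snapshots, `[[`, numeric(1), "t"),
                        width_m = widths)
  structure(list(
    snapshots = snapshots, ledger = ledger, metrics = metrics,
    flow = flow, grid = grid, params = params, internal = ip,
    numerics = num, switch_kind = kind, pulse = pulse,
    convection = convection, freeze_ct = freeze_ct,
    width_final = widths[length(widths)],
    triggered = R1_max >= ip$R1_th, R1_max = R1_max,
    death_onset_s = death_onset, j_mid = j_mid,
    provenance = list(package_version =
                        as.character(utils::packageVersion("tumordrugsim")),
                      grid = c(nr_i = nr, nz = nz,
                               refinement = num$refinement),
                      dt_s = dt, t_end_h = num$t_end_h)
  ), class = "tds_result")
}

#' Width of the tumour-cell death region in a radial density profile
#'
#' The contiguous radial extent, measured outward from the vessel wall,
#' over which the cell density has fallen below `frac` of its initial
#' value.  Returns 0 if the wall-adjacent cell is still above threshold
#' and the full annulus thickness if every cell is below.
#'
#' @param ct_profile radial cell-density profile (length nr, same units as
#'   `c_t0`).
#' @param grid a `tds_grid`.
#' @param c_t0 initial cell density (same units as the profile).
#' @param frac threshold fraction in (0, 1).
#' @return width in metres.
#' @export
death_region_width <- function(ct_profile, grid, c_t0, frac = 0.9) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  stopifnot(length(ct_profile) == grid$nr)
  below <- ct_profile < frac * c_t0
  if (!below[1]) return(0)
  k <- which(!below)
  outer_face <- if (length(k) == 0) grid$nr + 1 else min(k)
  grid$r_f[outer_face] - grid$r_f[1]
}

#' Radial profile of a field at a given axial position
#'
#' @param result a `tds_result`.
#' @param field one of `"c_E"`, `"c_I"`, `"R"`, `"R1"`, `"c_t"`.
#' @param z_frac axial position as a fraction of L.
#' @param snapshot snapshot index (default: last).
#' @return data frame with columns `r_m` and `value`.
#' @export
radial_profile <- function(result, field = "c_t", z_frac = 0.5,
                           snapshot = NULL) {
  stopifnot(inherits(result, "tds_result"))
  if (is.null(snapshot)) snapshot <- length(result$snapshots)
  snap <- result$snapshots[[snapshot]]
  if (!field %in% names(snap) || field == "t")
    stop("unknown field: ", field)
  j <- which.min(abs(result$grid$z_c - z_frac * result$grid$L))
  data.frame(r_m = result$grid$r_c, value = snap[[field]][, j])
}

#' Mass-balance summary of a completed run
#'
#' @param result a `tds_result`.
#' @return list with the final per-compartment masses, cumulative boundary
#'   fluxes, the relative-residual time series and its extrema.
#' @export
mass_balance_report <- function(result) {
  stopifnot(inherits(result, "tds_result"))
  led <- result$ledger
  n <- nrow(led)
  list(
    masses = c(lumen = led$m_lumen[n], extracellular = led$m_extracell[n],
               intracellular_cum = led$m_intracell_cum[n]),
    fluxes = c(inflow_cum = led$inflow_cum[n],
               outflow_cum = led$outflow_cum[n]),
    residual_series = data.frame(t_s = led$t_s,
                                 residual_rel = led$residual_rel),
    final_residual = led$residual_rel[n],
    max_abs_residual = max(abs(led$residual_rel))
  )
}

#' Pulse-characteristics experiment (infusion time and intensity sweeps)
#'
#' One run per infusion time (at the base intensity) and per intensity (at
#' the base infusion time), for each requested switch mode; death-region
#' widths at the end time are tabulated relative to the baseline pulse.
#'
#' @param base base `tds_params`.
#' @param T_list_h infusion times to scan (h).
#' @param S_list intensities to scan.
#' @param numerics numerics overrides (see [run_simulation()]).
#' @param switch_kinds character vector of switch modes to run.
#' @return data frame (class `tds_experiment`) with columns `experiment`,
#'   `switch_kind`, `S`, `T_h`, `width_m`, `rel_width`, `triggered`.
#' @export
experiment_pulse_characteristics <- function(base, T_list_h, S_list,
                                             numerics = list(),
                                             switch_kinds = c("bistable",
                                                              "monostable")) {
  if (length(T_list_h) == 0 || length(S_list) == 0)
    stop("T and S lists must be non-empty")
  rows <- list()
  for (kind in switch_kinds) {
    base_run <- run_simulation(base, numerics, switch_kind = kind)
    w0 <- base_run$width_final
    rows[[length(rows) + 1]] <- data.frame(
      experiment = "baseline", switch_kind = kind, S = base$pulse_S,
      T_h = base$pulse_T_h, width_m = w0,
      rel_width = if (w0 > 0) 1 else NA_real_, triggered = base_run$triggered)
    for (T_h in T_list_h) {
      r <- if (identical(T_h, base$pulse_T_h)) base_run else
        run_simulation(base, numerics, switch_kind = kind,
                       pulse = pulse_input(base$pulse_S, T_h))
      rows[[length(rows) + 1]] <- data.frame(
        experiment = "infusion_time", switch_kind = kind, S = base$pulse_S,
        T_h = T_h, width_m = r$width_final,
        rel_width = if (w0 > 0) r$width_final / w0 else NA_real_,
        triggered = r$triggered)
    }
    for (S in S_list) {
      r <- if (identical(S, base$pulse_S)) base_run else
        run_simulation(base, numerics, switch_kind = kind,
                       pulse = pulse_input(S, base$pulse_T_h))
      rows[[length(rows) + 1]] <- data.frame(
        experiment = "pulse_intensity", switch_kind = kind, S = S,
        T_h = base$pulse_T_h, width_m = r$width_final,
        rel_width = if (w0 > 0) r$width_final / w0 else NA_real_,
        triggered = r$triggered)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tds_experiment", "data.frame")
  out
}

#' Dose-fractionation experiment (constant S x T)
#'
#' Runs every schedule with both switch modes and tabulates death-region
#' widths, death onset times, and the monostable/bistable width ratio.
#'
#' @param base base `tds_params`.
#' @param schedules data frame with columns `S` and `T_h`; all schedules
#'   must share the same dose S*T.
#' @param numerics numerics overrides.
#' @return data frame (class `tds_experiment`) with one row per
#'   (schedule, switch mode); attribute `"ratios"` holds the per-schedule
#'   monostable/bistable width ratios.
#' @export
experiment_fractionation <- function(base,
                                     schedules = data.frame(
                                       S = c(2, 1, 2 / 3, 0.5),
                                       T_h = c(1, 2, 3, 4)),
                                     numerics = list()) {
  dose <- schedules$S * schedules$T_h
  if (max(dose) - min(dose) > 1e-9 * max(dose))
    stop("all schedules must share the same dose S*T")
  rows <- list()
  base_w <- list()
  for (kind in c("bistable", "monostable")) {
    base_run <- run_simulation(base, numerics, switch_kind = kind)
    base_w[[kind]] <- base_run$width_final
  }
  width_mat <- matrix(NA_real_, nrow(schedules), 2,
                      dimnames = list(NULL, c("bistable", "monostable")))
  for (si in seq_len(nrow(schedules))) {
    for (kind in c("bistable", "monostable")) {
      r <- run_simulation(base, numerics, switch_kind = kind,
                          pulse = pulse_input(schedules$S[si],
                                              schedules$T_h[si]))
      width_mat[si, kind] <- r$width_final
      w0 <- base_w[[kind]]
      rows[[length(rows) + 1]] <- data.frame(
        schedule = si, S = schedules$S[si], T_h = schedules$T_h[si],
        switch_kind = kind, width_m = r$width_final,
        rel_width = if (w0 > 0) r$width_final / w0 else NA_real_,
        death_onset_h = r$death_onset_s / 3600, triggered = r$triggered)
    }
  }
  out <- do.call(rbind, rows)
  ratios <- data.frame(schedule = seq_len(nrow(schedules)),
                       S = schedules$S, T_h = schedules$T_h,
                       ratio_mono_over_bi =
                         width_mat[, "monostable"] /
                         ifelse(width_mat[, "bistable"] > 0,
                                width_mat[, "bistable"], NA_real_))
  attr(out, "ratios") <- ratios
  class(out) <- c("tds_experiment", "data.frame")
  out
}

#' One-parameter sensitivity sweep
#'
#' Multiplies a transport or geometric parameter by each factor and runs
#' the simulation, tabulating the death-region width and whether apoptosis
#' was triggered anywhere.
#'
#' @param base base `tds_params`.
#' @param name one of `"D_E"`, `"P_wall"`, `"R_T"`, `"L_p"`, `"K"`.
#' @param factors positive multipliers.
#' @param numerics numerics overrides.
#' @param switch_kind switch mode for the sweep.
#' @param pulse optional `tds_pulse` overriding the base pulse (e.g. a
#'   higher-dosage arm).
#' @return data frame (class `tds_experiment`) with columns `param`,
#'   `factor`, `value`, `width_m`, `rel_width`, `triggered`.
#' @export
sweep_parameter <- function(base, name, factors, numerics = list(),
                            switch_kind = "bistable", pulse = NULL) {
  key <- switch(name, D_E = "D_E", P_wall = "P_wall", R_T = "R_T_um",
                L_p = "L_p", K = "K_tissue",
                stop("unknown parameter id: ", name))
  if (any(factors <= 0)) stop("factors must be positive")
  rows <- list()
  w1 <- NA_real_
  for (f in factors) {
    pl <- unclass(base)[names(.param_defaults())]
    pl[[key]] <- f * base[[key]]
    p <- do.call(model_parameters, pl)
    r <- run_simulation(p, numerics, switch_kind = switch_kind, pulse = pulse)
    if (f == 1) w1 <- r$width_final
    rows[[length(rows) + 1]] <- data.frame(
      param = name, factor = f, value = p[[key]], width_m = r$width_final,
      triggered = r$triggered)
  }
  out <- do.call(rbind, rows)
  ref <- if (!is.na(w1) && w1 > 0) w1 else
    if (out$width_m[1] > 0) out$width_m[1] else NA_real_
  out$rel_width <- out$width_m / ref
  class(out) <- c("tds_experiment", "data.frame")
  out
}

#' @method print tds_result
#' @export
print.tds_result <- function(x, ...) {
  cat("<tds_result>", x$switch_kind, "switch,",
      x$numerics$t_end_h, "h,", x$grid$nr, "x", x$grid$nz, "grid\n")
  cat("  death-region width:", signif(x$width_final * 1e6, 4), "um",
      "(frac =", x$numerics$frac, ")\n")
  cat("  apoptosis triggered:", x$triggered,
      "; final balance residual:",
      signif(x$ledger$residual_rel[nrow(x$ledger)], 3), "\n")
  invisible(x)
}
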