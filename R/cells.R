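# Coarse-grained intracellular apoptosis signalling and tumour cell density.
#
# Two interchangeable switch modules drive a downstream trigger species R1:
#  - a bistable switch (saturable activation, positive feedback proportional
#    to (p + q c_I), saturable deactivation) whose high state persists even
#    after the drug input is withdrawn (intrinsic irreversibility);
#  - an irreversible monostable switch (Hill response to c_I with first-order
#    relaxation) whose irreversibility is imposed downstream by latching the
#    growth-rate gate on first threshold crossing.
# Crossing the R1 threshold gates the logistic growth rate to zero, making
# c_t = 0 the only attractor of the density dynamics in the gated region.
#
# The exported rhs/analysis functions work in the tabulated laboratory time
# units (1/hr for signalling, 1/day for growth) on `tds_params`; the
# simulation loop uses the 1/s internal versions.

#' Bistable apoptosis switch rate
#'
#' dR/dt = Vf (1-R)/(Km1 + (1-R)) + (p + q c_I) kfb R (1-R) - Vr R/(Km2 + R),
#' in 1/hr, with the intracellular drug concentration c_I (normalised) as
#' input to the feedback term.
#'
#' @param R normalised switch species in [0, 1] (vectorised).
#' @param c_I normalised intracellular drug concentration.
#' @param params a `tds_params` object (Table-style laboratory units).
#' @return dR/dt in 1/hr.
#' @export
bistable_rhs <- function(R, c_I, params) {
  params$Vf * (1 - R) / (params$Km1 + (1 - R)) +
    (params$p + params$q * c_I) * params$kfb * R * (1 - R) -
    params$Vr * R / (params$Km2 + R)
}

#' Irreversible monostable switch rate
#'
#' dR/dt = k (c_I^n / (kh + c_I^n) - R) in 1/hr.  The Hill denominator is
#' taken literally as kh + c_I^n (`hill_denominator = "literal"`); the
#' homogeneous alternative kh^n + c_I^n is available as a parameter flag
#' (identical at kh = 1, but the units of kh differ).
#'
#' @inheritParams bistable_rhs
#' @return dR/dt in 1/hr.
#' @export
monostable_rhs <- function(R, c_I, params) {
  khn <- if (params$hill_denominator == "homogeneous")
    params$kh^params$n_hill else params$kh
  params$k_mono * (c_I^params$n_hill / (khn + c_I^params$n_hill) - R)
}

#' Downstream trigger species rate
#'
#' dR1/dt = kf R (1 - R1) - kr R1 in 1/hr: activation proportional to the
#' upstream switch species and saturating in R1, first-order degradation.
#'
#' @param R1 normalised trigger species in [0, 1].
#' @param R normalised upstream switch species.
#' @param params a `tds_params`.
#' @return dR1/dt in 1/hr.
#' @export
r1_rhs <- function(R1, R, params) {
  params$kf * R * (1 - R1) - params$kr * R1
}

#' Logistic tumour-cell-density rate
#'
#' dc_t/dt = a1_eff c_t - a2 c_t - b c_t^2 in (1e5 cells/mm^3)/day.  The
#' non-trivial steady state is (a1 - a2)/b; with the growth rate gated to
#' zero the only attractor is c_t = 0.
#'
#' @param c_t cell density (1e5 cells/mm^3 units, vectorised).
#' @param a1_eff effective growth rate (1/day), possibly gated.
#' @param params a `tds_params`.
#' @return dc_t/dt in (1e5 cells/mm^3)/day.
#' @export
logistic_rhs <- function(c_t, a1_eff, params) {
  a1_eff * c_t - params$a2 * c_t - params$b * c_t^2
}

#' Steady states of the bistable switch at a fixed drug input
#'
#' Finds all roots of the bistable rate in [0, 1] by a sign-change scan at
#' resolution `dR` refined by bisection to 1e-10, and classifies stability
#' from the local slope.
#'
#' @param c_I normalised intracellular drug concentration (scalar).
#' @param params a `tds_params`.
#' @param dR scan resolution.
#' @return data frame with columns `R` (root) and `stable` (logical),
#'   ordered by R.
#' @export
bistable_steady_states <- function(c_I, params, dR = 1e-4) {
  f <- function(R) bistable_rhs(R, c_I, params)
  Rg <- seq(0, 1, by = dR)
  v <- f(Rg)
  sgn <- which(v[-1] * v[-length(v)] < 0)
  exact <- which(v == 0)
  roots <- numeric(0)
  for (i in sgn)
    roots <- c(roots, stats::uniroot(f, c(Rg[i], Rg[i + 1]),
                                     tol = 1e-12)$root)
  roots <- sort(unique(c(roots, Rg[exact])))
  if (length(roots) > 1 && any(diff(roots) < 2 * dR))
    stop("scan resolution too coarse to separate roots; decrease dR")
  h <- 1e-7
  stable <- vapply(roots, function(r) {
    (f(min(r + h, 1)) - f(max(r - h, 0))) < 0
  }, logical(1))
  data.frame(R = roots, stable = stable)
}

#' Saddle-node input level of the bistable switch
#'
#' Smallest intracellular drug concentration at which the stable low branch
#' disappears (the switch becomes monostable-high), located by bisection on
#' the root count.
#'
#' @param params a `tds_params`.
#' @param c_I_max upper end of the scanned input range.
#' @param tol relative bisection tolerance.
#' @param dR root-scan resolution.
#' @return the saddle-node input c_I* (normalised).
#' @export
switch_input_threshold <- function(params, c_I_max = 100, tol = 1e-6,
                                   dR = 1e-4) {
  # near the saddle the outer roots approach each other; refine the scan
  # adaptively, and once they are closer than the finest resolution treat
  # the state as still bistable (the bias is far below `tol`)
  nroots <- function(c) {
    dR_try <- dR
    repeat {
      out <- tryCatch(nrow(bistable_steady_states(c, params, dR_try)),
                      error = function(e) {
                        if (grepl("too coarse", conditionMessage(e))) NA_integer_
                        else stop(e)
                      })
      if (!is.na(out)) return(out)
      if (dR_try <= 1.1e-6) return(3L)
      dR_try <- dR_try / 10
    }
  }
  if (params$q <= 0)
    stop("no bifurcation in the input: q = 0 decouples c_I from the switch")
  if (nroots(0) != 3)
    stop("switch is not bistable at zero input with these parameters")
  if (nroots(c_I_max) != 1)
    stop("no bifurcation found below c_I = ", c_I_max)
  lo <- 0; hi <- c_I_max
  while ((hi - lo) > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (nroots(mid) == 1) hi <- mid else lo <- mid
  }
  hi
}

#' Effective growth rate under the apoptosis gate
#'
#' Bistable mode: the gate follows R1 each evaluation (a1 where R1 < R1_th,
#' 0 otherwise); reversibility at this level is inherited from the switch
#' itself, whose high state is self-sustaining.  Monostable mode: a per-cell
#' latch is set permanently on first crossing and the growth rate stays 0
#' wherever latched.
#'
#' @param cell_state list with elements `R1` (numeric) and `triggered`
#'   (logical, same shape; the monostable latch).
#' @param mode `"bistable"` or `"monostable"`.
#' @param params a `tds_params`.
#' @return list `a1_eff` (1/day, shaped like R1) and `triggered` (updated
#'   latch).
#' @export
effective_growth <- function(cell_state, mode = c("bistable", "monostable"),
                             params) {
  mode <- match.arg(mode)
  R1 <- cell_state$R1
  trig <- cell_state$triggered
  if (is.null(trig)) trig <- R1 >= params$R1_th & FALSE
  if (mode == "monostable") {
    trig <- trig | (R1 >= params$R1_th)
    a1_eff <- ifelse(trig, 0, params$a1)
  } else {
    a1_eff <- ifelse(R1 >= params$R1_th, 0, params$a1)
  }
  list(a1_eff = a1_eff, triggered = trig)
}

#' Initial cell state on a grid
#'
#' Uniform live cell density at `c_t0`; signalling species at zero
#' (pre-injection initial condition).
#'
#' @param grid a `tds_grid`.
#' @param ip internal parameters.
#' @return object of class `tds_cell_state`: matrices `R`, `R1`, `c_t`
#'   (1e5 cells/mm^3 units) and logical latch `triggered`.
#' @export
cell_state <- function(grid, ip) {
  z <- matrix(0, grid$nr, grid$nz)
  structure(list(R = z, R1 = z, c_t = z + ip$c_t0,
                 triggered = matrix(FALSE, grid$nr, grid$nz)),
            class = "tds_cell_state")
}

# ---- vectorised local reaction integrator (internal units, 1/s) -----------

# One global-step advance of the pointwise system
#   c_E' = -c_t * X * conv,  c_I' = X,  R' = switch(R, c_I),
#   R1' = kf R (1 - R1) - kr R1,  c_t' = (a1_eff - a2) c_t - b c_t^2,
# with X = V1 c_E/(c_E + k1) - V2 c_I/(c_I + k2), using n_sub RK4 substeps.
# The growth gate (and monostable latch) is evaluated at each substep start
# and held frozen across the substep's RK stages.  Also accumulates the net
# cellular uptake (extracellular mass units) for the balance ledger.
.advance_reactions <- function(cE, cI, R, R1, ct, latch, dt, ip,
                               switch_kind, freeze_ct = FALSE,
                               n_sub = NULL) {
  if (is.null(n_sub)) {
    lam <- max(ct) * ip$V1 * ip$uptake_conv / ip$k1 + ip$V2 / ip$k2 +
      ip$Vr / ip$Km2 + ip$Vf / ip$Km1 + ip$kf + ip$k_mono
    n_sub <- max(1L, ceiling(dt * lam / 0.8))
  }
  h <- dt / n_sub
  khn <- if (ip$hill_denominator == "homogeneous") ip$kh^ip$n_hill else ip$kh
  bist <- switch_kind == "bistable"
  up_cum <- cE * 0
  for (s in seq_len(n_sub)) {
    if (bist) {
      gate <- R1 < ip$R1_th
    } else {
      latch <- latch | (R1 >= ip$R1_th)
      gate <- !latch
    }
    a1_eff <- ip$a1 * gate
    rhs <- function(e, i, r, r1, c) {
      X <- ip$V1 * e / (e + ip$k1) - ip$V2 * i / (i + ip$k2)
      dR <- if (bist)
        ip$Vf * (1 - r) / (ip$Km1 + (1 - r)) +
          (ip$p_basal + ip$q * i) * ip$kfb * r * (1 - r) -
          ip$Vr * r / (ip$Km2 + r)
      else
        ip$k_mono * (i^ip$n_hill / (khn + i^ip$n_hill) - r)
      list(de = -c * X * ip$uptake_conv,
           di = X,
           dr = dR,
           dr1 = ip$kf * r * (1 - r1) - ip$kr * r1,
           dc = if (freeze_ct) 0 * c else (a1_eff - ip$a2) * c - ip$b * c^2,
           du = c * X * ip$uptake_conv)
    }
    k1 <- rhs(cE, cI, R, R1, ct)
    k2 <- rhs(cE + h / 2 * k1$de, cI + h / 2 * k1$di, R + h / 2 * k1$dr,
              R1 + h / 2 * k1$dr1, ct + h / 2 * k1$dc)
    k3 <- rhs(cE + h / 2 * k2$de, cI + h / 2 * k2$di, R + h / 2 * k2$dr,
              R1 + h / 2 * k2$dr1, ct + h / 2 * k2$dc)
    k4 <- rhs(cE + h * k3$de, cI + h * k3$di, R + h * k3$dr,
              R1 + h * k3$dr1, ct + h * k3$dc)
    cE <- pmax(cE + h / 6 * (k1$de + 2 * k2$de + 2 * k3$de + k4$de), 0)
    cI <- pmax(cI + h / 6 * (k1$di + 2 * k2$di + 2 * k3$di + k4$di), 0)
    R  <- pmin(pmax(R + h / 6 * (k1$dr + 2 * k2$dr + 2 * k3$dr + k4$dr), 0), 1)
    R1 <- pmin(pmax(R1 + h / 6 * (k1$dr1 + 2 * k2$dr1 + 2 * k3$dr1 + k4$dr1),
                    0), 1)
    ct <- pmax(ct + h / 6 * (k1$dc + 2 * k2$dc + 2 * k3$dc + k4$dc), 0)
    up_cum <- up_cum + h / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
  }
  if (!bist) latch <- latch | (R1 >= ip$R1_th)
  list(c_E = cE, c_I = cI, R = R, R1 = R1, c_t = ct, triggered = latch,
       uptake = up_cum)
}

#' Integrate the local reaction system at fixed conditions
#'
#' Advances the pointwise membrane-exchange + signalling + density system
#' over a time interval with no transport, using the same sub-stepped RK4
#' integrator as the full simulation.  Useful for studying the switch
#' dynamics under controlled drug exposure.
#'
#' @param state list with numeric fields `c_E`, `c_I`, `R`, `R1`, `c_t`
#'   (any common shape) and optionally logical `triggered`.
#' @param duration_s integration time (s).
#' @param ip internal parameters.
#' @param switch_kind `"bistable"` or `"monostable"`.
#' @param dt_s sub-interval length between gate re-evaluations (s).
#' @return the advanced state (same fields, plus `triggered`).
#' @export
advance_reactions <- function(state, duration_s, ip,
                              switch_kind = ip$switch_kind, dt_s = 10) {
  latch <- state$triggered
  if (is.null(latch)) latch <- state$R1 >= 2  # all FALSE, shape of R1
  cE <- state$c_E; cI <- state$c_I; R <- state$R; R1 <- state$R1
  ct <- state$c_t
  nstep <- max(1L, ceiling(duration_s / dt_s))
  h <- duration_s / nstep
  for (n in seq_len(nstep)) {
    out <- .advance_reactions(cE, cI, R, R1, ct, latch, h, ip, switch_kind)
    cE <- out$c_E; cI <- out$c_I; R <- out$R; R1 <- out$R1; ct <- out$c_t
    latch <- out$triggered
  }
  list(c_E = cE, c_I = cI, R = R, R1 = R1, c_t = ct, triggered = latch)
}
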