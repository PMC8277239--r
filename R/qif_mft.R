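# Exact mean-field reduction of all-to-all QIF networks with Lorentzian
# heterogeneity, its limit cycles, the adjoint-based infinitesimal
# macroscopic PRC, and finite-amplitude PRCs on the reduced system.
#
# ING (state r, V, s1, s2):
#   tau r' = Delta/(pi tau) + 2 r V
#   tau V' = V^2 + eta_bar - tau (s2 - s1) - tau^2 pi^2 r^2
#   s1' = -s1/tau1 + J r ,  s2' = -s2/tau2 + J r
# PING (state r_I, V_I, r_E, V_E, s_EI1, s_EI2, s_IE1, s_IE2): analogous,
# with +tau_I s_IE driving I and -tau_E s_EI driving E.

#' Mean-field parameter set
#'
#' @param family `"ING"` or `"PING"`.
#' @param tau_i,tau_e membrane time constants.
#' @param eta_i,eta_e drive-distribution centers (`eta_i` defaults to 20
#'   for ING and -5 for PING).
#' @param delta_i,delta_e drive half-widths (> 0; `delta_i` defaults to 3
#'   for ING and 1 for PING).
#' @param J_ii,J_ei,J_ie synaptic strengths (I-I for ING; I-to-E and E-to-I
#'   for PING).
#' @param tau1,tau2 synaptic rise/decay constants, `tau2 > tau1`.
#' @return list of class `mf_params`.
#' @export
mf_params <- function(family = c("ING", "PING"), tau_i = 10, eta_i = NULL,
                      delta_i = NULL, J_ii = 15, tau_e = 10, eta_e = 5,
                      delta_e = 1, J_ei = 15, J_ie = 15,
                      tau1 = 0.98, tau2 = 1) {
  family <- match.arg(family)
  # family-dependent reference drives: tonically active I for ING, I driven
  # only through E for PING
  eta_i <- eta_i %||% if (family == "ING") 20 else -5
  delta_i <- delta_i %||% if (family == "ING") 3 else 1
  stopifnot(tau2 > tau1, tau1 > 0, delta_i > 0)
  if (family == "PING") stopifnot(delta_e > 0)
  structure(list(family = family, tau_i = tau_i, eta_i = eta_i,
                 delta_i = delta_i, J_ii = J_ii, tau_e = tau_e,
                 eta_e = eta_e, delta_e = delta_e, J_ei = J_ei,
                 J_ie = J_ie, tau1 = tau1, tau2 = tau2),
            class = "mf_params")
}

#' Mean-field vector field
#'
#' @param state named state vector: ING `(r, V, s1, s2)`; PING
#'   `(rI, VI, rE, VE, sEI1, sEI2, sIE1, sIE2)`.
#' @param p an [mf_params()].
#' @param I_ext additive current(s): scalar for ING (to V); for PING a named
#'   vector `c(I = ..., E = ...)`.
#' @return derivative vector.
#' @export
mf_rhs <- function(state, p, I_ext = 0) {
  if (p$family == "ING") {
    r <- state[1]; V <- state[2]; s1 <- state[3]; s2 <- state[4]
    c(r = (p$delta_i / (pi * p$tau_i) + 2 * r * V) / p$tau_i,
      V = (V^2 + p$eta_i - p$tau_i * (s2 - s1) - p$tau_i^2 * pi^2 * r^2 +
             I_ext[1]) / p$tau_i,
      s1 = -s1 / p$tau1 + p$J_ii * r / (p$tau2 - p$tau1),
      s2 = -s2 / p$tau2 + p$J_ii * r / (p$tau2 - p$tau1))
  } else {
    rI <- state[1]; VI <- state[2]; rE <- state[3]; VE <- state[4]
    sEI1 <- state[5]; sEI2 <- state[6]; sIE1 <- state[7]; sIE2 <- state[8]
    Ii <- if (length(I_ext) > 1) I_ext[["I"]] else 0
    Ie <- if (length(I_ext) > 1) I_ext[["E"]] else I_ext[1]
    c(rI = (p$delta_i / (pi * p$tau_i) + 2 * rI * VI) / p$tau_i,
      VI = (VI^2 + p$eta_i + p$tau_i * (sIE2 - sIE1) -
              p$tau_i^2 * pi^2 * rI^2 + Ii) / p$tau_i,
      rE = (p$delta_e / (pi * p$tau_e) + 2 * rE * VE) / p$tau_e,
      VE = (VE^2 + p$eta_e - p$tau_e * (sEI2 - sEI1) -
              p$tau_e^2 * pi^2 * rE^2 + Ie) / p$tau_e,
      sEI1 = -sEI1 / p$tau1 + p$J_ei * rI / (p$tau2 - p$tau1),
      sEI2 = -sEI2 / p$tau2 + p$J_ei * rI / (p$tau2 - p$tau1),
      sIE1 = -sIE1 / p$tau1 + p$J_ie * rE / (p$tau2 - p$tau1),
      sIE2 = -sIE2 / p$tau2 + p$J_ie * rE / (p$tau2 - p$tau1))
  }
}

#' Jacobian of the mean-field vector field
#' @inheritParams mf_rhs
#' @return square matrix.
#' @export
mf_jacobian <- function(state, p) {
  if (p$family == "ING") {
    r <- state[1]; V <- state[2]
    ti <- p$tau_i
    matrix(c(
      2 * V / ti,            2 * r / ti,  0,            0,
      -2 * ti * pi^2 * r,    2 * V / ti,  1,           -1,
      p$J_ii / (p$tau2 - p$tau1), 0,    -1 / p$tau1,   0,
      p$J_ii / (p$tau2 - p$tau1), 0,     0,            -1 / p$tau2),
      nrow = 4, byrow = TRUE)
  } else {
    rI <- state[1]; VI <- state[2]; rE <- state[3]; VE <- state[4]
    ti <- p$tau_i; te <- p$tau_e
    J <- matrix(0, 8, 8)
    J[1, 1] <- 2 * VI / ti; J[1, 2] <- 2 * rI / ti
    J[2, 1] <- -2 * ti * pi^2 * rI; J[2, 2] <- 2 * VI / ti
    J[2, 7] <- -1; J[2, 8] <- 1
    J[3, 3] <- 2 * VE / te; J[3, 4] <- 2 * rE / te
    J[4, 3] <- -2 * te * pi^2 * rE; J[4, 4] <- 2 * VE / te
    J[4, 5] <- 1; J[4, 6] <- -1
    nrm <- 1 / (p$tau2 - p$tau1)
    J[5, 1] <- p$J_ei * nrm; J[5, 5] <- -1 / p$tau1
    J[6, 1] <- p$J_ei * nrm; J[6, 6] <- -1 / p$tau2
    J[7, 3] <- p$J_ie * nrm; J[7, 7] <- -1 / p$tau1
    J[8, 3] <- p$J_ie * nrm; J[8, 8] <- -1 / p$tau2
    J
  }
}

mf_state_names <- function(p) {
  if (p$family == "ING") c("r", "V", "s1", "s2")
  else c("rI", "VI", "rE", "VE", "sEI1", "sEI2", "sIE1", "sIE2")
}

mf_s_index <- function(p) {
  # indices (s2, s1) of the anchoring synaptic variable s = s2 - s1
  if (p$family == "ING") c(4L, 3L) else c(6L, 5L)
}

mf_ode <- function(t, y, parms) {
  list(mf_rhs(y, parms$p, parms$I_ext))
}

mf_integrate <- function(p, y0, times, I_ext = 0, rtol = 1e-8, atol = 1e-10) {
  out <- ode(y = y0, times = times, func = mf_ode,
             parms = list(p = p, I_ext = I_ext),
             method = "lsoda", rtol = rtol, atol = atol)
  out <- as.matrix(out)
  colnames(out) <- c("time", mf_state_names(p))
  out
}

mf_default_init <- function(p) {
  if (p$family == "ING") c(r = 0.05, V = -1, s1 = 0, s2 = 0)
  else c(rI = 0.05, VI = -1, rE = 0.05, VE = -1,
         sEI1 = 0, sEI2 = 0, sIE1 = 0, sIE2 = 0)
}

# quadratic interpolation of a local maximum of x sampled at uniform dt
refine_peak <- function(tt, x, i) {
  if (i <= 1 || i >= length(x)) return(c(tt[i], x[i]))
  den <- x[i - 1] - 2 * x[i] + x[i + 1]
  d <- if (abs(den) < 1e-300) 0 else (x[i - 1] - x[i + 1]) / (2 * den)
  if (!is.finite(d) || abs(d) > 1) d <- 0
  dt <- tt[2] - tt[1]
  c(tt[i] + d * dt, x[i] - 0.25 * (x[i - 1] - x[i + 1]) * d)
}

peak_locs <- function(x) {
  # local maxima, robust to flat plateaus at the sampled resolution
  ds <- sign(diff(x))
  nz <- ds != 0
  if (!any(nz)) return(integer(0))
  idx <- cummax(ifelse(nz, seq_along(ds), 0L))
  ds <- ifelse(idx > 0, ds[pmax(idx, 1L)], 0)
  which(diff(ds) == -2) + 1L
}

peak_times <- function(tt, s) {
  loc <- peak_locs(s)
  amp <- max(s) - min(s)
  loc <- loc[s[loc] > min(s) + 0.5 * amp]   # major peaks only
  vapply(loc, function(i) refine_peak(tt, s, i)[1], 0)
}

#' Find the limit cycle of the mean-field system
#'
#' Integrates from a generic initial condition through a transient, detects
#' convergence of the inter-peak interval of the anchoring synaptic variable
#' (`s_II` for ING, `s_EI` for PING), and samples one period densely with
#' phase 0 anchored at the interpolated peak of that variable.
#'
#' @param p an [mf_params()].
#' @param transient transient integration time.
#' @param n_samples samples per period of the returned orbit.
#' @param period_tol relative tolerance on successive inter-peak intervals.
#' @param rtol,atol integrator tolerances.
#' @return object of class `mf_limit_cycle`: `period`, `time` (phase *
#'   period), `states` (matrix, anchored at the s-peak), `p`.
#' @export
find_limit_cycle <- function(p, transient = 400, n_samples = 2048,
                             period_tol = 1e-5, rtol = 1e-8, atol = 1e-10) {
  y0 <- mf_default_init(p)
  dt <- 0.02
  sidx <- mf_s_index(p)
  sname2 <- mf_state_names(p)[sidx[1]]; sname1 <- mf_state_names(p)[sidx[2]]
  vcol <- if (p$family == "ING") "V" else "VI"
  half <- NULL; s <- NULL; pks <- NULL
  for (attempt in 1:2) {
    run <- tryCatch(
      mf_integrate(p, y0, seq(0, transient, by = dt), rtol = rtol,
                   atol = atol),
      error = function(e) NULL)
    if (is.null(run) || any(!is.finite(run))) stop("divergent")
    if (max(abs(run[, vcol])) > 1e4) stop("divergent")
    half <- run[run[, "time"] > transient / 2, ]
    s <- half[, sname2] - half[, sname1]
    if (max(s) - min(s) < 1e-8 * max(abs(s), 1e-12)) stop("non-oscillatory")
    # distinguish a limit cycle from a decaying focus: the swing of s must
    # not shrink across the analysis window
    n2 <- nrow(half) %/% 2
    amp1 <- diff(range(s[seq_len(n2)]))
    amp2 <- diff(range(s[(n2 + 1):length(s)]))
    if (amp2 < 1e-10 || amp2 < 0.5 * amp1) stop("non-oscillatory")
    if (amp2 >= 0.98 * amp1) break
    if (attempt == 2) stop("non-oscillatory")
    transient <- transient * 3        # still ringing down: integrate longer
  }
  pks <- peak_times(half[, "time"], s)
  if (length(pks) < 5) stop("non-oscillatory")
  ipi <- diff(pks)
  m <- length(ipi)
  if (abs(ipi[m] - ipi[m - 1]) > period_tol * ipi[m] * 10) {
    stop("limit cycle did not converge")
  }
  period <- mean(tail(ipi, 3))
  # re-sample one period from the last full peak
  t0 <- pks[length(pks) - 1]
  y1 <- half[max(which(half[, "time"] <= t0)), -1]
  # small correction integrate to exact t0
  tt <- seq(0, period, length.out = n_samples + 1)
  t_off <- t0 - half[max(which(half[, "time"] <= t0)), "time"]
  seg <- mf_integrate(p, y1, c(0, t_off + tt), rtol = rtol, atol = atol)
  states <- seg[-1, -1, drop = FALSE][seq_len(n_samples + 1), , drop = FALSE]
  structure(list(period = period, time = tt, states = states, p = p),
            class = "mf_limit_cycle")
}

#' @export
print.mf_limit_cycle <- function(x, ...) {
  cat(sprintf("<mf_limit_cycle: %s, T=%.4f>\n", x$p$family, x$period))
  invisible(x)
}

lc_interp <- function(lc) {
  # periodic interpolant of the orbit, columnwise; the residual closure
  # error of the sampled orbit is forced shut
  tt <- lc$time
  st <- lc$states
  st[nrow(st), ] <- st[1, ]
  funs <- lapply(seq_len(ncol(st)), function(j)
    splinefun(tt, st[, j], method = "periodic"))
  function(t) {
    tm <- t %% lc$period
    vapply(funs, function(f) f(tm), 0)
  }
}

#' Adjoint-based infinitesimal macroscopic PRC
#'
#' Computes the periodic solution of the adjoint equation
#' `dZ/dt = -J(x(t))^T Z` on the limit cycle: the monodromy matrix of the
#' variational equation is integrated over one period, its left eigenvector
#' to the unit Floquet multiplier anchors `Z(0)`, and a single backward pass
#' (stable, since the remaining multipliers lie inside the unit circle)
#' fills in the phase grid. `Z` is normalized so that `<Z(t), F(x(t))> =
#' 1/T` at every phase; the phase runs from 0 to 1 over one period with 0 at
#' the peak of the anchoring synaptic variable. The V-component is the phase
#' response to mean-voltage perturbations.
#'
#' @param lc an `mf_limit_cycle`.
#' @param n_grid number of phase samples returned.
#' @param mult_tol acceptance tolerance on the unit Floquet multiplier; a
#'   larger deviation signals a non-periodic (unstable or poorly converged)
#'   cycle and raises an error.
#' @return object of class `mf_imprc`: data frame `phase` plus one column
#'   per state variable, attribute `period`; normalization holds pointwise.
#' @export
adjoint_imprc <- function(lc, n_grid = 1024, mult_tol = 0.01) {
  p <- lc$p
  Tp <- lc$period
  d <- ncol(lc$states)
  orbit <- lc_interp(lc)
  # monodromy of the forward variational equation
  var_ode <- function(t, y, parms) {
    J <- mf_jacobian(orbit(t %% Tp), p)
    list(as.numeric(J %*% matrix(y, d, d)))
  }
  sol <- ode(y = as.numeric(diag(d)), times = c(0, Tp), func = var_ode,
             parms = NULL, method = "lsoda", rtol = 1e-11, atol = 1e-13)
  M <- matrix(as.numeric(sol[2, -1]), d, d)
  e <- eigen(t(M))
  i1 <- which.min(abs(e$values - 1))
  if (abs(e$values[i1] - 1) > mult_tol) {
    stop("adjoint transients do not decay: no unit Floquet multiplier ",
         "(cycle unstable or not converged)")
  }
  if (any(abs(e$values[-i1]) > 1 + mult_tol)) {
    stop("adjoint transients do not decay: unstable limit cycle")
  }
  z0 <- Re(e$vectors[, i1])
  F0 <- mf_rhs(lc$states[1, ], p)
  z0 <- z0 / (sum(z0 * F0) * Tp)
  # one stable backward pass: W(u) = Z(T - u)
  adj_ode <- function(u, w, parms) {
    J <- mf_jacobian(orbit((Tp - u) %% Tp), p)
    list(as.numeric(t(J) %*% w))
  }
  times <- seq(0, Tp, length.out = n_grid + 1)
  solb <- ode(y = z0, times = times, func = adj_ode, parms = NULL,
              method = "lsoda", rtol = 1e-10, atol = 1e-12)
  Z <- as.matrix(solb[, -1, drop = FALSE])
  phase <- (Tp - times) / Tp
  phase[1] <- 0                       # u = 0 is phase 0
  keep <- seq_len(n_grid)             # drop duplicate phase-0 endpoint
  Z <- Z[keep, , drop = FALSE]; phase <- phase[keep]
  o <- order(phase)
  Z <- Z[o, , drop = FALSE]; phase <- phase[o]
  # pointwise renormalization absorbs residual integration drift
  for (i in seq_len(nrow(Z))) {
    Fx <- mf_rhs(orbit(phase[i] * Tp), p)
    Z[i, ] <- Z[i, ] / (sum(Z[i, ] * Fx) * Tp)
  }
  out <- data.frame(phase = phase)
  nm <- mf_state_names(p)
  for (j in seq_along(nm)) out[[nm[j]]] <- Z[, j]
  structure(out, class = c("mf_imprc", "data.frame"), period = Tp)
}

#' Verify the adjoint normalization identity
#'
#' @param imprc an `mf_imprc`.
#' @param lc the limit cycle it was computed on.
#' @return maximal absolute deviation of `<Z, F> * T` from 1 over the phase
#'   grid.
#' @export
imprc_normalization_error <- function(imprc, lc) {
  orbit <- lc_interp(lc)
  Tp <- attr(imprc, "period")
  nm <- mf_state_names(lc$p)
  dev <- vapply(seq_len(nrow(imprc)), function(i) {
    x <- orbit(imprc$phase[i] * Tp)
    Fx <- mf_rhs(x, lc$p)
    z <- as.numeric(imprc[i, nm])
    abs(sum(z * Fx) * Tp - 1)
  }, 0)
  max(dev)
}

#' Finite-amplitude PRC of the reduced system
#'
#' Perturbs the mean voltage of one population with a square current pulse
#' of net deflection `dv` (height `dv * tau / dur` over `dur`) at each phase
#' of the grid, integrates until the phase offset measured from the peaks of
#' the anchoring synaptic variable has converged, and reports the shift as a
#' fraction of the period (positive = advance).
#'
#' @param lc an `mf_limit_cycle`.
#' @param dv net voltage deflection.
#' @param target `"I"` or `"E"`: which population's voltage is perturbed.
#' @param phases phase grid in `[0, 1)`.
#' @param dur pulse duration.
#' @param n_cycles cycles integrated after the pulse.
#' @param with_inhibition also return the within-network inhibition integral
#'   (time integral of `tau * s` over the run after the pulse).
#' @return object of class `fmprc` (columns `phi`, `dphi`) with attribute
#'   `period`; `phi` here equals the anchoring phase in `[0, 1)` mapped to
#'   `[-0.5, 0.5)`.
#' @export
emft_fmprc <- function(lc, dv, target = c("I", "E"),
                       phases = seq(0, 0.95, by = 0.05), dur = 0.02,
                       n_cycles = 12, with_inhibition = FALSE) {
  target <- match.arg(target)
  p <- lc$p
  Tp <- lc$period
  sidx <- mf_s_index(p)
  tau_t <- if (target == "I") p$tau_i else p$tau_e
  amp <- dv * tau_t / dur
  t_tot <- (n_cycles + 2) * Tp
  dt <- Tp / 400
  # unperturbed reference peaks
  run_u <- mf_integrate(p, lc$states[1, ], seq(0, t_tot, by = dt))
  s_u <- run_u[, 1 + sidx[1]] - run_u[, 1 + sidx[2]]
  pk_u <- peak_times(run_u[, "time"], s_u)
  out <- data.frame(phi = wrap_phase(phases), dphi = NA_real_)
  inh <- rep(NA_real_, length(phases))
  for (j in seq_along(phases)) {
    tp <- phases[j] * Tp
    # segment 1: to pulse onset
    seg1 <- if (tp > 0) {
      mf_integrate(p, lc$states[1, ], c(0, tp))
    } else rbind(c(time = 0, lc$states[1, ]), c(time = 0, lc$states[1, ]))
    y <- seg1[nrow(seg1), -1]
    # segment 2: pulse window with fine fixed steps
    Iext <- if (p$family == "PING") {
      v <- c(I = 0, E = 0); v[target] <- amp; v
    } else amp
    seg2 <- mf_integrate(p, y, seq(0, dur, length.out = 21), I_ext = Iext,
                         rtol = 1e-10, atol = 1e-12)
    y <- seg2[nrow(seg2), -1]
    # segment 3: relaxation
    seg3 <- mf_integrate(p, y, seq(0, t_tot - tp - dur, by = dt))
    tt3 <- seg3[, "time"] + tp + dur
    s_p <- seg3[, 1 + sidx[1]] - seg3[, 1 + sidx[2]]
    pk_p <- peak_times(tt3, s_p)
    # asymptotic shift from late peaks
    late_u <- pk_u[pk_u > tp + 3 * Tp]
    if (length(late_u) < 3 || length(pk_p) < 3) next
    sh <- vapply(tail(late_u, 4), function(tu) {
      wrap_phase((tu - pk_p[which.min(abs(pk_p - tu))]) / Tp)
    }, 0)
    if (max(abs(diff(sh))) > 0.01) next   # not converged / ejected
    out$dphi[j] <- mean(tail(sh, 2))
    if (with_inhibition) {
      keep <- tt3 <= tp + dur + 2 * Tp
      inh[j] <- sum(s_p[keep]) * dt
    }
  }
  if (with_inhibition) out$inh_integral <- inh
  structure(out, class = c("fmprc", "data.frame"), period = Tp,
            pulse = list(dv = dv, target = target, dur = dur),
            meta = list(family = p$family))
}

#' Dynamical-regime and maximal-paradoxical-response maps
#'
#' Classifies each parameter-grid point of the mean-field system as
#' oscillatory, stationary (the Hopf side) or divergent, and, for
#' oscillatory points, records the maximal paradoxical component of the
#' imPRC (and optionally of finite-amplitude PRCs for each perturbation
#' scenario).
#'
#' @param grid data frame of parameter overrides; column names must match
#'   [mf_params()] arguments (e.g. `delta_i`, or `delta_e` and `delta_i`).
#' @param base an [mf_params()] supplying fixed parameters.
#' @param scenarios optional finite perturbations: data frame with columns
#'   `dv`, `target`; NULL computes the imPRC paradox only.
#' @param phases phase grid for the finite-amplitude PRCs.
#' @return data frame: the grid, `label`, `period`, `max_paradox_imprc`
#'   (largest magnitude of the negative lobe of the imPRC V-component) and,
#'   per scenario, `paradox_<target>_<sign>` columns.
#' @export
regime_and_response_maps <- function(grid, base, scenarios = NULL,
                                     phases = seq(0, 0.95, by = 0.05)) {
  out <- grid
  out$label <- NA_character_
  out$period <- NA_real_
  out$max_paradox_imprc <- NA_real_
  scen_cols <- character(0)
  if (!is.null(scenarios)) {
    scen_cols <- paste0("paradox_", scenarios$target,
                        ifelse(scenarios$dv > 0, "_exc", "_inh"))
    for (cc in scen_cols) out[[cc]] <- NA_real_
  }
  for (i in seq_len(nrow(grid))) {
    p <- base
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][i]
    lc <- tryCatch(find_limit_cycle(p), error = function(e) e)
    if (inherits(lc, "error")) {
      msg <- conditionMessage(lc)
      out$label[i] <- if (grepl("divergent", msg)) "divergent"
        else "stationary"
      next
    }
    out$label[i] <- "oscillatory"
    out$period[i] <- lc$period
    im <- adjoint_imprc(lc)
    vcol <- if (p$family == "ING") "V" else "VI"
    out$max_paradox_imprc[i] <- max(0, -min(im[[vcol]]))
    if (!is.null(scenarios)) {
      for (k in seq_len(nrow(scenarios))) {
        fp <- emft_fmprc(lc, scenarios$dv[k],
                         target = scenarios$target[k], phases = phases)
        # paradoxical component: response opposite in sign to the direct
        # effect of the perturbation (delay for excitation, advance for
        # inhibition)
        par_val <- if (scenarios$dv[k] > 0) max(0, -min(fp$dphi, na.rm = TRUE))
          else max(0, max(fp$dphi, na.rm = TRUE))
        out[[scen_cols[k]]][i] <- par_val
      }
    }
  }
  out
}

#' fmPRC of a spiking QIF network
#'
#' Finite-amplitude macroscopic PRC of the QIF spiking network measured, as
#' for the reduced system, from the peaks of the shared synaptic variable
#' (volley onsets are undefined under Lorentzian drives because some neurons
#' spike incessantly). A voltage pulse of net deflection `dv` is delivered
#' to the target population at each phase relative to the reference s-peak.
#'
#' @param net a QIF `network_spec`.
#' @param dv net voltage deflection.
#' @param phases phase grid in `[0, 1)`.
#' @param target perturbed population name (default: the external route).
#' @param settle_cycles cycles before the reference peak.
#' @param n_cycles readout cycles after the pulse.
#' @param dt integration step.
#' @param block synaptic block whose `s` anchors the phase (default: the
#'   first block, `I->I` for ING).
#' @return an `fmprc` (columns `phi`, `dphi`) with attribute `period`.
#' @export
qif_fmprc <- function(net, dv, phases = seq(0, 0.875, by = 0.125),
                      target = NULL, settle_cycles = 10, n_cycles = 12,
                      dt = 0.002, block = 1L) {
  stopifnot(net$family == "QIF")
  target <- target %||% net$ext$target
  period_guess <- 10
  t_end <- (settle_cycles + n_cycles + 4) * period_guess
  un <- simulate_network(net, t_end, dt = dt, record_spikes = FALSE)
  s_u <- un$syn[, block]
  pk_u <- peak_times(un$time, s_u)
  pk_u <- pk_u[pk_u > 3 * period_guess]
  if (length(pk_u) < settle_cycles + n_cycles) stop("network is not rhythmic")
  Tp <- mean(diff(pk_u))
  t_ref <- pk_u[settle_cycles]
  out <- data.frame(phi = wrap_phase(phases), dphi = NA_real_)
  for (j in seq_along(phases)) {
    tp <- t_ref + phases[j] * Tp
    pr <- simulate_network(net, t_end, dt = dt, record_spikes = FALSE,
                           pulses = list(voltage_pulse(tp, dv, pop = target)))
    pk_p <- peak_times(pr$time, pr$syn[, block])
    # persistent shift: average across readout cycles to suppress the
    # finite-size jitter of the volley times
    late_u <- pk_u[pk_u > tp + 3 * Tp & pk_u < min(t_end - Tp,
                                                   tp + (n_cycles + 0.5) * Tp)]
    if (length(late_u) < 3 || length(pk_p) < 3) next
    sh <- vapply(late_u, function(tu) {
      wrap_phase((tu - pk_p[which.min(abs(pk_p - tu))]) / Tp)
    }, 0)
    out$dphi[j] <- mean(sh)
  }
  structure(out, class = c("fmprc", "data.frame"), period = Tp,
            pulse = list(dv = dv, target = target),
            meta = net$meta)
}
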