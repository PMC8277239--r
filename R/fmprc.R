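# Finite-amplitude macroscopic phase-response curve (fmPRC).
#
# The collective phase shift is measured by comparing volley times of a
# perturbed and an unperturbed run that share the identical trajectory up to
# the perturbation time (deterministic fixed-step integration guarantees
# bit-identical state before the pulse). Phases and shifts are fractions of
# the period, wrapped into [-0.5, 0.5); positive shift = advance.

fill_pulse_time <- function(template, t_inh) {
  if (inherits(template, "square_pulse")) {
    template$t_on <- t_inh
  } else if (inherits(template, "conductance_pulse")) {
    template$t_arrival <- t_inh
  } else if (inherits(template, "voltage_pulse")) {
    template$t_on <- t_inh
  } else stop("unsupported pulse template")
  template
}

rhythm_pop <- function(net) net$ext$target %||% names(net$populations)[1]

#' Measure the finite-amplitude macroscopic PRC
#'
#' For each phase on the grid a single pulse is delivered at
#' `t_inh = t_ref + phi * T`, where `t_ref` is the first-spike time of the
#' volley reached after `settle_cycles` cycles and `T` the unperturbed
#' period. The shift of the m-th volley after the perturbation is
#' `dphi_m = (t_m^(unpert) - t_m^(pert)) / T`, with volley correspondence by
#' nearest-in-time and wrapping into `[-0.5, 0.5)`. The reported `dphi` is
#' the persistent (converged) shift, by default read out at cycle
#' `report_m = 5` once consecutive cycles agree within `conv_tol`; the
#' first-cycle shift is kept alongside.
#'
#' @param net a `network_spec` (or, with `realizations > 1`, see
#'   `net_builder`).
#' @param pulse pulse template ([square_pulse()], [conductance_pulse()] or
#'   [voltage_pulse()]) whose time field is filled per phase.
#' @param n_phases number of equally spaced phases in `[-0.5, 0.5)`.
#' @param phases optional explicit phase grid (overrides `n_phases`).
#' @param settle_cycles cycles simulated before the reference volley.
#' @param readout number of post-perturbation cycles evaluated.
#' @param conv_tol convergence tolerance on consecutive `dphi_m`.
#' @param report_m default readout cycle for the persistent shift.
#' @param realizations number of bias realizations averaged (PING).
#' @param net_builder function `k -> network_spec` giving realization `k`;
#'   defaults to a constant `net`.
#' @param period_hint initial guess of the period (ms).
#' @param refine_jumps optional jump tolerance (phase units): grid intervals
#'   whose mod-1 response jump exceeds it are bisected recursively, so steep
#'   continuous stretches get resolved and only true discontinuities remain
#'   at the minimum spacing. Applies when `realizations = 1`.
#' @param refine_min_step smallest phase spacing during refinement.
#' @return object of class `fmprc`: data frame with columns `phi`, `dphi`,
#'   `dphi_first`, `converged`, `n_valid`, plus attributes `period` (ms),
#'   `pulse`, `meta`.
#' @export
measure_fmprc <- function(net, pulse, n_phases = 64, phases = NULL,
                          settle_cycles = 15, readout = 8, conv_tol = 0.002,
                          report_m = 5, realizations = 1,
                          net_builder = NULL, period_hint = 25,
                          refine_jumps = NULL, refine_min_step = 1 / 1024) {
  phases <- phases %||% ((seq_len(n_phases) - 1) / n_phases - 0.5)
  net_builder <- net_builder %||% function(k) net
  if (realizations == 1) {
    one <- fmprc_one(net, pulse, phases, settle_cycles, readout, conv_tol,
                     report_m, period_hint, refine_tol = refine_jumps,
                     refine_min_step = refine_min_step)
    out <- one$tab
    out$n_valid <- as.integer(!is.na(out$dphi))
    return(structure(out, class = c("fmprc", "data.frame"),
                     period = one$period, pulse = pulse, meta = net$meta,
                     settle_cycles = settle_cycles, report_m = report_m))
  }
  acc <- matrix(0, length(phases), 2)  # sums of dphi, dphi_first
  nval <- integer(length(phases))
  conv_all <- rep(TRUE, length(phases))
  T_mean <- 0

  for (k in seq_len(realizations)) {
    nk <- net_builder(k)
    one <- fmprc_one(nk, pulse, phases, settle_cycles, readout, conv_tol,
                     report_m, period_hint)
    ok <- !is.na(one$tab$dphi)
    acc[ok, 1] <- acc[ok, 1] + one$tab$dphi[ok]
    acc[ok, 2] <- acc[ok, 2] + one$tab$dphi_first[ok]
    nval <- nval + ok
    conv_all <- conv_all & one$tab$converged
    T_mean <- T_mean + one$period
  }
  out <- data.frame(phi = phases,
                    dphi = ifelse(nval > 0, acc[, 1] / nval, NA_real_),
                    dphi_first = ifelse(nval > 0, acc[, 2] / nval, NA_real_),
                    converged = conv_all, n_valid = nval)
  structure(out, class = c("fmprc", "data.frame"),
            period = T_mean / realizations, pulse = pulse,
            meta = net$meta, settle_cycles = settle_cycles,
            report_m = report_m)
}

fmprc_session <- function(net, pulse, settle_cycles, readout, period_hint) {
  pop <- rhythm_pop(net)
  t_end <- (settle_cycles + readout + 6) * period_hint
  un <- simulate_network(net, t_end)
  vu <- detect_volleys(pop_spikes(un, pop), period_hint)
  if (nrow(vu) < settle_cycles + readout + 2) {
    # period longer than the hint suggested; extend once
    t_end <- t_end * 2
    un <- simulate_network(net, t_end)
    vu <- detect_volleys(pop_spikes(un, pop), period_hint)
  }
  if (nrow(vu) < settle_cycles + readout + 2) stop("network is not rhythmic")
  ref <- settle_cycles
  steady <- vu$t_first[max(2, ref - 5):nrow(vu)]
  list(net = net, pulse = pulse, pop = pop, t_end = t_end, vu = vu,
       ref = ref, T_ = mean(diff(steady)), t_ref = vu$t_first[ref],
       readout = readout)
}

fmprc_eval <- function(sess, phases, conv_tol, report_m) {
  tab <- data.frame(phi = phases, dphi = NA_real_, dphi_first = NA_real_,
                    converged = FALSE)
  for (j in seq_along(phases)) {
    t_inh <- sess$t_ref + phases[j] * sess$T_
    pr <- simulate_network(sess$net, sess$t_end,
                           pulses = list(fill_pulse_time(sess$pulse, t_inh)))
    vp <- detect_volleys(pop_spikes(pr, sess$pop), sess$T_)
    dm <- rep(NA_real_, sess$readout)
    for (m in seq_len(sess$readout)) {
      if (sess$ref + m > nrow(sess$vu)) break
      t_u <- sess$vu$t_first[sess$ref + m]
      if (nrow(vp) == 0) break
      i_near <- which.min(abs(vp$t_first - t_u))
      if (abs(vp$t_first[i_near] - t_u) > 1.5 * sess$T_) next  # rhythm lost
      dm[m] <- wrap_phase((t_u - vp$t_first[i_near]) / sess$T_)
    }
    tab$dphi_first[j] <- dm[1]
    m_use <- NA_integer_
    for (m in seq(min(report_m, sess$readout), sess$readout)) {
      if (!is.na(dm[m]) && !is.na(dm[m - 1]) &&
          abs(dm[m] - dm[m - 1]) < conv_tol) { m_use <- m; break }
    }
    if (!is.na(m_use)) {
      tab$dphi[j] <- dm[m_use]
      tab$converged[j] <- TRUE
    } else {
      last <- max(which(!is.na(dm)), -Inf)
      if (is.finite(last)) tab$dphi[j] <- dm[last]
    }
  }
  tab
}

fmprc_one <- function(net, pulse, phases, settle_cycles, readout, conv_tol,
                      report_m, period_hint, refine_tol = NULL,
                      refine_min_step = 1 / 1024) {
  sess <- fmprc_session(net, pulse, settle_cycles, readout, period_hint)
  tab <- fmprc_eval(sess, phases, conv_tol, report_m)
  if (!is.null(refine_tol)) {
    # bisect intervals whose mod-1 jump exceeds the tolerance: a steep but
    # continuous stretch resolves under refinement, a true discontinuity
    # persists down to the minimum step
    for (pass in 1:12) {
      o <- order(tab$phi)
      tab <- tab[o, ]
      phis <- c(tab$phi, tab$phi[1] + 1)
      vals <- c(tab$dphi, tab$dphi[1])
      jump <- abs(wrap_phase(diff(vals)))
      gap <- diff(phis)
      need <- which(!is.na(jump) & jump > refine_tol &
                      gap > refine_min_step * 1.5)
      if (!length(need)) break
      new_phi <- wrap_phase((phis[need] + phis[need + 1]) / 2)
      new_phi <- setdiff(round(new_phi, 10), round(tab$phi, 10))
      if (!length(new_phi)) break
      tab <- rbind(tab, fmprc_eval(sess, new_phi, conv_tol, report_m))
    }
    tab <- tab[order(tab$phi), ]
    rownames(tab) <- NULL
  }
  list(tab = tab, period = sess$T_)
}

#' Maximal paradoxical advance of an fmPRC
#'
#' @param prc an `fmprc`.
#' @return list with `max` (largest persistent shift), `phase` (its phase),
#'   `paradoxical` (TRUE when the maximum is positive for an inhibitory probe
#'   -- i.e. when `max > 0`), and `max_ms` (the shift in milliseconds).
#' @export
max_advance <- function(prc) {
  ok <- !is.na(prc$dphi)
  if (!any(ok)) stop("fmPRC has no valid entries")
  i <- which.max(prc$dphi)
  list(max = prc$dphi[i], phase = prc$phi[i],
       paradoxical = prc$dphi[i] > 0,
       max_ms = prc$dphi[i] * attr(prc, "period"))
}

#' Sweep fmPRC summaries over a parameter grid
#'
#' Runs [measure_fmprc()] for each row of `points`, optionally recalibrating
#' the mean input to hold the natural frequency fixed.
#'
#' @param points data frame of grid points; columns are passed to `net_for`
#'   and `pulse_for`.
#' @param net_for function `(I, point) -> network_spec`.
#' @param pulse_for function `point -> pulse template`.
#' @param mode `"fixed_f"` recalibrates the mean input per point to
#'   `target_f`; `"fixed_I"` uses `I_fixed` throughout.
#' @param target_f frequency target for `"fixed_f"` mode (Hz).
#' @param I_fixed mean input for `"fixed_I"` mode (pA).
#' @param cal_tol calibration tolerance (Hz).
#' @param bracket calibration current bracket (pA).
#' @param ... passed to [measure_fmprc()].
#' @return list with `summary` (data frame: the grid plus `I`, `f`, `period`,
#'   `max_dphi`, `max_dphi_ms`, `argmax_phi`, `flagged`) and `prcs` (list of
#'   `fmprc` objects, NULL where flagged).
#' @export
fmprc_sweep <- function(points, net_for, pulse_for,
                        mode = c("fixed_f", "fixed_I"),
                        target_f = 40, I_fixed = NULL, cal_tol = 0.2,
                        bracket = c(8, 40), ...) {
  mode <- match.arg(mode)
  prcs <- vector("list", nrow(points))
  res <- points
  res$I <- NA_real_; res$f <- NA_real_; res$period <- NA_real_
  res$max_dphi <- NA_real_; res$max_dphi_ms <- NA_real_
  res$argmax_phi <- NA_real_; res$flagged <- FALSE
  for (r in seq_len(nrow(points))) {
    pt <- points[r, , drop = FALSE]
    out <- tryCatch({
      if (mode == "fixed_f") {
        cal <- calibrate_mean_input(function(I) net_for(I, pt), target_f,
                                    tol = cal_tol, bracket = bracket)
        I <- cal$I; f <- cal$f; net <- cal$net
      } else {
        I <- I_fixed; net <- net_for(I, pt)
        f <- natural_frequency(net)
      }
      prc <- measure_fmprc(net, pulse_for(pt),
                           period_hint = 1000 / f, ...)
      list(I = I, f = f, prc = prc)
    }, error = function(e) NULL)
    if (is.null(out)) { res$flagged[r] <- TRUE; next }
    ma <- max_advance(out$prc)
    res$I[r] <- out$I; res$f[r] <- out$f
    res$period[r] <- attr(out$prc, "period")
    res$max_dphi[r] <- ma$max; res$max_dphi_ms[r] <- ma$max_ms
    res$argmax_phi[r] <- ma$phase
    prcs[[r]] <- out$prc
  }
  list(summary = res, prcs = prcs)
}

#' Microscopic PRC of a single IF neuron
#'
#' Phase shift of the next spike of a periodically firing, uncoupled leaky IF
#' neuron in response to a brief current pulse, as a function of the pulse
#' phase. For inhibitory pulses all shifts are delays (<= 0): the
#' single-neuron PRC is type I.
#'
#' @param net a single-population `network_spec` with `n = 1` and zero
#'   coupling (e.g. `ing_network(n = 1, W = 0, cv = 0)`).
#' @param pulse a [square_pulse()] template.
#' @param phases phase grid in `[0, 1)`.
#' @return data frame `phi`, `dphi` (fraction of the intrinsic period;
#'   positive = advance).
#' @export
single_neuron_prc <- function(net, pulse, phases = seq(0, 0.95, by = 0.05)) {
  pop <- rhythm_pop(net)
  un <- simulate_network(net, 120)
  sp <- pop_spikes(un, pop)
  if (nrow(sp) < 4) stop("neuron does not fire periodically under bias alone")
  T_ <- mean(diff(sp$t))
  ref <- max(3, ceiling(30 / T_))
  t_ref <- sp$t[ref]
  out <- data.frame(phi = phases, dphi = NA_real_)
  for (j in seq_along(phases)) {
    t_on <- t_ref + phases[j] * T_
    pr <- simulate_network(net, t_ref + 4 * T_,
                           pulses = list(fill_pulse_time(pulse, t_on)))
    spt <- pop_spikes(pr, pop)$t
    nxt_u <- sp$t[sp$t > t_on][1]
    nxt_p <- spt[spt > t_on][1]
    if (!is.na(nxt_u) && !is.na(nxt_p)) out$dphi[j] <- (nxt_u - nxt_p) / T_
  }
  out
}

#' Mechanism probe for a paradoxical phase
#'
#' Compares the perturbed and unperturbed run at one phase: number of spikes
#' in the perturbed cycle versus the unperturbed cycle, and the mean
#' within-network inhibitory current magnitude over the interval following
#' the pulse. A paradoxical advance comes with fewer spikes and weaker
#' within-network inhibition.
#'
#' @param net an ING `network_spec`.
#' @param pulse pulse template.
#' @param phi perturbation phase.
#' @param settle_cycles,period_hint as in [measure_fmprc()].
#' @return list with `spikes_unpert`, `spikes_pert` (volley spike counts),
#'   `inh_unpert`, `inh_pert` (peak within-network synaptic activation over
#'   one period after the pulse -- lower peak = weaker inhibition), and
#'   `dphi_first`.
#' @export
fmprc_mechanism <- function(net, pulse, phi, settle_cycles = 15,
                            period_hint = 25) {
  pop <- rhythm_pop(net)
  t_end <- (settle_cycles + 8) * period_hint
  un <- simulate_network(net, t_end)
  vu <- detect_volleys(pop_spikes(un, pop), period_hint)
  T_ <- mean(diff(vu$t_first[2:nrow(vu)]))
  ref <- settle_cycles
  t_ref <- vu$t_first[ref]
  t_inh <- t_ref + phi * T_
  pr <- simulate_network(net, t_end, pulses = list(fill_pulse_time(pulse, t_inh)))
  vp <- detect_volleys(pop_spikes(pr, pop), T_)
  i_u <- which.min(abs(vu$t_first - t_ref))
  i_p <- which.min(abs(vp$t_first - t_ref))
  win <- c(t_inh, t_inh + T_)
  peak_inh <- function(sim) {
    keep <- sim$time >= win[1] & sim$time <= win[2]
    max(sim$syn[keep, 1])
  }
  t_u_next <- vu$t_first[i_u + 1]
  t_p_next <- vp$t_first[which.min(abs(vp$t_first - t_u_next))]
  list(spikes_unpert = vu$count[i_u], spikes_pert = vp$count[i_p],
       inh_unpert = peak_inh(un), inh_pert = peak_inh(pr),
       dphi_first = wrap_phase((t_u_next - t_p_next) / T_))
}
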