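# Clock-forced simulations and synchronization phase diagrams.

#' Run a clock-forced network simulation
#'
#' Drives the network's external route (I-cells for ING, E-cells for PING)
#' with a strictly periodic train of double-exponential conductance pulses.
#'
#' @param net a `network_spec`.
#' @param f_clock clock frequency (Hz).
#' @param W_ext per-synapse weight of each clock pulse.
#' @param t_end run length (ms).
#' @param t_first first clock onset (ms).
#' @param n_source number of synchronized neurons in the clock network; by
#'   default the clock mirrors the forced network (size of its external
#'   route population), so each volley delivers `n_source * W_ext`.
#' @return list with `sim` (a `sim_result`), `onsets` (clock onset times),
#'   `f_clock`, `tau_d` (delay of the external synapse).
#' @export
simulate_entrained <- function(net, f_clock, W_ext, t_end = 4000,
                               t_first = 0, n_source = NULL) {
  n_source <- n_source %||% net$populations[[rhythm_pop(net)]]$n
  train <- clock_train(1000 / f_clock, t_end, t_first)
  sim <- simulate_network(net, t_end,
                          forcing = clock_forcing(train, W_ext, n_source))
  list(sim = sim, onsets = train$onsets, f_clock = f_clock,
       tau_d = net$ext$tau_d %||% 0)
}

#' Network phase relative to the clock, cycle by cycle
#'
#' For each clock cycle n the phase is
#' `Phi(n) = (t_clock(n) + tau_d - t_first(n)) / T`, where `t_first(n)` is
#' the first spike of the network volley in that cycle and the delay tau_d
#' accounts for the arrival of the clock-generated inhibition. Cycles in
#' which the network emits no volley are marked silent and set to the
#' sentinel value 2.
#'
#' @param sim a `sim_result` of a forced run.
#' @param onsets clock onset times (ms).
#' @param tau_d external synaptic delay (ms).
#' @param T_norm normalization period (ms); the clock period by default.
#' @param pop rhythm population; the network's external route by default.
#' @param transient discard clock cycles before this time (ms).
#' @return data frame `n`, `t_clock`, `Phi` (wrapped into `[0, 1)`, silent =
#'   2), `silent`.
#' @export
relative_phase_series <- function(sim, onsets, tau_d, T_norm = NULL,
                                  pop = NULL, transient = 500) {
  pop <- pop %||% rhythm_pop(sim$net)
  T_clock <- median(diff(onsets))
  T_norm <- T_norm %||% T_clock
  v <- detect_volleys(pop_spikes(sim, pop), T_clock, t_min = transient / 2)
  onsets <- onsets[onsets >= transient]
  arr <- onsets + tau_d
  out <- data.frame(n = seq_along(arr), t_clock = onsets, Phi = 2,
                    silent = TRUE)
  for (i in seq_along(arr)) {
    # volley starting within this clock cycle (arrival to arrival)
    hi <- arr[i] + T_clock
    cand <- v$t_first[v$t_first >= arr[i] & v$t_first < hi]
    if (length(cand)) {
      out$Phi[i] <- wrap_unit((arr[i] - cand[1]) / T_norm)
      out$silent[i] <- FALSE
    }
  }
  out
}

phase_variance <- function(Phi) {
  # variance of wrapped phases about their circular mean
  if (!length(Phi)) return(NA_real_)
  z <- mean(exp(2i * pi * Phi))
  mu <- Arg(z) / (2 * pi)
  var(wrap_phase(Phi - mu))
}

#' Classify the synchronization type of a forced run
#'
#' Types follow the dominant-frequency / subharmonic criteria: type 1 when
#' the dominant LFP frequency differs from the clock frequency (not
#' synchronized); type 2 when they agree but a subharmonic peak (power at
#' least `floor_frac` of the clock-frequency power) remains; type 3 when
#' they agree with no subharmonic response (1:1 phase synchronization).
#'
#' @param sim a `sim_result` of a forced run.
#' @param f_clock clock frequency (Hz).
#' @param onsets clock onsets (ms).
#' @param tau_d external delay (ms).
#' @param pop rhythm population.
#' @param transient spectral transient removal (ms).
#' @param floor_frac subharmonic prominence floor relative to the power at
#'   the clock frequency.
#' @return a one-row data frame: `f_dom`, `f_clock`, `f_sub`, `f_super`,
#'   `pr_sub`, `pr_super` (power ratios capped at 1), `var_phase`,
#'   `silent_fraction`, `sync_type`.
#' @export
classify_sync <- function(sim, f_clock, onsets, tau_d, pop = NULL,
                          transient = 500, floor_frac = 0.02) {
  pop <- pop %||% rhythm_pop(sim$net)
  sp <- lfp_spectrum(sim$time, sim$lfp[, pop], transient = transient,
                     floor_frac = 1e-4)
  ph <- relative_phase_series(sim, onsets, tau_d, pop = pop,
                              transient = transient)
  silent_fraction <- mean(ph$silent)
  vph <- phase_variance(ph$Phi[!ph$silent])
  if (sp$flat) {
    return(data.frame(f_dom = NA_real_, f_clock = f_clock, f_sub = NA_real_,
                      f_super = NA_real_, pr_sub = NA_real_,
                      pr_super = NA_real_, var_phase = vph,
                      silent_fraction = silent_fraction, sync_type = 1L))
  }
  bin <- sp$df
  p_clock <- max(sp$power[abs(sp$freq - f_clock) <= bin])
  pk <- sp$peaks
  sub <- pk[pk$freq < f_clock - 1.5 * bin, ]
  sup <- pk[pk$freq > f_clock + 1.5 * bin, ]
  f_sub <- if (nrow(sub)) sub$freq[1] else NA_real_
  pr_sub <- if (nrow(sub)) min(1, sub$power[1] / p_clock) else 0
  f_super <- if (nrow(sup)) sup$freq[1] else NA_real_
  pr_super <- if (nrow(sup)) min(1, sup$power[1] / p_clock) else 0
  dom_is_clock <- abs(sp$f_dom - f_clock) <= 1.5 * bin
  sync_type <- if (!dom_is_clock) 1L
    else if (pr_sub >= floor_frac) 2L else 3L
  data.frame(f_dom = sp$f_dom, f_clock = f_clock, f_sub = f_sub,
             f_super = f_super, pr_sub = pr_sub, pr_super = pr_super,
             var_phase = vph, silent_fraction = silent_fraction,
             sync_type = sync_type)
}

#' Synchronization phase diagram over heterogeneity and detuning
#'
#' For each heterogeneity level the mean input is calibrated to the target
#' natural frequency; the network is then forced at `f_clock = target_f +
#' df` for every detuning on the grid and the synchronization summary is
#' recorded.
#'
#' @param cv_grid heterogeneity grid.
#' @param df_grid detuning grid (Hz).
#' @param net_for function `(I, cv) -> network_spec`.
#' @param target_f natural frequency to hold fixed (Hz).
#' @param W_ext per-synapse clock pulse weight.
#' @param n_source clock network size (default: the forced population size).
#' @param t_end run length per point (ms).
#' @param cal_tol calibration tolerance (Hz).
#' @param bracket calibration bracket (pA).
#' @param transient analysis transient (ms).
#' @return data frame with one row per (cv, df): calibrated `I`, achieved
#'   `f_nat`, and the [classify_sync()] summary columns; failed points are
#'   flagged with `flagged = TRUE`.
#' @export
phase_diagram <- function(cv_grid, df_grid, net_for, target_f = 44,
                          W_ext = 6e-2, n_source = NULL, t_end = 4000,
                          cal_tol = 0.2, bracket = c(8, 40),
                          transient = 500) {
  rows <- list()
  for (cv in cv_grid) {
    cal <- tryCatch(
      calibrate_mean_input(function(I) net_for(I, cv), target_f,
                           tol = cal_tol, bracket = bracket),
      error = function(e) NULL)
    for (df_ in df_grid) {
      base <- data.frame(cv = cv, df = df_, I = NA_real_, f_nat = NA_real_,
                         flagged = TRUE, f_dom = NA_real_,
                         f_clock = target_f + df_, f_sub = NA_real_,
                         f_super = NA_real_, pr_sub = NA_real_,
                         pr_super = NA_real_, var_phase = NA_real_,
                         silent_fraction = NA_real_, sync_type = NA_integer_)
      if (!is.null(cal)) {
        ent <- simulate_entrained(cal$net, target_f + df_, W_ext, t_end,
                                  n_source = n_source)
        cls <- classify_sync(ent$sim, ent$f_clock, ent$onsets, ent$tau_d,
                             transient = transient)
        base <- cbind(data.frame(cv = cv, df = df_, I = cal$I,
                                 f_nat = cal$f, flagged = FALSE), cls)
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
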