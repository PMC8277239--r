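# Front end to the compiled network integrators.

#' Square current pulse descriptor
#'
#' Brief square-wave current delivered identically to every neuron of a
#' population through the external conductance, e.g. the 0.1 ms pulses used
#' to probe the macroscopic phase response. For IF networks the amplitude is
#' a current (pA) converted through the external conductance of the target
#' population; the resulting rapid deflection is approximately
#' `amplitude * duration / (g * tau)`.
#'
#' @param t_on pulse onset (ms).
#' @param amplitude current amplitude (pA); negative values depolarize if the
#'   drive convention is inhibitory. Sign convention: the amplitude enters
#'   the voltage equation as `+I/g`, so inhibitory pulses have `amplitude < 0`.
#' @param duration pulse duration (ms, > 0).
#' @param pop target population name; defaults to the network's external
#'   input route.
#' @return object of class `square_pulse`.
#' @export
square_pulse <- function(t_on, amplitude, duration = 0.1, pop = NULL) {
  stopifnot(duration > 0)
  structure(list(t_on = t_on, amplitude = amplitude, duration = duration,
                 pop = pop), class = "square_pulse")
}

#' Double-exponential conductance pulse descriptor
#'
#' A single synaptic-like transient with the kinetics of the network's
#' external synapse: both exponentials jump by `W` at `t_arrival`. The time
#' stamp refers to the arrival (conductance jump), i.e. the synaptic delay of
#' the emitting source is considered already elapsed.
#'
#' @param t_arrival time of the conductance jump (ms).
#' @param W dimensionless per-synapse weight of the transient.
#' @param n_source number of synchronized source neurons the pulse stands in
#'   for: the delivered jump is `n_source * W` (a clock network of N
#'   synchronous cells, connected all-to-all, delivers N pulses at once).
#' @param pop target population name; defaults to the external route.
#' @return object of class `conductance_pulse`.
#' @export
conductance_pulse <- function(t_arrival, W, n_source = 1, pop = NULL) {
  structure(list(t_arrival = t_arrival, W = W * n_source, pop = pop),
            class = "conductance_pulse")
}

#' Voltage perturbation for QIF populations
#'
#' Net mean-voltage deflection `dv` delivered as a square current pulse of
#' height `dv * tau / duration` over `duration` time units.
#'
#' @param t_on onset time.
#' @param dv net voltage deflection (model units).
#' @param duration pulse duration (default 0.02).
#' @param pop target population name.
#' @return object of class `voltage_pulse`.
#' @export
voltage_pulse <- function(t_on, dv, duration = 0.02, pop = NULL) {
  stopifnot(duration > 0)
  structure(list(t_on = t_on, dv = dv, duration = duration, pop = pop),
            class = "voltage_pulse")
}

#' Clock forcing descriptor
#'
#' Attaches a periodic conductance-pulse train to the network's external
#' input route: every onset of `train` produces, after the external synapse's
#' delay, a double-exponential transient of weight `W_ext`.
#'
#' @param train a [clock_train()].
#' @param W_ext dimensionless per-synapse weight of each clock pulse.
#' @param n_source number of synchronized neurons in the clock network; the
#'   delivered per-volley jump is `n_source * W_ext`.
#' @return object of class `clock_forcing`.
#' @export
clock_forcing <- function(train, W_ext, n_source = 1) {
  stopifnot(inherits(train, "clock_train"))
  structure(list(train = train, W_ext = W_ext * n_source),
            class = "clock_forcing")
}

pop_index <- function(net, name) {
  i <- match(name, names(net$populations))
  if (is.na(i)) stop("unknown population: ", name)
  i
}

#' Simulate a spiking network
#'
#' Integrates an IF or QIF `network_spec` with fixed step `dt`, recording the
#' per-population mean voltage (LFP), the shared synaptic states, and the
#' spike raster. IF voltages use an exponential-Euler update with exact
#' exponential decay of the synaptic states between spike events; threshold
#' crossings are located by linear interpolation within the step and the
#' delayed synaptic jumps are scheduled at the interpolated time plus the
#' block delay.
#'
#' @param net a `network_spec`.
#' @param t_end simulation end (ms; model units for QIF).
#' @param dt integration step (default 0.01 ms for IF, 0.002 for QIF).
#' @param record_dt recording interval (default 0.05 ms for IF, 0.05 for QIF).
#' @param pulses list of [square_pulse()], [conductance_pulse()] or
#'   [voltage_pulse()] descriptors.
#' @param forcing optional [clock_forcing()].
#' @param record_spikes keep the raster (disable for long sweeps).
#' @param v0 optional named list of initial-voltage vectors per population.
#' @return object of class `sim_result` with elements `time`, `lfp`, `syn`
#'   (and `rate` for QIF), `spikes` (data frame `id`, `t`), `spike_count`,
#'   `pops`, `dt`, `t_end`, `net`.
#' @export
simulate_network <- function(net, t_end, dt = NULL, record_dt = NULL,
                             pulses = list(), forcing = NULL,
                             record_spikes = TRUE, v0 = NULL) {
  stopifnot(inherits(net, "network_spec"))
  qif <- net$family == "QIF"
  dt <- dt %||% if (qif) 0.002 else 0.01
  record_dt <- record_dt %||% 0.05
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  if (inherits(pulses, c("square_pulse", "conductance_pulse", "voltage_pulse")))
    pulses <- list(pulses)

  pops <- lapply(net$populations, function(p) {
    init <- v0[[p$name]] %||% p$v0
    if (qif) {
      list(n = p$n, tau = p$tau, v_peak = p$v_peak, v_reset = p$v_reset,
           eta = p$eta, v0 = init)
    } else {
      list(n = p$n, tau = p$tau, v_rest = p$v_rest, v_peak = p$v_peak,
           v_reset = p$v_reset, u_bias = p$bias / p$g_bias, v0 = init)
    }
  })

  blocks <- lapply(net$connections, function(b) {
    if (qif) {
      list(src = pop_index(net, b$src), tgt = pop_index(net, b$tgt),
           jump = b$J / (net$populations[[b$src]]$n * (b$tau2 - b$tau1)),
           tau1 = b$tau1, tau2 = b$tau2, tau_d = b$tau_d, sign = b$sign,
           s1 = 0, s2 = 0)
    } else {
      list(src = pop_index(net, b$src), tgt = pop_index(net, b$tgt),
           W = b$W, tau1 = b$tau1, tau2 = b$tau2, tau_d = b$tau_d,
           v_rev = b$v_rev, A1 = 0, A2 = 0)
    }
  })
  block_names <- vapply(net$connections, function(b)
    paste0(b$src, "->", b$tgt), "")

  sq <- list(pop = numeric(0), t_on = numeric(0), dur = numeric(0),
             u = numeric(0))
  add_ext_block <- function(tgt_name, jump_times, jump_w) {
    e <- net$ext
    if (qif) {
      b <- net$connections[[1]]
      blocks[[length(blocks) + 1L]] <<- list(
        src = 0L, tgt = pop_index(net, tgt_name), jump = 0,
        tau1 = b$tau1, tau2 = b$tau2, tau_d = 0, sign = -1,
        s1 = 0, s2 = 0, jump_times = jump_times, jump_w = jump_w)
    } else {
      blocks[[length(blocks) + 1L]] <<- list(
        src = 0L, tgt = pop_index(net, tgt_name), W = 0,
        tau1 = e$tau1, tau2 = e$tau2, tau_d = e$tau_d, v_rev = e$v_rev,
        A1 = 0, A2 = 0, jump_times = jump_times, jump_w = jump_w)
    }
    block_names <<- c(block_names, paste0("ext->", tgt_name))
  }

  for (p in pulses) {
    tgt <- p$pop %||% net$ext$target
    pi_ <- pop_index(net, tgt)
    if (inherits(p, "square_pulse")) {
      u <- if (qif) p$amplitude else p$amplitude / net$ext$g
      sq$pop <- c(sq$pop, pi_); sq$t_on <- c(sq$t_on, p$t_on)
      sq$dur <- c(sq$dur, p$duration); sq$u <- c(sq$u, u)
    } else if (inherits(p, "voltage_pulse")) {
      if (!qif) stop("voltage_pulse applies to QIF networks")
      amp <- p$dv * net$populations[[tgt]]$tau / p$duration
      sq$pop <- c(sq$pop, pi_); sq$t_on <- c(sq$t_on, p$t_on)
      sq$dur <- c(sq$dur, p$duration); sq$u <- c(sq$u, amp)
    } else if (inherits(p, "conductance_pulse")) {
      add_ext_block(tgt, p$t_arrival, p$W)
    } else stop("unknown pulse descriptor")
  }

  if (!is.null(forcing)) {
    stopifnot(inherits(forcing, "clock_forcing"))
    tgt <- net$ext$target
    arrive <- forcing$train$onsets + (net$ext$tau_d %||% 0)
    add_ext_block(tgt, arrive, forcing$W_ext)
  }

  pulses_cpp <- if (length(sq$pop)) {
    if (qif) list(pop = sq$pop, t_on = sq$t_on, dur = sq$dur, amp = sq$u)
    else list(pop = sq$pop, t_on = sq$t_on, dur = sq$dur, u = sq$u)
  } else list()

  raw <- if (qif) {
    sim_qif_cpp(unname(pops), blocks, pulses_cpp, t_end, dt, record_every,
                record_spikes)
  } else {
    sim_if_cpp(unname(pops), blocks, pulses_cpp, t_end, dt, record_every,
               record_spikes)
  }

  lfp <- raw$lfp; colnames(lfp) <- names(net$populations)
  syn <- raw$syn; colnames(syn) <- block_names
  sizes <- vapply(net$populations, function(p) as.integer(p$n), 0L)
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offsets) <- names(sizes)

  out <- list(time = raw$time, lfp = lfp, syn = syn,
              spikes = data.frame(id = raw$spike_id, t = raw$spike_t),
              spike_count = raw$spike_count,
              pops = data.frame(name = names(sizes), n = as.integer(sizes),
                                offset = as.integer(offsets)),
              dt = dt, record_dt = record_dt, t_end = t_end, net = net,
              v_final = raw$v_final)
  if (qif) out$rate <- {
    r <- raw$rate; colnames(r) <- names(net$populations); r
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %s, t_end=%g, dt=%g, %d spikes>\n",
              x$net$family, x$t_end, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Spikes of one population
#'
#' @param sim a `sim_result`.
#' @param pop population name.
#' @return data frame with columns `id` (1-based within the population) and
#'   `t` (ms), sorted by time.
#' @export
pop_spikes <- function(sim, pop) {
  i <- match(pop, sim$pops$name)
  if (is.na(i)) stop("unknown population: ", pop)
  lo <- sim$pops$offset[i]
  s <- sim$spikes[sim$spikes$id > lo & sim$spikes$id <= lo + sim$pops$n[i], ]
  s$id <- s$id - lo
  s[order(s$t), ]
}

#' Mean synaptic current of a block
#'
#' Reconstructs the population-mean synaptic current of an IF block from the
#' recorded shared synaptic state and the target LFP:
#' `g * tau/(tau2-tau1) * s(t) * (v_rev - mean V(t))`.
#'
#' @param sim a `sim_result` from an IF network.
#' @param block block label (e.g. `"I->I"`); defaults to the first block.
#' @return data frame `time`, `current` (pA).
#' @export
syn_current <- function(sim, block = NULL) {
  block <- block %||% colnames(sim$syn)[1]
  bi <- match(block, colnames(sim$syn))
  if (is.na(bi)) stop("unknown block: ", block)
  b <- sim$net$connections[[bi]]
  tgt <- sim$net$populations[[b$tgt]]
  q <- b$g * tgt$tau / (b$tau2 - b$tau1)
  data.frame(time = sim$time,
             current = q * sim$syn[, bi] * (b$v_rev - sim$lfp[, b$tgt]))
}
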