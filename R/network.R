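# Network specifications for the all-to-all IF and QIF networks.
#
# Conductances enter the IF voltage equation only through ratios I/g, so each
# population stores bias drives in current units together with its bias
# conductance; the simulator works with u = I/g (mV). Synaptic blocks are
# all-to-all with one shared weight ("all synapses of the same type were
# equally strong"), which licenses the shared filtered-spike-train state.

#' IF population descriptor
#'
#' @param name population label ("I", "E", ...).
#' @param n number of neurons.
#' @param tau membrane time constant (ms).
#' @param v_rest,v_peak,v_reset resting, threshold and reset potentials (mV).
#' @param bias vector (length `n`) of tonic bias currents (pA).
#' @param g_bias bias conductance (nS).
#' @param v0 initial voltage(s) (mV); recycled over the population.
#' @return list of class `if_population`.
#' @export
if_population <- function(name, n, tau, v_rest, v_peak, v_reset,
                          bias, g_bias, v0 = v_rest) {
  stopifnot(tau > 0, v_reset < v_peak, length(bias) == n)
  structure(list(name = name, n = n, tau = tau, v_rest = v_rest,
                 v_peak = v_peak, v_reset = v_reset, bias = bias,
                 g_bias = g_bias, v0 = v0),
            class = "if_population")
}

#' Synaptic connection block (all-to-all)
#'
#' Delayed double-exponential conductance synapse from every neuron of `src`
#' onto every neuron of `tgt`. The synaptic current onto neuron i is
#' `g * tau_tgt/(tau2-tau1) * (A2-A1) * (v_rev - V_i)`, where each presynaptic
#' spike adds `W` to both exponentials `A1, A2` after the delay `tau_d`.
#'
#' @param src,tgt population names.
#' @param W dimensionless synaptic weight (>= 0).
#' @param g synaptic conductance (nS); bookkeeping only, it cancels in the
#'   voltage equation.
#' @param tau1,tau2 rise/decay time constants (ms), `tau2 > tau1 > 0`.
#' @param tau_d synaptic delay (ms, >= 0).
#' @param v_rev reversal potential (mV).
#' @return list of class `synapse_block`.
#' @export
synapse_block <- function(src, tgt, W, g, tau1, tau2, tau_d, v_rev) {
  stopifnot(tau2 > tau1, tau1 > 0, tau_d >= 0, W >= 0)
  structure(list(src = src, tgt = tgt, W = W, g = g, tau1 = tau1,
                 tau2 = tau2, tau_d = tau_d, v_rev = v_rev),
            class = "synapse_block")
}

#' Assemble a network specification
#'
#' @param populations list of [if_population()] (or QIF populations).
#' @param connections list of [synapse_block()].
#' @param family `"IF"` or `"QIF"`.
#' @param ext description of the external-input synapse (target population,
#'   conductance, kinetics, delay, reversal potential) used by clock forcing
#'   and conductance pulses.
#' @param meta named list of free-form metadata.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(populations, connections, family = c("IF", "QIF"),
                         ext = NULL, meta = list()) {
  family <- match.arg(family)
  names(populations) <- vapply(populations, `[[`, "", "name")
  structure(list(populations = populations, connections = connections,
                 family = family, ext = ext, meta = meta),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec: %s, %d population(s), %d block(s)>\n",
              x$family, length(x$populations), length(x$connections)))
  for (p in x$populations) {
    cat(sprintf("  %s: n=%d tau=%g\n", p$name, p$n, p$tau))
  }
  invisible(x)
}

# Fixed IF-model constants (membrane and synaptic parameters of the reference
# parameter set; see the methods vignette).
.if_const <- list(
  ing = list(tau = 20, v_rest = -55, v_peak = -50, v_reset = -60,
             tau_d = 3, n = 500, W = 3e-2, W_ext = 6e-2,
             g_bias = 0.3, g_syn = 4, g_ext = 4,
             tau1_i = 0.5, tau2_i = 5, v_rev_i = -70),
  ping = list(tau_e = 20, tau_i = 10, v_rest = -70, v_peak = -52,
              v_reset = -59, tau_d = 1, n_e = 800, n_i = 200,
              W_i = 4.5e-3, W_e = 1.5e-3, W_ext = 3e-4,
              g_ext = 0.19, g_bias_e = 0.19, g_bias_i = 0.3,
              g_ei = 0.3, g_ie = 2.5,
              tau1_e = 0.5, tau2_e = 2, v_rev_e = 0,
              tau1_i = 0.5, tau2_i = 5, v_rev_i = -70)
)

#' ING network of leaky IF neurons
#'
#' All-to-all inhibitory network with delayed double-exponential synapses and
#' Gaussian-quantile heterogeneous bias currents. Defaults are the reference
#' ING parameter set (tau = 20 ms, thresholds -50/-60 mV around rest -55 mV,
#' I-I weight 3e-2 through 4 nS, rise/decay 0.5/5 ms, delay 3 ms, bias
#' conductance 0.3 nS).
#'
#' @param mean_current mean bias current (pA).
#' @param cv coefficient of variation of the bias heterogeneity.
#' @param n number of I-cells.
#' @param W within-network synaptic weight.
#' @param tau_d synaptic delay (ms).
#' @param tau1,tau2 inhibitory synapse rise/decay constants (ms).
#' @param bias optional explicit bias vector (pA); overrides the quantile
#'   construction.
#' @param v0 initial voltages (mV).
#' @return a `network_spec`.
#' @export
ing_network <- function(mean_current = 20.4, cv = 0.15, n = 500,
                        W = 3e-2, tau_d = 3,
                        tau1 = 0.5, tau2 = 5,
                        bias = NULL, v0 = NULL) {
  k <- .if_const$ing
  if (is.null(bias)) bias <- gaussian_bias_quantiles(mean_current, cv, n)
  pop <- if_population("I", n, k$tau, k$v_rest, k$v_peak, k$v_reset,
                       bias, k$g_bias, v0 %||% k$v_rest)
  blk <- synapse_block("I", "I", W, k$g_syn, tau1, tau2, tau_d, k$v_rev_i)
  ext <- list(target = "I", g = k$g_ext, tau1 = tau1, tau2 = tau2,
              tau_d = tau_d, v_rev = k$v_rev_i)
  network_spec(list(pop), list(blk), "IF", ext,
               meta = list(kind = "ING", mean_current = mean_current, cv = cv))
}

#' PING network of leaky IF neurons
#'
#' Excitatory-inhibitory network with all-to-all E-I and I-E connections only
#' (no E-E, no I-I). E-cells receive deterministic Gaussian-quantile bias
#' currents; I-cells receive a random subthreshold Gaussian drive (without
#' E input they stay below threshold).
#'
#' @param mean_e mean E-cell bias current (pA); set by frequency calibration
#'   in the analyses.
#' @param cv_e coefficient of variation of the E-cell bias.
#' @param mean_i,cv_i mean (pA) and CV of the I-cell subthreshold drive.
#' @param n_e,n_i population sizes.
#' @param i_seed seed for the random I-cell bias realization.
#' @param tau_d synaptic delay (ms).
#' @param W_e,W_i E-to-I and I-to-E synaptic weights.
#' @param bias_e,bias_i optional explicit bias vectors.
#' @return a `network_spec`.
#' @export
ping_network <- function(mean_e = 5, cv_e = 0.1,
                         mean_i = 3.6, cv_i = 0.167,
                         n_e = 800, n_i = 200, i_seed = 1L,
                         tau_d = 1, W_e = 1.5e-3, W_i = 4.5e-3,
                         bias_e = NULL, bias_i = NULL) {
  k <- .if_const$ping
  if (is.null(bias_e)) bias_e <- gaussian_bias_quantiles(mean_e, cv_e, n_e)
  if (is.null(bias_i)) bias_i <- gaussian_bias_sample(mean_i, cv_i, n_i, i_seed)
  pe <- if_population("E", n_e, k$tau_e, k$v_rest, k$v_peak, k$v_reset,
                      bias_e, k$g_bias_e)
  pi_ <- if_population("I", n_i, k$tau_i, k$v_rest, k$v_peak, k$v_reset,
                       bias_i, k$g_bias_i)
  b_ei <- synapse_block("E", "I", W_e, k$g_ei, k$tau1_e, k$tau2_e,
                        tau_d, k$v_rev_e)
  b_ie <- synapse_block("I", "E", W_i, k$g_ie, k$tau1_i, k$tau2_i,
                        tau_d, k$v_rev_i)
  ext <- list(target = "E", g = k$g_ext, tau1 = k$tau1_e, tau2 = k$tau2_e,
              tau_d = tau_d, v_rev = k$v_rev_e)
  network_spec(list(pe, pi_), list(b_ei, b_ie), "IF", ext,
               meta = list(kind = "PING", mean_e = mean_e, cv_e = cv_e,
                           mean_i = mean_i, cv_i = cv_i, i_seed = i_seed))
}

#' QIF population descriptor
#'
#' @param name label.
#' @param n number of neurons.
#' @param tau membrane time constant (model time units).
#' @param eta vector of tonic drives (length `n`).
#' @param v_peak,v_reset finite truncation values for the spiking simulation.
#' @param v0 initial voltage(s).
#' @return list of class `qif_population`.
#' @export
qif_population <- function(name, n, tau, eta, v_peak = 500, v_reset = -500,
                           v0 = 0) {
  stopifnot(tau > 0, v_reset < 0, v_peak > 0, length(eta) == n)
  structure(list(name = name, n = n, tau = tau, eta = eta,
                 v_peak = v_peak, v_reset = v_reset, v0 = v0),
            class = "qif_population")
}

#' Rate-driven synapse block for QIF networks
#'
#' Double-exponential synaptic filter driven by the population rate: each
#' presynaptic spike increments both filter states by `J/N_src`; the synaptic
#' current onto the target is `sign * tau_tgt * (s2 - s1)`.
#'
#' @param src,tgt population names.
#' @param J synaptic strength.
#' @param sign `+1` excitatory, `-1` inhibitory.
#' @param tau1,tau2 rise/decay constants, `tau2 > tau1 > 0`.
#' @param tau_d delay (0 in the reference model).
#' @return list of class `qif_block`.
#' @export
qif_block <- function(src, tgt, J, sign, tau1 = 0.98, tau2 = 1, tau_d = 0) {
  stopifnot(tau2 > tau1, tau1 > 0, sign %in% c(-1, 1))
  structure(list(src = src, tgt = tgt, J = J, sign = sign,
                 tau1 = tau1, tau2 = tau2, tau_d = tau_d),
            class = "qif_block")
}

#' QIF ING network with Lorentzian-quantile drives
#'
#' @param eta_bar center of the Lorentzian drive distribution.
#' @param delta half-width of the distribution.
#' @param n number of I-cells.
#' @param J inhibitory coupling strength.
#' @param tau membrane time constant.
#' @param tau1,tau2 synaptic rise/decay constants.
#' @param eta optional explicit drive vector.
#' @return a `network_spec` with `family = "QIF"`.
#' @export
qif_ing_network <- function(eta_bar = 20, delta = 3, n = 5000, J = 15,
                            tau = 10, tau1 = 0.98, tau2 = 1, eta = NULL) {
  if (is.null(eta)) eta <- lorentzian_bias_quantiles(eta_bar, delta, n)
  pop <- qif_population("I", n, tau, eta)
  blk <- qif_block("I", "I", J, sign = -1, tau1 = tau1, tau2 = tau2)
  network_spec(list(pop), list(blk), "QIF",
               ext = list(target = "I"),
               meta = list(kind = "ING", eta_bar = eta_bar, delta = delta,
                           J = J))
}

#' QIF PING network with Lorentzian-quantile drives
#'
#' E and I populations coupled through all-to-all E-I (excitatory) and I-E
#' (inhibitory) rate-driven double-exponential synapses.
#'
#' @param eta_bar_e,eta_bar_i centers of the E/I drive distributions.
#' @param delta_e,delta_i half-widths of the E/I drive distributions.
#' @param n_e,n_i population sizes.
#' @param J_ei inhibitory strength (I onto E).
#' @param J_ie excitatory strength (E onto I).
#' @param tau_e,tau_i membrane time constants.
#' @param tau1,tau2 synaptic rise/decay constants.
#' @return a `network_spec` with `family = "QIF"`.
#' @export
qif_ping_network <- function(eta_bar_e = 5, eta_bar_i = -5,
                             delta_e = 1, delta_i = 1,
                             n_e = 5000, n_i = 5000,
                             J_ei = 15, J_ie = 15,
                             tau_e = 10, tau_i = 10,
                             tau1 = 0.98, tau2 = 1) {
  pe <- qif_population("E", n_e, tau_e,
                       lorentzian_bias_quantiles(eta_bar_e, delta_e, n_e))
  pi_ <- qif_population("I", n_i, tau_i,
                        lorentzian_bias_quantiles(eta_bar_i, delta_i, n_i))
  b_ie <- qif_block("E", "I", J_ie, sign = +1, tau1 = tau1, tau2 = tau2)
  b_ei <- qif_block("I", "E", J_ei, sign = -1, tau1 = tau1, tau2 = tau2)
  network_spec(list(pe, pi_), list(b_ie, b_ei), "QIF",
               ext = list(target = "E"),
               meta = list(kind = "PING", eta_bar_e = eta_bar_e,
                           eta_bar_i = eta_bar_i, delta_e = delta_e,
                           delta_i = delta_i))
}
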