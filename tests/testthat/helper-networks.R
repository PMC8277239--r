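# Small fixture networks built in code; reference-scale networks are only
# used where a check is about the reference configuration itself.

# W scales as 500/n so the per-volley inhibition (and hence the collective
# dynamics) matches the reference 500-neuron network
tiny_ing <- function(cv = 0.15, n = 100, mean_current = 20.4,
                     W = 3e-2 * 500 / n, ...) {
  ing_network(mean_current, cv, n, W = W, ...)
}

single_if_neuron <- function(mean_current = 20.4) {
  ing_network(mean_current, cv = 0, n = 1, W = 0)
}

# closed-form interspike interval of an uncoupled leaky IF neuron
if_isi_theory <- function(I, g_bias = 0.3, tau = 20, v_rest = -55,
                          v_peak = -50, v_reset = -60) {
  vinf <- v_rest + I / g_bias
  tau * log((vinf - v_reset) / (vinf - v_peak))
}

# synthetic smooth fmPRC for map-level tests
sine_prc <- function(a, period = 25, n = 64) {
  phi <- (seq_len(n) - 1) / n - 0.5
  structure(data.frame(phi = phi, dphi = a * sin(2 * pi * phi),
                       dphi_first = a * sin(2 * pi * phi),
                       converged = TRUE, n_valid = 1L),
            class = c("fmprc", "data.frame"), period = period)
}
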