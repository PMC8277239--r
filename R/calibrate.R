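# Calibration of the mean tonic drive to hit a target rhythm frequency.

#' Measure the natural frequency of a network
#'
#' Simulates the unperturbed network and returns the rhythm frequency from
#' the mean inter-volley interval of the rhythm-defining population (I for
#' ING, E for PING).
#'
#' @param net a `network_spec`.
#' @param t_sim simulation length (ms).
#' @param transient discarded initial span (ms).
#' @param period_hint volley-grouping hint (ms).
#' @return frequency (Hz).
#' @export
natural_frequency <- function(net, t_sim = 1500, transient = 400,
                              period_hint = 25) {
  pop <- net$ext$target %||% names(net$populations)[1]
  sim <- simulate_network(net, t_sim)
  v <- detect_volleys(pop_spikes(sim, pop), period_hint, t_min = transient)
  if (nrow(v) < 3) stop("network is not rhythmic")
  volley_frequency(v)
}

#' Calibrate the mean input to a target frequency
#'
#' Finds, by bisection on the monotone increasing frequency-vs-drive
#' relation, the mean bias current for which the network rhythm attains a
#' target natural frequency.
#'
#' @param make_net function mapping a mean current (pA) to a `network_spec`
#'   (all other parameters, including the heterogeneity CV, held fixed).
#' @param target_f target frequency (Hz).
#' @param tol frequency tolerance (Hz).
#' @param bracket initial current bracket `c(lo, hi)` (pA); expanded a
#'   bounded number of times if it does not straddle the target.
#' @param t_sim,transient simulation span passed to [natural_frequency()].
#' @param max_iter bisection iteration cap.
#' @return list with `I` (calibrated mean current), `f` (achieved frequency),
#'   `net` (the calibrated network).
#' @export
calibrate_mean_input <- function(make_net, target_f, tol = 0.1,
                                 bracket = c(8, 40), t_sim = 1500,
                                 transient = 400, max_iter = 30) {
  period_hint <- 1000 / target_f
  f_of <- function(I) {
    net <- make_net(I)
    tryCatch(natural_frequency(net, t_sim, transient, period_hint),
             error = function(e) NA_real_)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f_of(lo); f_hi <- f_of(hi)
  expand <- 0
  while ((is.na(f_lo) || f_lo > target_f) && expand < 6) {
    hi <- lo; f_hi <- f_lo
    lo <- lo * 0.6; f_lo <- f_of(lo); expand <- expand + 1
  }
  while ((is.na(f_hi) || f_hi < target_f) && expand < 12) {
    hi <- hi * 1.5; f_hi <- f_of(hi); expand <- expand + 1
  }
  if (is.na(f_lo) || is.na(f_hi) || f_lo > target_f || f_hi < target_f) {
    stop("could not bracket the target frequency")
  }
  I <- NA_real_; f <- NA_real_
  for (k in seq_len(max_iter)) {
    I <- 0.5 * (lo + hi)
    f <- f_of(I)
    if (is.na(f)) stop("network lost rhythmicity during bisection")
    if (abs(f - target_f) <= tol) break
    if (f < target_f) lo <- I else hi <- I
  }
  if (abs(f - target_f) > tol) {
    stop(sprintf("calibration did not converge: f=%.2f target=%.2f", f,
                 target_f))
  }
  list(I = I, f = f, net = make_net(I))
}
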