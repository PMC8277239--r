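# Generators for the heterogeneous tonic drive and the periodic "clock" input.
# All inputs of the analysis are synthetic: deterministic quantile vectors
# (Gaussian for IF networks, Lorentzian for QIF networks), random Gaussian
# realizations for the PING I-cells, and periodic pulse-onset trains.

#' Deterministic Gaussian-quantile bias currents
#'
#' Places the `n` bias currents at the equally spaced rank quantiles
#' `i/(n+1)` of a Gaussian with mean `mean_current` and coefficient of
#' variation `cv`:
#' \deqn{I_i = I (1 + \sqrt{2}\, CV\, \mathrm{erf}^{-1}(-1 + 2i/(1+n)))}
#' which is the Gaussian quantile function written through the inverse error
#' function. The vector is ascending and exactly symmetric about the mean.
#'
#' @param mean_current mean bias current (pA), must be positive.
#' @param cv coefficient of variation of the heterogeneity (dimensionless,
#'   >= 0). `cv = 0` gives a homogeneous vector.
#' @param n number of neurons.
#' @return ascending numeric vector of length `n` (pA).
#' @export
gaussian_bias_quantiles <- function(mean_current, cv, n) {
  stopifnot(n >= 1, cv >= 0, mean_current > 0)
  i <- seq_len(n)
  # sqrt(2) * erfinv(-1 + 2p) == qnorm(p)
  out <- mean_current * (1 + cv * qnorm(i / (1 + n)))
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("negative bias current: cv too large for the given mean")
  }
  out
}

#' Deterministic Lorentzian-quantile drives
#'
#' Places `n` drives at the quantiles of a Lorentzian (Cauchy) distribution
#' with center `center` and half-width at half-maximum `half_width`:
#' \deqn{\eta_i = \bar\eta + \Delta \tan(\pi(i/(1+n) - 1/2))}
#'
#' @param center distribution center (dimensionless drive).
#' @param half_width half-width `Delta` (> 0).
#' @param n number of neurons.
#' @return strictly ascending numeric vector of length `n`.
#' @export
lorentzian_bias_quantiles <- function(center, half_width, n) {
  stopifnot(n >= 1, half_width > 0)
  i <- seq_len(n)
  center + half_width * tan(pi * (i / (1 + n) - 0.5))
}

#' Random Gaussian bias-current realization
#'
#' I.i.d. Gaussian draws used for the subthreshold drive of PING I-cells.
#' Negative draws (possible at large `cv`) are rejected and redrawn, since
#' negative tonic excitation lies outside the model regime.
#'
#' @param mean_current mean (pA).
#' @param cv coefficient of variation (>= 0).
#' @param n number of draws (> 0).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return numeric vector of length `n` (pA), unsorted.
#' @export
gaussian_bias_sample <- function(mean_current, cv, n, seed) {
  if (n <= 0) stop("n must be positive")
  stopifnot(cv >= 0)
  out <- withr_seed(seed, {
    x <- rnorm(n, mean_current, cv * mean_current)
    guard <- 0L
    while (any(x < 0) && guard < 1000L) {
      bad <- x < 0
      x[bad] <- rnorm(sum(bad), mean_current, cv * mean_current)
      guard <- guard + 1L
    }
    x
  })
  if (any(out < 0)) stop("negative bias current: rejection failed")
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Periodic clock pulse train
#'
#' Onset times of a strictly periodic forcing train, emulating the perfectly
#' synchronous spike volleys of a homogeneous "clock" network. Each onset
#' triggers, after the synaptic delay of the external synapse, a
#' double-exponential conductance transient identical to a within-network
#' synaptic event of weight `W_ext`.
#'
#' @param period clock period (ms, > 0).
#' @param t_end end of the train (ms, > period).
#' @param t_first time of the first onset (ms).
#' @param duration optional square-pulse duration for square trains; must be
#'   smaller than `period`.
#' @return object of class `clock_train` with the onset times.
#' @export
clock_train <- function(period, t_end, t_first = 0, duration = NULL) {
  stopifnot(period > 0, t_end > period)
  if (!is.null(duration) && duration >= period) {
    stop("overlapping pulses: duration must be smaller than the period")
  }
  onsets <- seq(t_first, t_end, by = period)
  structure(list(onsets = onsets, period = period, t_end = t_end),
            class = "clock_train")
}

#' Evaluate a double-exponential conductance waveform
#'
#' Sum of normalized double-exponential transients, one per event time, used
#' to compare a synthesized clock train against the output of a simulated
#' homogeneous clock network.
#'
#' @param t times at which to evaluate (ms).
#' @param events event (conductance-jump) times (ms).
#' @param w per-event weight.
#' @param tau1,tau2 rise and decay time constants (ms), `tau2 > tau1`.
#' @return numeric vector: `w * sum_k (exp(-(t-t_k)/tau2) - exp(-(t-t_k)/tau1))`.
#' @export
double_exp_waveform <- function(t, events, w, tau1, tau2) {
  out <- numeric(length(t))
  for (ev in events) {
    d <- t - ev
    pos <- d >= 0
    out[pos] <- out[pos] + w * (exp(-d[pos] / tau2) - exp(-d[pos] / tau1))
  }
  out
}

#' Write a bias-current vector to CSV
#'
#' @param bias numeric vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bias_csv <- function(bias, path) {
  write.csv(data.frame(index = seq_along(bias), value = bias),
            path, row.names = FALSE)
  invisible(path)
}
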