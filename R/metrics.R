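# Rhythm descriptors: spike volleys, spectra, phase dispersion.

#' Group a raster into spike volleys
#'
#' Spikes are grouped into volleys wherever consecutive spike times are
#' separated by more than `gap_frac` times the expected period. Neurons that
#' spike twice within a cycle contribute both spikes to the same volley.
#'
#' @param spikes data frame with columns `id`, `t` (e.g. [pop_spikes()]).
#' @param period_hint expected rhythm period (ms, > 0).
#' @param gap_frac gap threshold as a fraction of `period_hint`.
#' @param t_min discard spikes before this time (transient removal).
#' @return data frame with one row per volley: `t_first`, `t_last`, `count`
#'   (number of spikes), `n_neurons` (distinct neurons), `max_mult` (largest
#'   per-neuron spike multiplicity within the volley). Empty raster gives a
#'   zero-row frame.
#' @export
detect_volleys <- function(spikes, period_hint, gap_frac = 0.5, t_min = 0) {
  if (period_hint <= 0) stop("period_hint must be positive")
  s <- spikes[spikes$t >= t_min, ]
  s <- s[order(s$t), ]
  empty <- data.frame(t_first = numeric(0), t_last = numeric(0),
                      count = integer(0), n_neurons = integer(0),
                      max_mult = integer(0))
  if (nrow(s) == 0) return(empty)
  brk <- c(0, cumsum(diff(s$t) > gap_frac * period_hint))
  out <- do.call(rbind, lapply(split(seq_len(nrow(s)), brk), function(ix) {
    tt <- s$t[ix]
    tab <- tabulate(factor(s$id[ix]))
    data.frame(t_first = tt[1], t_last = tt[length(tt)],
               count = length(ix), n_neurons = length(unique(s$id[ix])),
               max_mult = max(tab))
  }))
  rownames(out) <- NULL
  out
}

#' Natural frequency from volley timing
#'
#' Rhythm frequency as the reciprocal of the mean inter-volley interval,
#' which resolves frequency far below one spectral bin for clean rhythms.
#'
#' @param volleys output of [detect_volleys()] (needs >= 3 volleys).
#' @return frequency in Hz (times in ms).
#' @export
volley_frequency <- function(volleys) {
  if (nrow(volleys) < 3) stop("need at least 3 volleys")
  1000 / mean(diff(volleys$t_first))
}

#' Periodogram of an LFP trace
#'
#' Mean-subtracted single-taper periodogram after transient removal. The
#' dominant frequency is the location of the global power maximum; the peak
#' table lists local maxima above a relative prominence floor.
#'
#' @param time sample times (ms).
#' @param lfp LFP samples (same length).
#' @param transient initial span to discard (ms).
#' @param f_max upper frequency cut for the returned grid (Hz).
#' @param floor_frac keep peaks with power >= `floor_frac` times the maximum.
#' @return object of class `lfp_spectrum`: list with `freq` (Hz), `power`,
#'   `f_dom`, `peaks` (data frame `freq`, `power`), `df` (bin width), and
#'   `flat` (TRUE when the trace carries no oscillation and `f_dom` is
#'   meaningless).
#' @export
lfp_spectrum <- function(time, lfp, transient = 500, f_max = 250,
                         floor_frac = 0.01) {
  keep <- time >= transient
  x <- lfp[keep]
  n <- length(x)
  if (n < 16) stop("trace too short after transient removal")
  dt_s <- mean(diff(time[keep])) / 1000  # seconds
  x <- x - mean(x)
  if (sd(x) < 1e-12) {
    return(structure(list(freq = numeric(0), power = numeric(0),
                          f_dom = NA_real_, peaks = NULL,
                          df = 1 / (n * dt_s), flat = TRUE),
                     class = "lfp_spectrum"))
  }
  p <- Mod(fft(x))^2 / n
  freq <- (seq_len(n) - 1) / (n * dt_s)
  keep_f <- freq > 0 & freq <= f_max
  freq <- freq[keep_f]; p <- p[keep_f]
  f_dom <- freq[which.max(p)]
  loc <- which(diff(sign(diff(p))) == -2) + 1L
  loc <- loc[p[loc] >= floor_frac * max(p)]
  peaks <- data.frame(freq = freq[loc], power = p[loc])
  peaks <- peaks[order(-peaks$power), ]
  structure(list(freq = freq, power = p, f_dom = f_dom, peaks = peaks,
                 df = 1 / (n * dt_s), flat = FALSE),
            class = "lfp_spectrum")
}

#' @export
print.lfp_spectrum <- function(x, ...) {
  cat(sprintf("<lfp_spectrum: f_dom=%.2f Hz, bin=%.3f Hz>\n",
              x$f_dom, x$df))
  invisible(x)
}

#' Phase dispersion of the rhythm
#'
#' Mean over cycles of the volley spread `(t_last - t_first)` normalized by
#' the period. Single-spike volleys contribute zero.
#'
#' @param volleys output of [detect_volleys()] (>= 3 volleys).
#' @param period rhythm period (ms); defaults to the mean inter-volley
#'   interval.
#' @return dimensionless dispersion.
#' @export
phase_dispersion <- function(volleys, period = NULL) {
  if (nrow(volleys) < 3) stop("need at least 3 volleys")
  period <- period %||% mean(diff(volleys$t_first))
  mean((volleys$t_last - volleys$t_first) / period)
}
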