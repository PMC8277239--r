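#' Wrap phases into the fundamental interval [-0.5, 0.5)
#'
#' Phases and phase shifts are expressed as fractions of the rhythm period and
#' reported in the symmetric fundamental interval.
#'
#' @param x numeric vector of phases (period units).
#' @return `x` wrapped elementwise into `[-0.5, 0.5)`.
#' @export
wrap_phase <- function(x) {
  x - round(x)
}

#' Wrap values into [0, 1)
#' @param x numeric vector.
#' @return `x` modulo 1 in `[0, 1)`.
#' @export
wrap_unit <- function(x) {
  x - floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
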