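#' Multi-echo acquisition parameters
#'
#' Describes a CPMG-style multi-echo spin-echo acquisition with equally
#' spaced echoes: echo `k` is read at `k * echo_spacing` ms. The defaults
#' match a 32-echo GraSE protocol with TE = 10..320 ms and TR = 1000 ms.
#' `t1` is the single longitudinal relaxation time assumed by the decay
#' basis; multi-echo T2 fits over a 320 ms train are insensitive to its
#' exact value.
#'
#' @param n_echoes Number of echoes (>= 2).
#' @param echo_spacing Echo spacing in ms (> 0).
#' @param repetition_time Repetition time in ms (bookkeeping only; the echo
#'   train model does not include TR-driven recovery).
#' @param excitation_flip Excitation flip angle in degrees (ideal 90).
#' @param t1 Assumed T1 in ms for the extended-phase-graph basis.
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' echo_times(acq)[1:4]
#' @export
acq_params <- function(n_echoes = 32L, echo_spacing = 10, repetition_time = 1000,
                       excitation_flip = 90, t1 = 1000) {
  n_echoes <- as.integer(n_echoes)
  if (is.na(n_echoes) || n_echoes < 2L) {
    stop("`n_echoes` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(echo_spacing) || echo_spacing <= 0) {
    stop("`echo_spacing` must be > 0", call. = FALSE)
  }
  if (!is.numeric(t1) || t1 <= 0) stop("`t1` must be > 0", call. = FALSE)
  structure(
    list(
      n_echoes = n_echoes,
      echo_spacing = echo_spacing,
      repetition_time = repetition_time,
      excitation_flip = excitation_flip,
      t1 = t1
    ),
    class = "acq_params"
  )
}

#' @rdname acq_params
#' @param acq An `acq_params` object.
#' @export
echo_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  seq_len(acq$n_echoes) * acq$echo_spacing
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %d echoes, TE %g..%g ms (spacing %g ms), TR %g ms, assumed T1 %g ms\n",
    x$n_echoes, x$echo_spacing, x$n_echoes * x$echo_spacing,
    x$echo_spacing, x$repetition_time, x$t1
  ))
  invisible(x)
}

#' Logarithmic T2 analysis grid
#'
#' Logarithmically spaced T2 relaxation times used as the spectral grid of
#' the multi-exponential inversion. The default is 200 nodes over
#' 1 to 3000 ms.
#'
#' @param n Number of grid nodes.
#' @param t2_min,t2_max Grid range in ms.
#' @return Numeric vector of strictly increasing T2 values (ms).
#' @examples
#' grid <- t2_grid()
#' range(grid)
#' @export
t2_grid <- function(n = 200L, t2_min = 1, t2_max = 3000) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (t2_min <= 0 || t2_max <= t2_min) {
    stop("require 0 < t2_min < t2_max", call. = FALSE)
  }
  exp(seq(log(t2_min), log(t2_max), length.out = n))
}
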