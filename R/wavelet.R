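#' Analytic Morlet wavelet
#'
#' The mother wavelet used for the continuous wavelet transform: a Gaussian
#' bump in frequency centred at `center_frequency` cycles (so the
#' pseudo-frequency of scale \eqn{a} at sampling step \eqn{dt} is
#' \eqn{f = f_c / (a\,dt)}), with frequency spread `center_frequency /
#' n_cycles`. Negative-frequency content is zeroed, making the wavelet
#' analytic so the phase transform is well defined. `n_cycles = 6` gives
#' the familiar ~6-cycle Morlet envelope.
#'
#' @param center_frequency centre frequency \eqn{f_c} in cycles (default 1).
#' @param n_cycles approximate number of oscillation cycles under the
#'   Gaussian envelope (default 6).
#' @return object of class `wavelet_spec`.
#' @export
morlet_wavelet <- function(center_frequency = 1.0, n_cycles = 6) {
  if (center_frequency <= 0) stop("center_frequency must be positive")
  if (n_cycles <= 0) stop("n_cycles must be positive")
  sf <- center_frequency / n_cycles        # frequency-domain std (cycles)
  structure(list(family = "analytic_morlet",
                 center_frequency = center_frequency,
                 n_cycles = n_cycles,
                 sigma_f = sf,
                 sigma_t = 1 / (2 * pi * sf)),   # time-domain std (samples)
            class = "wavelet_spec")
}

# frequency response at `u` cycles/sample (analytic: zero for u <= 0)
wavelet_freq <- function(wavelet, u) {
  out <- exp(-(u - wavelet$center_frequency)^2 / (2 * wavelet$sigma_f^2))
  out[u <= 0] <- 0
  out
}

# time-domain mother wavelet at offset `t` samples (Fourier pair of
# wavelet_freq, up to the negligible truncated negative-frequency tail)
wavelet_time <- function(wavelet, t) {
  wavelet$sigma_f * sqrt(2 * pi) *
    exp(2i * pi * wavelet$center_frequency * t -
          t^2 / (2 * wavelet$sigma_t^2))
}

#' Effective half-support of the scaled wavelet, in samples
#'
#' Five time-domain standard deviations of the Gaussian envelope at scale
#' `scale`; used for reflect-padding and for flagging boundary columns.
#' @param wavelet a [morlet_wavelet()].
#' @param scale scale value(s) in samples.
#' @return integer half-support(s) in samples.
#' @export
wavelet_support <- function(wavelet, scale) {
  as.integer(ceiling(5 * wavelet$sigma_t * scale))
}
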