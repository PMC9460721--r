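#' Phase transform: local instantaneous frequency of the CWT
#'
#' \eqn{\omega_x(a,b) = \Re[\partial_b W_x(a,b) / (i 2\pi W_x(a,b))]}
#' in Hz, computed from the spectrally differentiated transform carried by
#' the [cwt()] map. Entries with \eqn{|W| \le \gamma} are masked invalid:
#' the phase is undefined where the transform (numerically) vanishes.
#'
#' @param cwt_map output of [cwt()] (must carry `dcoeffs`).
#' @param gamma magnitude threshold; default `1e-8 * max(|W|)`.
#' @return object of class `phase_map`: `omega` (Hz, `NA` where invalid)
#'   and logical `valid_mask`, same shape as the coefficients.
#' @export
phase_transform <- function(cwt_map, gamma = NULL) {
  if (is.null(cwt_map$dcoeffs))
    stop("cwt_map carries no derivative transform (use cwt(), not ",
         "cwt_direct())")
  W <- cwt_map$coeffs
  dW <- cwt_map$dcoeffs
  mag2 <- Re(W)^2 + Im(W)^2
  if (is.null(gamma)) gamma <- 1e-8 * sqrt(max(mag2))
  if (gamma < 0) stop("gamma must be >= 0")
  # Re[dW / (i 2 pi W)] = Im(dW * Conj(W)) / (2 pi |W|^2)
  omega <- suppressWarnings(Im(dW * Conj(W)) / (2 * pi * mag2))
  valid <- sqrt(mag2) > gamma & is.finite(omega)
  omega[!valid] <- NA_real_
  structure(list(omega = omega, valid_mask = valid, gamma = gamma),
            class = "phase_map")
}

#' Synchrosqueezing: reassign CWT coefficients along frequency
#'
#' Discrete realization of the reassignment
#' \eqn{T_x(\xi, b) = \sum_k W_x(a_k, b)\, \Delta a_k / a_k} over the
#' scales whose instantaneous frequency \eqn{\omega(a_k, b)} falls in the
#' bin of \eqn{\xi}. The scale grid is log-uniform, so
#' \eqn{\Delta a_k / a_k = \ln 2 / v} with `v` voices per octave.
#' Frequencies are assigned to the nearest bin centre of a linear grid
#' over `[fmin, fmax]` (ties to the lower bin); estimates outside the
#' range, and invalid entries, are discarded. Reassignment moves mass but
#' never rescales it, so column sums of `T` equal the corresponding
#' weighted sums of `W` exactly.
#'
#' @param cwt_map output of [cwt()].
#' @param phase output of [phase_transform()] for the same map.
#' @param freq_bins number of linear frequency bins (default 128).
#' @param fmin,fmax frequency range of the output grid; defaults to the
#'   scale grid's range.
#' @return object of class `swt_map`: complex `coeffs`
#'   (freq_bins x n_times), ascending `freqs` (Hz), `times`.
#' @export
synchrosqueeze <- function(cwt_map, phase, freq_bins = 128,
                           fmin = cwt_map$grid$fmin,
                           fmax = cwt_map$grid$fmax) {
  if (freq_bins < 2) stop("freq_bins must be at least 2")
  if (fmax <= fmin) stop("need fmin < fmax for the output frequency grid")
  W <- cwt_map$coeffs
  K <- nrow(W); nt <- ncol(W)
  xi <- seq(fmin, fmax, length.out = freq_bins)
  delta <- (fmax - fmin) / (freq_bins - 1)
  weight <- log(2) / cwt_map$grid$voices_per_octave

  Tm <- matrix(0 + 0i, nrow = freq_bins, ncol = nt)
  for (k in seq_len(K)) {
    om <- phase$omega[k, ]
    ok <- which(phase$valid_mask[k, ] & om >= fmin & om <= fmax)
    if (!length(ok)) next
    bin <- ceiling((om[ok] - fmin) / delta - 0.5) + 1L
    bin[bin < 1L] <- 1L
    bin[bin > freq_bins] <- freq_bins
    idx <- cbind(bin, ok)
    Tm[idx] <- Tm[idx] + W[k, ok] * weight
  }
  structure(list(coeffs = Tm, freqs = xi, times = cwt_map$times,
                 fs = cwt_map$grid$fs, weight = weight,
                 grid = cwt_map$grid),
            class = "swt_map")
}
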