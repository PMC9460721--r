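# Continuous wavelet transform on a logarithmic scale grid.
#
# The production path works in the frequency domain: one FFT of the
# (reflect-padded) signal, multiplied per scale by the conjugate scaled
# wavelet response with the a^(-1/2) normalization, inverse-transformed
# with mvfft. A direct time-domain Riemann-sum evaluation (`cwt_direct`)
# is kept as the independent oracle for the same quantity.

#' Logarithmic scale grid for the CWT
#'
#' Frequencies \eqn{f_k = fmin \cdot 2^{k/v}} for \eqn{k = 0 \dots K},
#' \eqn{K = \lfloor v \log_2(fmax/fmin) \rfloor} with `v` voices per
#' octave; scales \eqn{a_k = f_c f_s / f_k} in samples.
#'
#' @param fs sampling rate in Hz.
#' @param fmin,fmax frequency band covered, `0 < fmin <= fmax <= fs/2`.
#' @param voices_per_octave scales per frequency doubling (default 8).
#' @param wavelet a [morlet_wavelet()] supplying the centre frequency.
#' @return object of class `scale_grid` with ascending `freq_hz` and the
#'   matching descending `scale` (samples).
#' @export
make_scale_grid <- function(fs, fmin, fmax, voices_per_octave = 8,
                            wavelet = morlet_wavelet()) {
  if (fmin <= 0) stop("fmin must be positive")
  if (fmax < fmin) stop("fmax must be >= fmin")
  if (fmax > fs / 2)
    stop("fmax (", fmax, " Hz) exceeds the Nyquist frequency ", fs / 2,
         " Hz")
  K <- if (fmax == fmin) 0L
  else as.integer(floor(voices_per_octave * log2(fmax / fmin)))
  freq <- fmin * 2^((0:K) / voices_per_octave)
  structure(list(freq_hz = freq,
                 scale = wavelet$center_frequency * fs / freq,
                 voices_per_octave = voices_per_octave,
                 fmin = fmin, fmax = fmax, fs = fs),
            class = "scale_grid")
}

# reflect-pad (no edge repetition) allowing pad > length(x)
reflect_pad <- function(x, pad) {
  n <- length(x)
  if (n == 1L) return(rep(x, n + 2L * pad))
  period <- 2L * (n - 1L)
  idx <- (seq_len(n + 2L * pad) - 1L) - pad
  m <- ((idx %% period) + period) %% period
  m <- ifelse(m > n - 1L, period - m, m)
  x[m + 1L]
}

#' Continuous wavelet transform
#'
#' Computes \eqn{W_x(a, b)} on the grid's scales via the frequency-domain
#' product of the signal spectrum with the conjugate scaled wavelet
#' response (L2 normalization \eqn{a^{-1/2}}). The signal is reflect-padded
#' by the maximum wavelet support before transforming and cropped after,
#' so boundary columns are attenuated rather than wrapped. The transform
#' of the time derivative (`dcoeffs`, per second) is computed alongside
#' and drives the phase transform.
#'
#' @param signal real numeric vector, length >= 2, finite.
#' @param wavelet a [morlet_wavelet()].
#' @param grid a [make_scale_grid()] for the signal's sampling rate.
#' @return object of class `cwt_map`: complex `coeffs` and `dcoeffs`
#'   (n_scales x n_times, rows ascending in frequency), `grid`, `times`.
#' @export
cwt <- function(signal, wavelet = morlet_wavelet(),
                grid = make_scale_grid(256, 0.5, 50)) {
  if (length(signal) < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stop("signal contains NaN/Inf")
  n <- length(signal)
  fs <- grid$fs
  pad <- max(wavelet_support(wavelet, max(grid$scale)))
  xp <- reflect_pad(signal, pad)
  N <- nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, rep(0, N - length(xp)))
  X <- fft(xp)

  u <- (seq_len(N) - 1L) / N               # cycles/sample
  neg <- u > 0.5                            # upper half = negative freqs
  K <- length(grid$scale)
  H <- matrix(0 + 0i, nrow = N, ncol = K)
  for (k in seq_len(K)) {
    a <- grid$scale[k]
    h <- sqrt(a) * wavelet_freq(wavelet, a * u)
    h[neg] <- 0
    H[, k] <- X * h                         # wavelet response is real
  }
  W <- mvfft(H, inverse = TRUE) / N
  dW <- mvfft(H * (2i * pi * u * fs), inverse = TRUE) / N

  rows <- (pad + 1L):(pad + n)
  structure(list(coeffs = t(W[rows, , drop = FALSE]),
                 dcoeffs = t(dW[rows, , drop = FALSE]),
                 grid = grid, wavelet = wavelet,
                 times = (seq_len(n) - 1L) / fs),
            class = "cwt_map")
}

#' Boundary (cone-of-influence) flags for a CWT map
#'
#' `TRUE` wherever a coefficient's time index lies within the wavelet's
#' effective support ([wavelet_support()]) of either signal edge at that
#' coefficient's scale. Flagged coefficients are contaminated by the
#' reflect-padding and are retained in all production outputs, but
#' quantitative localization measurements should exclude them; at the
#' largest scales of a short signal every column may be flagged.
#'
#' @param cwt_map output of [cwt()] or [cwt_direct()].
#' @return logical matrix (n_scales x n_times), `TRUE` = boundary.
#' @export
boundary_mask <- function(cwt_map) {
  n <- ncol(cwt_map$coeffs)
  supp <- wavelet_support(cwt_map$wavelet, cwt_map$grid$scale)
  t(vapply(supp, function(L) {
    idx <- seq_len(n)
    idx <= L | idx > n - L
  }, logical(n)))
}

#' Direct Riemann-sum CWT (reference oracle)
#'
#' Evaluates the defining time-domain inner products
#' \eqn{W_x(a,b) = \sum_t x(t)\, a^{-1/2}\, \overline{\psi((t-b)/a)}}
#' by sliding truncated time-domain kernels over the same reflect-padded
#' signal as [cwt()]. Independent of the FFT path; used to validate it.
#'
#' @inheritParams cwt
#' @return object of class `cwt_map` (without `dcoeffs`).
#' @export
cwt_direct <- function(signal, wavelet = morlet_wavelet(),
                       grid = make_scale_grid(256, 0.5, 50)) {
  if (length(signal) < 2L) stop("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stop("signal contains NaN/Inf")
  n <- length(signal)
  pad <- max(wavelet_support(wavelet, max(grid$scale)))
  xp <- reflect_pad(signal, pad)
  K <- length(grid$scale)
  W <- matrix(0 + 0i, nrow = K, ncol = n)
  for (k in seq_len(K)) {
    a <- grid$scale[k]
    L <- wavelet_support(wavelet, a)
    j <- (-L):L
    kern <- Conj(wavelet_time(wavelet, j / a)) / sqrt(a)
    # y[b] = sum_j xp[b + j] * kern[j]  (correlation via stats::filter)
    f_re <- rev(Re(kern))
    f_im <- rev(Im(kern))
    y <- stats::filter(xp, f_re, method = "convolution", sides = 2) +
      1i * stats::filter(xp, f_im, method = "convolution", sides = 2)
    W[k, ] <- y[(pad + 1L):(pad + n)]
  }
  structure(list(coeffs = W, grid = grid, wavelet = wavelet,
                 times = (seq_len(n) - 1L) / grid$fs),
            class = "cwt_map")
}
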