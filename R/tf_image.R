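# Time-frequency maps -> fixed-size classifier input images.

#' Restrict an SWT map to a frequency band
#'
#' Drops rows outside `[fmin, fmax]` (inclusive). The clinically relevant
#' EEG content sits below 50 Hz, so the default keeps 0-50 Hz (the
#' effective lower edge is the transform's own `fmin`, since a log-scale
#' CWT grid cannot reach a true 0 Hz).
#'
#' @param map an `swt_map` from [synchrosqueeze()].
#' @param fmin,fmax band limits in Hz.
#' @return an `swt_map` with the retained rows.
#' @export
band_limit <- function(map, fmin = 0, fmax = 50) {
  keep <- which(map$freqs >= fmin & map$freqs <= fmax)
  if (!length(keep))
    stop("band [", fmin, ", ", fmax, "] Hz does not overlap the map grid [",
         min(map$freqs), ", ", max(map$freqs), "] Hz")
  map$coeffs <- map$coeffs[keep, , drop = FALSE]
  map$freqs <- map$freqs[keep]
  map
}

#' Magnitude of a time-frequency map
#'
#' @param map an `swt_map` (or `cwt_map`).
#' @param log1p if `TRUE`, return `log(1 + |T|)` instead of `|T|`
#'   (default `FALSE`).
#' @return real matrix of the same shape as the coefficients.
#' @export
to_magnitude <- function(map, log1p = FALSE) {
  m <- Mod(map$coeffs)
  if (log1p) m <- log1p(m)
  m
}

#' Bilinear image resize (half-pixel-center convention)
#'
#' Standard separable bilinear interpolation with source coordinates
#' `(i + 0.5) * in/out - 0.5`, clamped at the borders (the common
#' image-library default, no corner alignment). Output values are convex
#' combinations of input values, hence bounded by the input range.
#' A 1-pixel input dimension falls back to nearest-neighbour replication.
#'
#' @param mat real input matrix (H0 x W0).
#' @param out_h,out_w output size (default 128 x 128).
#' @return real `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(mat, out_h = 128, out_w = 128) {
  interp_matrix <- function(n_in, n_out) {
    # rows: output pixels; convex weights over input pixels
    A <- matrix(0, nrow = n_out, ncol = n_in)
    if (n_in == 1L) { A[, 1] <- 1; return(A) }
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- pmin(floor(src), n_in - 2)
    frac <- src - lo
    A[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    A[cbind(seq_len(n_out), lo + 2)] <- A[cbind(seq_len(n_out), lo + 2)] +
      frac
    A
  }
  Ar <- interp_matrix(nrow(mat), out_h)
  Ac <- interp_matrix(ncol(mat), out_w)
  Ar %*% mat %*% t(Ac)
}

#' Build the classifier input image for one segment
#'
#' Per channel: synchrosqueezed (or plain CWT) time-frequency transform,
#' band limiting, magnitude, bilinear resize to `out_h x out_w`, then
#' per-channel min-max normalization to `[0, 1]` (a constant channel maps
#' to all zeros). Channels are stacked in the segment's (= montage) order.
#'
#' @param segment a `labeled_segment` from [extract_segments()].
#' @param fs sampling rate of the segment's record in Hz.
#' @param wavelet a [morlet_wavelet()].
#' @param grid a [make_scale_grid()]; defaults to 0.5-50 Hz at `fs`.
#' @param freq_bins linear frequency bins of the squeezed map (128).
#' @param transform `"swt"` (default) or `"cwt"` (no reassignment; the
#'   log-frequency rows are used directly as image rows).
#' @param out_h,out_w image size (128 x 128).
#' @param fmax_band upper band limit in Hz (50).
#' @param log_magnitude passed to [to_magnitude()].
#' @param normalize `"channel"` (default) min-max per channel, `"global"`
#'   min-max over the whole tensor, or `"none"`.
#' @return object of class `tf_image`: `pixels` array
#'   (out_h x out_w x n_channels) in `[0,1]`, plus provenance meta.
#' @export
build_image <- function(segment, fs, wavelet = morlet_wavelet(),
                        grid = make_scale_grid(fs, 0.5, min(50, fs / 2),
                                               wavelet = wavelet),
                        freq_bins = 128, transform = c("swt", "cwt"),
                        out_h = 128, out_w = 128, fmax_band = 50,
                        log_magnitude = FALSE,
                        normalize = c("channel", "global", "none")) {
  transform <- match.arg(transform)
  normalize <- match.arg(normalize)
  x <- segment$data
  if (!all(is.finite(x))) stop("segment data contains NaN/Inf")
  nch <- nrow(x)
  pixels <- array(0, dim = c(out_h, out_w, nch))
  for (ch in seq_len(nch)) {
    cm <- cwt(x[ch, ], wavelet = wavelet, grid = grid)
    if (transform == "swt") {
      ph <- phase_transform(cm)
      map <- synchrosqueeze(cm, ph, freq_bins = freq_bins)
    } else {
      map <- structure(list(coeffs = cm$coeffs, freqs = grid$freq_hz,
                            times = cm$times, fs = fs, grid = grid),
                       class = "swt_map")
    }
    map <- band_limit(map, fmin = 0, fmax = fmax_band)
    mag <- to_magnitude(map, log1p = log_magnitude)
    pixels[, , ch] <- resize_bilinear(mag, out_h, out_w)
  }
  if (normalize == "channel") {
    for (ch in seq_len(nch)) {
      v <- pixels[, , ch]
      rng <- range(v)
      pixels[, , ch] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
      else 0
    }
  } else if (normalize == "global") {
    rng <- range(pixels)
    pixels <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1])
    else array(0, dim = dim(pixels))
  }
  structure(list(pixels = pixels,
                 meta = list(record_id = segment$record_id,
                             start = segment$start,
                             duration = segment$duration,
                             label = segment$label,
                             transform = transform)),
            class = "tf_image")
}
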