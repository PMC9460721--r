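# Shared fixture builders. Everything is generated in code at test time.

# a tiny classifier image with an optional bright horizontal band whose
# position encodes the class (trivially separable)
make_test_image <- function(label, seed, side = 32, channels = 2,
                            band = if (label == "preictal") 10:14 else NULL) {
  set.seed(seed)
  px <- array(runif(side * side * channels, 0, 0.3),
              dim = c(side, side, channels))
  if (!is.null(band)) px[band, , 1] <- px[band, , 1] + 0.6
  px <- pmin(px, 1)
  structure(list(pixels = px,
                 meta = list(record_id = "test", start = 0, duration = 1,
                             label = label, transform = "swt")),
            class = "tf_image")
}

make_image_set <- function(n_per_class, seed = 1, side = 32, channels = 2) {
  c(lapply(seq_len(n_per_class),
           function(i) make_test_image("preictal", seed * 1000 + i,
                                       side, channels)),
    lapply(seq_len(n_per_class),
           function(i) make_test_image("interictal", seed * 1000 + 500 + i,
                                       side, channels)))
}

# small model configuration for fast unit tests (32 x 32 inputs)
tiny_model_config <- function(...) {
  args <- list(input_shape = c(32, 32, 2), block_widths = c(2, 4, 4, 4, 4),
               projection_channels = 4, fusion_size = 8,
               fc_sizes = c(16, 8), epochs = 25, learning_rate = 2e-3,
               batch_size = 32, seed = 7)
  do.call(model_config, utils::modifyList(args, list(...)))
}

# a labeled segment holding given data
make_segment <- function(data, label = "preictal", record_id = "rec",
                         start = 0, duration = ncol(data) / 256) {
  structure(list(record_id = record_id, start = start, duration = duration,
                 label = label, data = data),
            class = "labeled_segment")
}

# independent brute-force synchrosqueezing oracle: explicit loop over
# (scale, time), nearest-bin assignment with ties to the lower bin
oracle_squeeze <- function(cwt_map, phase, freq_bins, fmin, fmax) {
  W <- cwt_map$coeffs
  xi <- seq(fmin, fmax, length.out = freq_bins)
  delta <- (fmax - fmin) / (freq_bins - 1)
  weight <- log(2) / cwt_map$grid$voices_per_octave
  Tm <- matrix(0 + 0i, nrow = freq_bins, ncol = ncol(W))
  for (k in seq_len(nrow(W))) for (b in seq_len(ncol(W))) {
    if (!phase$valid_mask[k, b]) next
    om <- phase$omega[k, b]
    if (om < fmin || om > fmax) next
    d <- abs(xi - om)
    l <- which(d == min(d))[1]              # ties -> lower bin
    Tm[l, b] <- Tm[l, b] + W[k, b] * weight
  }
  Tm
}
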