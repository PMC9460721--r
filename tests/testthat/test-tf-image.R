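# Band limiting, magnitude, bilinear resize, image assembly.

test_that("band_limit keeps exactly the rows inside the band", {
  m <- structure(list(coeffs = matrix(1 + 0i, 10, 4),
                      freqs = seq(1, 64, length.out = 10),
                      times = 1:4), class = "swt_map")
  bl <- band_limit(m, 0, 50)
  expect_true(all(bl$freqs <= 50))
  expect_equal(nrow(bl$coeffs), sum(m$freqs <= 50))
  expect_equal(band_limit(m, 1, 64)$coeffs, m$coeffs)   # identity
  expect_error(band_limit(m, 70, 80), "does not overlap")
})

test_that("to_magnitude is conjugation-invariant", {
  z <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3)
  m1 <- to_magnitude(list(coeffs = z))
  m2 <- to_magnitude(list(coeffs = Conj(z)))
  expect_equal(m1, m2)
  expect_equal(to_magnitude(list(coeffs = matrix(0 + 0i, 2, 2))),
               matrix(0, 2, 2))
  expect_equal(to_magnitude(list(coeffs = z), log1p = TRUE), log1p(m1))
})

test_that("bilinear resize matches a per-pixel closed-form oracle", {
  m <- matrix(c(0, 2, 1, 3), 2)                 # [[0,1],[2,3]]
  out <- resize_bilinear(m, 4, 4)
  # independent evaluation under the half-pixel-center convention
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    sr <- min(max((i - 0.5) * 2 / 4 - 0.5, 0), 1)
    sc <- min(max((j - 0.5) * 2 / 4 - 0.5, 0), 1)
    r0 <- min(floor(sr), 0)                    # clamp to n_in - 2
    c0 <- min(floor(sc), 0)
    fr <- sr - r0; fc <- sc - c0
    oracle[i, j] <- (1 - fr) * (1 - fc) * m[r0 + 1, c0 + 1] +
      fr * (1 - fc) * m[r0 + 2, c0 + 1] +
      (1 - fr) * fc * m[r0 + 1, c0 + 2] +
      fr * fc * m[r0 + 2, c0 + 2]
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # identity, constancy, range preservation
  set.seed(4)
  big <- matrix(runif(128 * 128), 128)
  expect_equal(resize_bilinear(big, 128, 128), big, tolerance = 1e-12)
  expect_equal(resize_bilinear(matrix(2.5, 7, 9), 128, 128),
               matrix(2.5, 128, 128))
  src <- matrix(rnorm(50 * 80), 50)
  rs <- resize_bilinear(src, 128, 128)
  expect_gte(min(rs), min(src) - 1e-12)
  expect_lte(max(rs), max(src) + 1e-12)
  # 1-pixel dimension falls back to replication
  expect_equal(resize_bilinear(matrix(1:3, 1, 3), 2, 3)[1, ],
               resize_bilinear(matrix(1:3, 1, 3), 2, 3)[2, ])
})

test_that("build_image produces normalized tensors in montage order", {
  fs <- 256
  set.seed(8)
  seg <- make_segment(matrix(rnorm(3 * fs), 3), "preictal",
                      duration = 1)
  img <- build_image(seg, fs, grid = make_scale_grid(fs, 1, 50, 6),
                     freq_bins = 32, out_h = 32, out_w = 32)
  expect_equal(dim(img$pixels), c(32, 32, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_equal(img$meta$label, "preictal")

  # deterministic
  img2 <- build_image(seg, fs, grid = make_scale_grid(fs, 1, 50, 6),
                      freq_bins = 32, out_h = 32, out_w = 32)
  expect_identical(img$pixels, img2$pixels)

  # all-zero segment -> all-zero image
  z <- build_image(make_segment(matrix(0, 2, fs), "interictal",
                                duration = 1),
                   fs, grid = make_scale_grid(fs, 1, 50, 6),
                   freq_bins = 32, out_h = 32, out_w = 32)
  expect_equal(max(abs(z$pixels)), 0)

  # channel order: a tone only in channel 2 lights only plane 2
  d <- matrix(0, 3, 3 * fs)
  d[2, ] <- sin(2 * pi * 10 * (0:(3 * fs - 1)) / fs)
  tag <- build_image(make_segment(d, "preictal", duration = 3), fs,
                     grid = make_scale_grid(fs, 1, 50, 6),
                     freq_bins = 32, out_h = 32, out_w = 32)
  expect_equal(max(tag$pixels[, , 1]), 0)
  expect_equal(max(tag$pixels[, , 3]), 0)
  expect_equal(max(tag$pixels[, , 2]), 1)

  # cwt transform variant keeps shape
  cimg <- build_image(seg, fs, grid = make_scale_grid(fs, 1, 50, 6),
                      transform = "cwt", out_h = 32, out_w = 32)
  expect_equal(dim(cimg$pixels), c(32, 32, 3))
})
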