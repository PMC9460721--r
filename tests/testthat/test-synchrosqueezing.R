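# CWT, phase transform and synchrosqueezing against independent oracles.

test_that("scale grid has floor(v log2(fmax/fmin)) + 1 frequencies", {
  g <- make_scale_grid(256, 1, 50, 8)
  expect_length(g$freq_hz, 46)
  expect_equal(g$freq_hz[1], 1)
  expect_true(all(diff(g$freq_hz) > 0))
  expect_true(all(diff(g$scale) < 0))
  # pseudo-frequency relation f = f_c * fs / a
  expect_equal(g$freq_hz, 1 * 256 / g$scale)
  expect_length(make_scale_grid(256, 5, 5)$freq_hz, 1)
  expect_error(make_scale_grid(256, 1, 200), "Nyquist")
  expect_error(make_scale_grid(256, 0, 50), "positive")
})

test_that("cwt is linear and maps zero to zero", {
  g <- make_scale_grid(64, 2, 20, 6)
  t <- (0:255) / 64
  x <- sin(2 * pi * 5 * t)
  y <- cos(2 * pi * 9 * t)
  Wx <- cwt(x, grid = g)$coeffs
  Wy <- cwt(y, grid = g)$coeffs
  Wxy <- cwt(2 * x + y, grid = g)$coeffs
  expect_equal(Wxy, 2 * Wx + Wy, tolerance = 1e-12)
  expect_equal(max(Mod(cwt(rep(0, 128), grid = g)$coeffs)), 0)
  expect_error(cwt(c(1, NaN, 3), grid = g), "NaN")
  expect_error(cwt(1, grid = g), "2 samples")
})

test_that("FFT-based cwt matches the Riemann-sum oracle", {
  g <- make_scale_grid(256, 2, 50, 8)
  set.seed(11)
  for (i in 1:3) {
    x <- as.numeric(stats::filter(rnorm(512), rep(0.3, 4), sides = 2))
    x[is.na(x)] <- 0
    a <- cwt(x, grid = g)$coeffs
    b <- cwt_direct(x, grid = g)$coeffs
    expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-3)
  }
})

test_that("tone localizes at the nearest grid frequency", {
  g <- make_scale_grid(256, 2, 50, 8)
  x <- sin(2 * pi * 10 * (0:511) / 256)
  W <- Mod(cwt(x, grid = g)$coeffs)
  k10 <- which.min(abs(g$freq_hz - 10))
  interior <- 129:384
  expect_true(all(apply(W[, interior], 2, which.max) %in%
                    (k10 + c(-1, 0, 1))))
})

test_that("phase transform recovers the instantaneous frequency", {
  g <- make_scale_grid(256, 2, 50, 8)
  x <- cos(2 * pi * 8 * (0:767) / 256)
  cm <- cwt(x, grid = g)
  ph <- phase_transform(cm)
  k8 <- which.min(abs(g$freq_hz - 8))
  interior <- 200:568
  expect_true(all(abs(ph$omega[k8, interior] - 8) < 0.1))
  # finite-difference oracle for the spectral derivative
  fd <- (cm$coeffs[k8, interior + 1] - cm$coeffs[k8, interior - 1]) /
    (2 / 256)
  om_fd <- Im(fd * Conj(cm$coeffs[k8, interior])) /
    (2 * pi * Mod(cm$coeffs[k8, interior])^2)
  # the centered difference at spacing 1/fs carries a sinc(2 pi f / fs)
  # truncation factor (~0.6% at 8 Hz); agreement within 1%
  expect_equal(ph$omega[k8, interior], om_fd, tolerance = 1e-2)
  # all-zero map -> nothing valid
  ph0 <- phase_transform(cwt(rep(0, 64), grid = make_scale_grid(256, 4, 20)))
  expect_false(any(ph0$valid_mask))
})

test_that("synchrosqueezing matches the brute-force binning oracle", {
  g <- make_scale_grid(256, 2, 40, 6)
  set.seed(3)
  x <- sin(2 * pi * 10 * (0:255) / 256) + 0.5 * rnorm(256)
  cm <- cwt(x, grid = g)
  ph <- phase_transform(cm)
  sq <- synchrosqueeze(cm, ph, freq_bins = 64)
  orc <- oracle_squeeze(cm, ph, 64, g$fmin, g$fmax)
  expect_equal(sq$coeffs, orc, tolerance = 1e-12)   # bin-exact
  expect_error(synchrosqueeze(cm, ph, freq_bins = 1), "at least 2")
})

test_that("per-column reassignment mass is conserved exactly", {
  g <- make_scale_grid(256, 0.5, 50, 8)
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(768)
    cm <- cwt(x, grid = g)
    ph <- phase_transform(cm)
    sq <- synchrosqueeze(cm, ph, 128)
    keep <- ph$valid_mask & !is.na(ph$omega) &
      ph$omega >= g$fmin & ph$omega <= g$fmax
    rhs <- colSums(cm$coeffs * ifelse(keep, 1, 0)) * log(2) / 8
    expect_lt(max(Mod(colSums(sq$coeffs) - rhs)) / max(Mod(rhs)), 1e-12)
  }
})

test_that("squeezed tone is sharper than the scalogram (entropy)", {
  g <- make_scale_grid(256, 0.5, 50, 8)
  x <- sin(2 * pi * 10 * (0:767) / 256)
  cm <- cwt(x, grid = g)
  sq <- synchrosqueeze(cm, phase_transform(cm), 128)
  entropy <- function(m) {
    p <- m / sum(m)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  m_swt <- rowMeans(Mod(sq$coeffs))
  m_cwt <- approx(g$freq_hz, rowMeans(Mod(cm$coeffs)), xout = sq$freqs,
                  rule = 2)$y
  expect_lt(entropy(m_swt), entropy(m_cwt))
})

test_that("boundary flags mark the per-scale cone of influence", {
  g <- make_scale_grid(256, 4, 40, 6)
  cm <- cwt(rnorm(512), grid = g)
  bm <- boundary_mask(cm)
  expect_equal(dim(bm), dim(cm$coeffs))
  supp <- wavelet_support(cm$wavelet, g$scale)
  # row for the smallest scale has the narrowest flagged margin
  expect_equal(sum(bm[nrow(bm), ]), 2 * min(supp))
  expect_equal(sum(bm[1, ]), min(2 * max(supp), 512))
  expect_false(any(bm[nrow(bm), (min(supp) + 1):(512 - min(supp))]))
})

test_that("time-shift covariance holds away from boundaries", {
  g <- make_scale_grid(256, 4, 40, 6)
  t <- (0:1023) / 256
  x <- sin(2 * pi * 12 * t) * exp(-((t - 2)^2))
  s <- 64
  W1 <- cwt(x, grid = g)$coeffs
  W2 <- cwt(c(rep(0, s), x[1:(1024 - s)]), grid = g)$coeffs
  interior <- 400:700
  expect_equal(W2[, interior + s], W1[, interior], tolerance = 1e-2)
})
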