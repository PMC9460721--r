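# Network construction, gradients, training behaviour, cross-validation.

test_that("layer graph has five same-size fusion maps and the expected
           parameter count", {
  cfg <- model_config()                      # full profile, 128x128x18
  s <- cpp_cnn_shapes(ssqeeg:::cfg_to_cpp(cfg))
  expect_equal(s$post_sizes, c(64, 32, 16, 8, 4))
  expect_equal(s$strides, c(2, 1, 1, 1, 1))  # block 1 reaches 32 by stride
  expect_equal(s$factors, c(1, 1, 2, 4, 8))
  expect_equal(sum(grepl("^conv", s$name)), sum(cfg$block_convs))

  # independent arithmetic oracle for the total parameter count
  widths <- cfg$block_widths; convs <- cfg$block_convs
  expected <- 0
  input <- 18
  for (b in 1:5) {
    for (j in seq_len(convs[b])) {
      expected <- expected + widths[b] * input * 9 + widths[b]
      input <- widths[b]
    }
  }
  expected <- expected + sum(64 * widths + 64)          # 1x1 projections
  expected <- expected + sum(64 * 64 * c(2, 4, 8)^2 + 64)  # deconvs
  flat <- 5 * 64 * 32 * 32
  expected <- expected + 256 * flat + 256 + 64 * 256 + 64 + 2 * 64 + 2
  got <- sum(s$rows * s$cols + s$bias)
  expect_equal(got, expected)

  # fused maps all have fusion_size^2 pixels and P channels by layout
  m <- build_model(tiny_model_config())
  expect_equal(dim(m$weights$W$fc1),
               c(16L, 5L * 4L * 8L * 8L))
})

test_that("config validation rejects impossible geometries", {
  expect_error(model_config(input_shape = c(100, 100, 2)), "divisible")
  expect_error(model_config(input_shape = c(128, 64, 2)), "H == W")
  expect_error(model_config(block_convs = c(2, 2)), "length 5")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(input_shape = c(32, 32, 2),
                      block_widths = c(2, 3, 3, 3, 3),
                      projection_channels = 3, fusion_size = 8,
                      fc_sizes = c(6, 5), dropout_rates = c(0, 0),
                      seed = 3)
  cc <- ssqeeg:::cfg_to_cpp(cfg)
  w <- ssqeeg:::cpp_cnn_init(cc, 3)
  set.seed(1)
  x <- runif(32 * 32 * 2)
  g <- ssqeeg:::cpp_cnn_lossgrad(cc, w, x, 1L)
  eps <- 1e-6
  checked <- 0
  for (nm in c("conv1_1", "conv3_2", "proj1", "deconv5", "fc1", "out")) {
    set.seed(match(nm, names(w$W)))
    for (i in sample(length(w$W[[nm]]), 4)) {
      w2 <- w
      w2$W[[nm]][i] <- w2$W[[nm]][i] + eps
      l1 <- ssqeeg:::cpp_cnn_lossgrad(cc, w2, x, 1L)$loss
      w2$W[[nm]][i] <- w2$W[[nm]][i] - 2 * eps
      l0 <- ssqeeg:::cpp_cnn_lossgrad(cc, w2, x, 1L)$loss
      num <- (l1 - l0) / (2 * eps)
      expect_equal(g$grad$W[[nm]][i], num, tolerance = 1e-4)
      checked <- checked + 1
    }
  }
  expect_equal(checked, 24)
})

test_that("softmax outputs are normalized probabilities", {
  m <- build_model(tiny_model_config())
  imgs <- make_image_set(3)
  p <- predict(m, imgs)
  expect_true(all(abs(rowSums(p$prob) - 1) < 1e-6))  # float engine
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  # duplicated input gives identical outputs
  p2 <- predict(m, imgs[c(1, 1)])
  expect_equal(p2$prob[1, ], p2$prob[2, ])
  # shape mismatch errors
  bad <- make_test_image("preictal", 1, side = 64)
  expect_error(predict(m, list(bad)), "shape")
})

test_that("training learns separable data, deterministically", {
  imgs <- make_image_set(40)
  train <- imgs[c(1:30, 41:70)]
  val <- imgs[c(31:40, 71:80)]
  m <- train_fold(train, val, tiny_model_config())
  expect_equal(nrow(m$history), 25)
  # monotone learning: median loss late < early
  expect_lt(median(m$history$train_loss[20:25]),
            median(m$history$train_loss[1:3]))
  expect_gte(max(m$history$train_acc), 0.9)
  p <- predict(m, val)
  expect_gte(mean(p$label == vapply(val, function(im) im$meta$label, "")), 0.9)

  # identical seed -> identical final loss; different seed differs
  m2 <- train_fold(train, val, tiny_model_config())
  expect_equal(tail(m$history$train_loss, 1),
               tail(m2$history$train_loss, 1), tolerance = 1e-9)
  m3 <- train_fold(train, val, tiny_model_config(seed = 99))
  expect_false(isTRUE(all.equal(tail(m$history$train_loss, 1),
                                tail(m3$history$train_loss, 1))))

  # epochs = 0: untrained, empty history
  m0 <- train_fold(train, config = tiny_model_config(epochs = 0))
  expect_equal(nrow(m0$history), 0)
  expect_equal(m0$weights$W$conv1_1,
               build_model(tiny_model_config(epochs = 0))$weights$W$conv1_1)

  # single-class training set errors
  expect_error(train_fold(imgs[1:10], config = tiny_model_config()),
               "single class")
})

test_that("stratified 5-fold cross-validation partitions correctly", {
  imgs <- make_image_set(30)                 # 60 images, 30/30
  cfg <- tiny_model_config(epochs = 2)
  folds <- cross_validate(imgs, k = 5, config = cfg, seed = 2)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(f$val_idx), 0)
  expect_true(all(sizes == 12))
  # each image validated exactly once
  all_idx <- sort(unlist(lapply(folds, `[[`, "val_idx")))
  expect_equal(all_idx, seq_along(imgs))
  # class ratio within one segment of global per fold
  for (f in folds)
    expect_lte(abs(sum(f$truth == "preictal") -
                     sum(f$truth == "interictal")), 1)
  expect_error(cross_validate(imgs[c(1:3, 31:60)], k = 5,
                              config = cfg, seed = 1),
               "smallest class")
})
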