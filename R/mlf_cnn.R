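# Multi-level-feature CNN: R-side configuration, training and prediction
# wrappers around the compiled network (src/cnn.cpp).

#' Model configuration for the multi-level-feature CNN
#'
#' Five VGG-style convolutional blocks (3x3 kernels, stride 1, ReLU, 2x2
#' max-pool; the fourth and fifth blocks carry fewer convolutions than
#' VGG16), a 1x1 projection after every block to a common channel width,
#' upsampling of each projected map to `fusion_size` (transposed
#' convolution; blocks larger than the fusion size are reached by a
#' strided 1x1 projection), channel concatenation of the five fusion maps,
#' and a head of two fully-connected + dropout layers and a softmax over
#' two classes (positive class: preictal).
#'
#' @param input_shape `c(H, W, C)`; `H == W` and divisible by 32.
#' @param block_convs convolutions per block (default `c(2,2,3,2,2)`).
#' @param block_widths channels per block (default VGG16 widths).
#' @param projection_channels width of the 1x1 projections (default 64).
#' @param fusion_size spatial side of the fused maps (default 32).
#' @param fc_sizes widths of the two fully-connected layers.
#' @param dropout_rates dropout after each fully-connected layer.
#' @param n_classes number of output classes (2).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-4).
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param profile `"full"` for the defaults above, `"reduced"` for the
#'   desk-scale profile used in the synthetic end-to-end evaluation
#'   (widths 4/8/8/8/8, projection 16, fusion 16, FC 64/32, 10 epochs,
#'   learning rate 1e-3).
#' @return object of class `model_config`.
#' @export
model_config <- function(input_shape = c(128, 128, 18),
                         block_convs = c(2, 2, 3, 2, 2),
                         block_widths = c(64, 128, 256, 512, 512),
                         projection_channels = 64,
                         fusion_size = 32,
                         fc_sizes = c(256, 64),
                         dropout_rates = c(0.5, 0.5),
                         n_classes = 2,
                         epochs = 50,
                         batch_size = 32,
                         learning_rate = 1e-4,
                         seed = 1L,
                         profile = c("full", "reduced")) {
  profile <- match.arg(profile)
  if (profile == "reduced") {
    if (missing(block_widths)) block_widths <- c(4, 8, 8, 8, 8)
    if (missing(projection_channels)) projection_channels <- 16
    if (missing(fusion_size)) fusion_size <- 16
    if (missing(fc_sizes)) fc_sizes <- c(64, 32)
    if (missing(epochs)) epochs <- 10
    if (missing(learning_rate)) learning_rate <- 1e-3
  }
  if (length(input_shape) != 3 || input_shape[1] != input_shape[2])
    stop("input_shape must be c(H, W, C) with H == W")
  if (input_shape[1] %% 32 != 0)
    stop("input spatial size must be divisible by 2^5 (five pooling stages)")
  if (length(block_convs) != 5 || length(block_widths) != 5)
    stop("block_convs and block_widths must have length 5")
  if (length(fc_sizes) != 2 || length(dropout_rates) != 2)
    stop("fc_sizes and dropout_rates must have length 2")
  structure(list(input_shape = as.integer(input_shape),
                 block_convs = as.integer(block_convs),
                 block_widths = as.integer(block_widths),
                 projection_channels = as.integer(projection_channels),
                 fusion_size = as.integer(fusion_size),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_rates = as.numeric(dropout_rates),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 seed = as.integer(seed), profile = profile),
            class = "model_config")
}

cfg_to_cpp <- function(config) {
  list(input_side = config$input_shape[1],
       input_channels = config$input_shape[3],
       block_convs = config$block_convs,
       block_widths = config$block_widths,
       projection_channels = config$projection_channels,
       fusion_size = config$fusion_size,
       fc1 = config$fc_sizes[1], fc2 = config$fc_sizes[2],
       n_classes = config$n_classes,
       dropout1 = config$dropout_rates[1],
       dropout2 = config$dropout_rates[2])
}

#' Layer shapes and parameter counts of a configuration
#'
#' @param config a [model_config()].
#' @return data.frame with one row per parameterized layer: name, weight
#'   shape, parameter count (weights + biases).
#' @export
model_shapes <- function(config) {
  s <- cpp_cnn_shapes(cfg_to_cpp(config))
  data.frame(name = s$name, out_dim = s$rows, in_dim = s$cols,
             n_params = s$rows * s$cols + s$rows)
}

images_to_matrix <- function(images, config) {
  D <- prod(config$input_shape)
  X <- matrix(0, nrow = D, ncol = length(images))
  for (i in seq_along(images)) {
    px <- images[[i]]$pixels
    if (!all(dim(px) == config$input_shape))
      stop("image ", i, " has shape ", paste(dim(px), collapse = "x"),
           ", expected ", paste(config$input_shape, collapse = "x"))
    X[, i] <- as.vector(px)
  }
  X
}

image_labels <- function(images) {
  lab <- vapply(images, function(im) im$meta$label, "")
  if (!all(lab %in% c("preictal", "interictal")))
    stop("image labels must be preictal/interictal")
  lab
}

#' Build an untrained multi-level-feature CNN
#'
#' Initializes weights (He-normal, seeded) for the layer graph described
#' by `config`.
#' @param config a [model_config()].
#' @return object of class `mlf_cnn` with fields `config`, `weights`,
#'   `history` (empty).
#' @export
build_model <- function(config = model_config()) {
  weights <- cpp_cnn_init(cfg_to_cpp(config), config$seed)
  structure(list(config = config, weights = weights,
                 history = data.frame(epoch = integer(),
                                      train_loss = numeric(),
                                      train_acc = numeric(),
                                      val_loss = numeric(),
                                      val_acc = numeric())),
            class = "mlf_cnn")
}

#' Train the network on one fold
#'
#' Minimizes softmax cross-entropy with Adam. Fully deterministic given
#' `config$seed` on CPU (the network owns its random stream for
#' initialization, shuffling and dropout). `epochs = 0` returns the
#' untrained model with empty history.
#'
#' @param train_images list of [build_image()] outputs; both classes must
#'   be present (unless `epochs = 0`).
#' @param val_images optional held-out list, evaluated after each epoch.
#' @param config a [model_config()].
#' @param model optional existing `mlf_cnn` to continue training.
#' @return a trained `mlf_cnn`; `history` has one row per epoch run.
#' @export
train_fold <- function(train_images, val_images = NULL,
                       config = model_config(), model = NULL) {
  if (is.null(model)) model <- build_model(config)
  config <- model$config
  if (config$epochs == 0) return(model)      # untrained, empty history
  y <- image_labels(train_images)
  if (config$epochs > 0 && length(unique(y)) < 2)
    stop("training set contains a single class: ", unique(y))
  X <- images_to_matrix(train_images, config)
  yi <- as.integer(y == "preictal")
  if (length(val_images)) {
    Xv <- images_to_matrix(val_images, config)
    yv <- as.integer(image_labels(val_images) == "preictal")
  } else {
    Xv <- matrix(0, nrow = nrow(X), ncol = 0)
    yv <- integer()
  }
  fit <- cpp_cnn_train(cfg_to_cpp(config), model$weights, X, yi, Xv, yv,
                       config$epochs, config$batch_size,
                       config$learning_rate, config$seed)
  model$weights <- fit$weights
  model$history <- rbind(model$history, fit$history)
  model
}

#' Predict class probabilities and hard labels
#'
#' @param object a trained `mlf_cnn`.
#' @param images list of `tf_image`s matching the model's input shape.
#' @param ... unused.
#' @return list with `prob` (n x 2 matrix, columns `interictal`,
#'   `preictal`) and `label` (character; probability ties resolve to
#'   `interictal`, the non-alarm class).
#' @export
predict.mlf_cnn <- function(object, images, ...) {
  X <- images_to_matrix(images, object$config)
  pr <- cpp_cnn_predict(cfg_to_cpp(object$config), object$weights, X)
  colnames(pr) <- c("interictal", "preictal")
  label <- ifelse(pr[, "preictal"] > pr[, "interictal"],
                  "preictal", "interictal")
  list(prob = pr, label = label)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the images into `k` stratified folds (class proportions
#' preserved within one segment per fold), trains one model per fold on
#' the remaining data and evaluates on the held-out fold. Intended to be
#' run per patient (patient-specific models).
#'
#' @param images balanced list of `tf_image`s.
#' @param k number of folds (default 5).
#' @param config a [model_config()].
#' @param seed seed for the fold assignment; fold `i`'s model trains with
#'   `config$seed + i`.
#' @return list of `k` fold results: `val_idx`, `truth`, `pred`, `prob`,
#'   `confusion`, `history`.
#' @export
cross_validate <- function(images, k = 5, config = model_config(),
                           seed = 1L) {
  y <- image_labels(images)
  counts <- table(y)
  if (k > min(counts))
    stop("k = ", k, " exceeds the size of the smallest class (",
         min(counts), ")")
  fold <- integer(length(y))
  for (cls in names(counts)) {
    idx <- which(y == cls)
    idx <- with_seed(seed + match(cls, names(counts)), sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(i) {
    val_idx <- which(fold == i)
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    model <- train_fold(images[fold != i], images[val_idx], cfg_i)
    pred <- predict(model, images[val_idx])
    list(fold = i, val_idx = val_idx, truth = y[val_idx],
         pred = pred$label, prob = pred$prob,
         confusion = confusion(y[val_idx], pred$label),
         history = model$history)
  })
}
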