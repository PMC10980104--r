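# Maturation-stage CNN classifier and the three-dataset training design.
#
# The reference architecture takes a (96, 96, 3) crop through three
# convolution stages (kernel 3, output channels 32, 16, 4, each followed by
# a max-pool of window 4 with stride 2 and padding 1, which halves the
# spatial size and yields activations (32,48,48), (16,24,24), (4,12,12)),
# then two fully connected layers (576 -> 64 -> 3) and a softmax head.
# Training applies a fresh random 96 x 96 crop and random horizontal flip to
# every image in every epoch; evaluation uses a deterministic center crop.

#' Classifier architecture specification
#'
#' @param input_size crop side length fed to the network (default 96; must be
#'   a multiple of 8 so three halvings are integral).
#' @param conv_channels output channels of the three convolution stages.
#' @param fc_hidden width of the first fully connected layer.
#' @param n_classes number of output classes.
#' @return object of class `classifier_spec`, with the per-stage activation
#'   shapes in `$activation_shapes` and the flattened dimension entering the
#'   first fully connected layer in `$flatten_dim`.
#' @export
#' @examples
#' classifier_spec()$flatten_dim  # 576
classifier_spec <- function(input_size = 96, conv_channels = c(32, 16, 4),
                            fc_hidden = 64, n_classes = 3) {
  stopifnot(length(conv_channels) == 3, input_size %% 8 == 0, input_size >= 8)
  sizes <- input_size / c(2, 4, 8)
  structure(list(
    input_size = input_size, conv_channels = conv_channels,
    fc_hidden = fc_hidden, n_classes = n_classes,
    activation_shapes = lapply(1:3, function(i) c(conv_channels[i], sizes[i], sizes[i])),
    flatten_dim = conv_channels[3] * sizes[3]^2),
    class = "classifier_spec")
}

#' Classifier training configuration
#'
#' Defaults follow the study protocol for the classifier: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, learning rate 5e-4, batch size 64,
#' 1000 epochs, and an L2 weight penalty standing in for weight-norm
#' regularization.
#'
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size minibatch size.
#' @param epochs training epochs (scalable down for desk-scale runs).
#' @param weight_penalty L2 coefficient applied to all weight matrices.
#' @param seed integer seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(learning_rate = 5e-4, adam_beta1 = 0.9,
                              adam_beta2 = 0.999, batch_size = 64,
                              epochs = 1000, weight_penalty = 1e-4, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, weight_penalty >= 0)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = batch_size,
                 epochs = epochs, weight_penalty = weight_penalty, seed = seed),
            class = "classifier_config")
}

#' Build the maturation-stage CNN classifier
#'
#' @param spec a [classifier_spec()].
#' @return object of class `cnn_classifier`. The network emits logits; use
#'   [predict_proba()] for class probabilities.
#' @export
build_cnn_classifier <- function(spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  ch <- spec$conv_channels
  net <- nn_net(
    nn_conv(3, ch[1], k = 3, stride = 1, pad = 1, init = "he"), nn_relu(),
    nn_maxpool(4, 2, 1),
    nn_conv(ch[1], ch[2], k = 3, stride = 1, pad = 1, init = "he"), nn_relu(),
    nn_maxpool(4, 2, 1),
    nn_conv(ch[2], ch[3], k = 3, stride = 1, pad = 1, init = "he"), nn_relu(),
    nn_maxpool(4, 2, 1),
    nn_flatten(),
    nn_linear(spec$flatten_dim, spec$fc_hidden, init = "he"), nn_relu(),
    nn_linear(spec$fc_hidden, spec$n_classes, init = "he")
  )
  structure(list(net = net, name = "proposed", input_size = spec$input_size,
                 source_size = round(spec$input_size * 4 / 3),
                 flatten_dim = spec$flatten_dim, spec = spec,
                 classes = MATURATION_CLASSES, history = NULL),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf("<cnn_classifier '%s'  input %dx%d  flatten %d  %s>\n",
              x$name, x$input_size, x$input_size, x$flatten_dim,
              if (is.null(x$history)) "untrained"
              else sprintf("trained %d epochs", nrow(x$history))))
  invisible(x)
}

#' Random crop and horizontal flip augmentation
#'
#' Extracts a contiguous `crop` x `crop` sub-window at a uniformly random
#' offset from the (optionally horizontally flipped) input. Labels and
#' channel count are untouched. With `seed` supplied the result is a pure
#' function of `(image, crop, seed)`; otherwise the current RNG stream is
#' consumed.
#'
#' @param image (H, W, C) numeric array with H, W >= `crop`.
#' @param crop output side length (default 96).
#' @param seed optional integer seed.
#' @return (crop, crop, C) array.
#' @export
random_crop_flip <- function(image, crop = 96, seed = NULL) {
  d <- dim(image)
  if (length(d) != 3) stop("image must be an (H, W, C) array")
  if (d[1] < crop || d[2] < crop)
    stop(sprintf("input (%d x %d) smaller than crop size %d", d[1], d[2], crop))
  do_crop <- function() {
    flip <- stats::runif(1) < 0.5
    r0 <- sample.int(d[1] - crop + 1L, 1) - 1L
    c0 <- sample.int(d[2] - crop + 1L, 1) - 1L
    x <- if (flip) image[, rev(seq_len(d[2])), , drop = FALSE] else image
    x[r0 + seq_len(crop), c0 + seq_len(crop), , drop = FALSE]
  }
  if (is.null(seed)) do_crop() else with_seed(seed, do_crop())
}

#' Assemble the three classifier training datasets
#'
#' The three-dataset design: `small_real` is the original (GAN-training)
#' dataset; `large_real` adds extra real images to it; `mixed` adds the
#' GAN-synthetic library to it. By construction
#' `|mixed| = |small_real| + |synthetic|` and both larger sets contain
#' `small_real`.
#'
#' @param small_real list of `labeled_image` (the GAN's training set).
#' @param extra_real list of additional real `labeled_image` (may be empty).
#' @param synthetic a `synthetic_library` (or plain list of GAN-provenance
#'   `labeled_image`; may be empty).
#' @return object of class `train_set_triplet` with elements `small_real`,
#'   `large_real`, `mixed`, and a per-class `counts` table.
#' @export
assemble_training_sets <- function(small_real, extra_real = list(),
                                   synthetic = list()) {
  syn_images <- if (inherits(synthetic, "synthetic_library")) synthetic$images
                else synthetic
  for (s in list(small_real, extra_real, syn_images))
    if (length(s) && !all(vapply(s, inherits, NA, "labeled_image")))
      stop("all inputs must be labeled_image lists")
  base_classes <- sort(unique(vapply(small_real, function(im) im$label, "")))
  for (nm in c("extra_real", "synthetic")) {
    s <- if (nm == "extra_real") extra_real else syn_images
    if (length(s)) {
      cls <- sort(unique(vapply(s, function(im) im$label, "")))
      if (!all(cls %in% base_classes))
        stop(nm, " contains classes absent from small_real: ",
             paste(setdiff(cls, base_classes), collapse = ", "))
    }
  }
  triplet <- list(small_real = small_real,
                  large_real = c(small_real, extra_real),
                  mixed = c(small_real, syn_images))
  counts <- sapply(triplet, function(s)
    table(factor(vapply(s, function(im) im$label, ""),
                 levels = MATURATION_CLASSES)))
  structure(c(triplet, list(counts = counts)), class = "train_set_triplet")
}

#' @export
print.train_set_triplet <- function(x, ...) {
  cat(sprintf("<train_set_triplet  small_real=%d  large_real=%d  mixed=%d>\n",
              length(x$small_real), length(x$large_real), length(x$mixed)))
  print(x$counts)
  invisible(x)
}

#' Train a maturation-stage classifier
#'
#' Minimizes softmax cross-entropy with Adam and an L2 weight penalty.
#' Source images are resized once to 4/3 of the crop size (the 128-px source
#' for a 96-px crop) and mapped to \[-1, 1\]; every epoch each image receives
#' a fresh random crop and random horizontal flip. The run is a deterministic
#' function of `config$seed`.
#'
#' @param dataset list of `labeled_image` covering at least two classes.
#' @param config a [classifier_config()].
#' @param model optionally a pre-built `cnn_classifier` (e.g. an ablation
#'   architecture); by default the reference architecture from `spec`.
#' @param spec a [classifier_spec()] used when `model` is `NULL`.
#' @param verbose print progress every `verbose` epochs (0 = silent).
#' @return the trained `cnn_classifier`, with `$history` (per-epoch mean loss
#'   and training accuracy) and `$config` attached.
#' @export
train_classifier <- function(dataset, config = classifier_config(),
                             model = NULL, spec = classifier_spec(),
                             verbose = 0) {
  labels <- vapply(dataset, function(im) im$label, "")
  if (length(unique(labels)) < 2)
    stop("training dataset must contain at least two classes")
  with_seed(config$seed, {
    if (is.null(model)) model <- build_cnn_classifier(spec)
    nn_adam_init(model$net)
    n <- length(dataset)
    src <- array(0, c(model$source_size, model$source_size, 3, n))
    for (i in seq_len(n))
      src[, , , i] <- resize_image(dataset[[i]]$pixels, model$source_size)
    src <- to_model_space(src)
    y <- as.integer(factor(labels, levels = model$classes))
    hist_loss <- hist_acc <- numeric(config$epochs)
    t <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        B <- length(idx)
        xb <- array(0, c(model$input_size, model$input_size, 3, B))
        for (j in seq_len(B))
          xb[, , , j] <- random_crop_flip(src[, , , idx[j]], model$input_size)
        logits <- nn_forward(model$net, xb, training = TRUE)
        ce <- softmax_ce(logits, y[idx])
        nn_backward(model$net, ce$grad)
        t <- t + 1L
        nn_adam_step(model$net, t, config$learning_rate, config$adam_beta1,
                     config$adam_beta2, weight_decay = config$weight_penalty)
        ep_loss <- ep_loss + ce$loss * B
        ep_correct <- ep_correct + sum(max.col(ce$probs) == y[idx])
      }
      hist_loss[ep] <- ep_loss / n
      hist_acc[ep] <- ep_correct / n
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("[classifier] epoch %d/%d  loss=%.4f  acc=%.3f",
                        ep, config$epochs, hist_loss[ep], hist_acc[ep]))
    }
    model$history <- data.frame(epoch = seq_len(config$epochs),
                                loss = hist_loss, accuracy = hist_acc)
    model$config <- config
    model
  })
}

#' Class probabilities for images
#'
#' Evaluation-time preprocessing is deterministic: resize to the model's
#' source size, center crop to the input size, map to \[-1, 1\], forward in
#' evaluation mode, softmax.
#'
#' @param model a trained `cnn_classifier`.
#' @param images list of `labeled_image`, or a (H, W, 3, N) storage-space
#'   array.
#' @return (N, 3) matrix of probabilities; each row sums to 1 and columns are
#'   named by class. The predicted class is the row-wise argmax.
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "cnn_classifier"))
  if (is.list(images)) {
    n <- length(images)
    xb <- array(0, c(model$input_size, model$input_size, 3, n))
    for (i in seq_len(n)) {
      s <- resize_image(images[[i]]$pixels, model$source_size)
      xb[, , , i] <- center_crop(s, model$input_size)
    }
  } else {
    d <- dim(images)
    if (length(d) != 4 || d[3] != 3) stop("expected an (H, W, 3, N) array")
    n <- d[4]
    xb <- array(0, c(model$input_size, model$input_size, 3, n))
    for (i in seq_len(n)) {
      s <- resize_image(images[, , , i], model$source_size)
      xb[, , , i] <- center_crop(s, model$input_size)
    }
  }
  logits <- nn_forward(model$net, to_model_space(xb), training = FALSE)
  probs <- softmax_probs(logits)
  colnames(probs) <- model$classes
  probs
}

#' Predicted class labels
#' @inheritParams predict_proba
#' @return character vector of predicted classes.
#' @export
predict_class <- function(model, images) {
  model$classes[max.col(predict_proba(model, images))]
}

#' Flattened dimension entering the first fully connected layer
#'
#' @param model_name one of `"proposed"`, `"fc_only"`, `"small_cnn"`,
#'   `"disc_like"`.
#' @return integer.
#' @export
#' @examples
#' flatten_feature_dim("proposed")  # 576
flatten_feature_dim <- function(model_name) {
  switch(match.arg(model_name, c("proposed", "fc_only", "small_cnn", "disc_like")),
         proposed = 4L * 12L * 12L,
         fc_only = 3L * 96L * 96L,
         small_cnn = 4L * 8L * 8L,
         disc_like = 4L * 16L * 16L)
}

#' Build an ablation architecture
#'
#' The three comparison models of the ablation study, all ending in a 3-class
#' softmax and trainable with [train_classifier()]:
#' * `fc_only` - five fully connected layers
#'   (27648 -> 4096 -> 1024 -> 256 -> 64 -> 3) on the flattened 96-px crop;
#' * `small_cnn` - two convolution stages with activations (16,32,32) and
#'   (4,8,8), then 256 -> 32 -> 3;
#' * `disc_like` - a larger discriminator-style CNN taking the full 128-px
#'   image through three stride-2 convolutions (channels 32, 16, 4, flatten
#'   1024 -> 64 -> 3).
#'
#' `input_size` scales `fc_only` and `small_cnn` down for cheap runs (the
#' flattened sizes then scale accordingly; the defaults reproduce the
#' reference dimensions).
#'
#' @param name ablation model name.
#' @param input_size crop side length; default 96 (128 for `disc_like`).
#' @return a `cnn_classifier`.
#' @export
build_ablation_model <- function(name = c("fc_only", "small_cnn", "disc_like"),
                                 input_size = NULL) {
  name <- match.arg(name)
  if (name == "fc_only") {
    s <- input_size %||% 96L
    d0 <- 3L * s * s
    widths <- c(d0, 4096L, 1024L, 256L, 64L, 3L)
    if (s != 96) widths <- c(d0, pmin(c(4096L, 1024L), d0), 256L, 64L, 3L)
    layers <- list(nn_flatten())
    for (i in seq_len(length(widths) - 1)) {
      layers <- c(layers, list(nn_linear(widths[i], widths[i + 1], init = "he")))
      if (i < length(widths) - 1) layers <- c(layers, list(nn_relu()))
    }
    net <- do.call(nn_net, layers)
    flat <- d0
  } else if (name == "small_cnn") {
    s <- input_size %||% 96L
    if (s %% 12 != 0) stop("small_cnn input size must be a multiple of 12")
    net <- nn_net(
      nn_conv(3, 16, k = 3, stride = 1, pad = 1, init = "he"), nn_relu(),
      nn_maxpool(3, 3, 0),
      nn_conv(16, 4, k = 3, stride = 1, pad = 1, init = "he"), nn_relu(),
      nn_maxpool(4, 4, 0),
      nn_flatten(),
      nn_linear(4L * (s %/% 12)^2, 32, init = "he"), nn_relu(),
      nn_linear(32, 3, init = "he")
    )
    flat <- 4L * (s %/% 12)^2
  } else {
    s <- input_size %||% 128L
    if (s %% 8 != 0) stop("disc_like input size must be a multiple of 8")
    net <- nn_net(
      nn_conv(3, 32, k = 4, stride = 2, pad = 1, init = "he"), nn_lrelu(),
      nn_conv(32, 16, k = 4, stride = 2, pad = 1, init = "he"), nn_bn2d(16), nn_lrelu(),
      nn_conv(16, 4, k = 4, stride = 2, pad = 1, init = "he"), nn_bn2d(4), nn_lrelu(),
      nn_flatten(),
      nn_linear(4L * (s %/% 8)^2, 64, init = "he"), nn_relu(),
      nn_linear(64, 3, init = "he")
    )
    flat <- 4L * (s %/% 8)^2
  }
  src <- if (name == "disc_like") s else round(s * 4 / 3)
  structure(list(net = net, name = name, input_size = s, source_size = src,
                 flatten_dim = flat, spec = NULL, classes = MATURATION_CLASSES,
                 history = NULL),
            class = "cnn_classifier")
}
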