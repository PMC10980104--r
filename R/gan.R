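# Per-class image GAN.
#
# Architecture (DCGAN-style, sized so that four strided stages connect the
# latent projection to the output resolution): the generator projects the
# 64-dim latent to an (s, s, base) feature map with s = image_size/16, then
# applies four stride-2 transposed convolutions with channel progression
# base -> base/2 -> base/4 -> base/8 -> out_channels, batch normalization and
# ReLU between layers and a final Tanh. The discriminator mirrors it with
# four stride-2 convolutions and Leaky ReLU (batch normalization on all but
# the first), followed by a linear head producing one real/fake logit.

#' GAN training configuration
#'
#' Defaults follow the study protocol for the image GAN: Adam with
#' `beta1 = 0.5`, `beta2 = 0.999`, learning rate 2e-4, batch size 64,
#' 2000 epochs, 128 x 128 output, 64-dim latent. `epochs`, `image_size` and
#' `base_channels` scale the model down for desk-scale runs.
#'
#' @param learning_rate Adam step size (> 0).
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param batch_size minibatch size.
#' @param epochs training epochs (>= 1); one epoch is one pass over the
#'   (shuffled) training set.
#' @param image_size output side length; must be a multiple of 16.
#' @param latent_dim latent vector length (default 64).
#' @param base_channels widest feature-map depth (default 256); must be a
#'   multiple of 8.
#' @param out_channels output channels (3 for RGB images, 5 for the temporal
#'   frames of the video GAN).
#' @param crop_frac side fraction kept by the random-crop augmentation.
#' @param flip apply random horizontal flips during training.
#' @param d_loss_floor skip the discriminator update on batches where its
#'   loss is already below this value (0, the default, never skips). Keeps
#'   the two networks in balance on tiny or degenerate training sets where
#'   the discriminator would otherwise win outright and starve the generator
#'   of gradient.
#' @param ema_decay exponential-moving-average decay for a smoothed copy of
#'   the generator weights (0 disables). Adversarial training makes the
#'   generator oscillate around the data statistics; sampling from the
#'   averaged weights removes most of that checkpoint-to-checkpoint bias.
#' @param saturating if `TRUE` the generator minimizes `log(1 - D(G(z)))`
#'   instead of the default non-saturating `-log D(G(z))`.
#' @param seed integer seed controlling initialization and training.
#' @return object of class `gan_config`.
#' @export
gan_config <- function(learning_rate = 2e-4, adam_beta1 = 0.5,
                       adam_beta2 = 0.999, batch_size = 64, epochs = 2000,
                       image_size = 128, latent_dim = 64, base_channels = 256,
                       out_channels = 3, crop_frac = 0.85, flip = TRUE,
                       d_loss_floor = 0, ema_decay = 0.99, saturating = FALSE,
                       seed = 1) {
  stopifnot(learning_rate > 0, adam_beta1 > 0, adam_beta2 > 0, batch_size >= 1,
            epochs >= 1, latent_dim >= 1)
  if (image_size %% 16 != 0) stop("image_size must be a multiple of 16")
  if (base_channels %% 8 != 0) stop("base_channels must be a multiple of 8")
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = batch_size,
                 epochs = epochs, image_size = image_size,
                 latent_dim = latent_dim, base_channels = base_channels,
                 out_channels = out_channels, crop_frac = crop_frac,
                 flip = flip, d_loss_floor = d_loss_floor,
                 ema_decay = ema_decay, saturating = saturating, seed = seed),
            class = "gan_config")
}

#' Draw latent vectors
#' @param n number of vectors.
#' @param latent_dim latent length (default 64).
#' @return (n, latent_dim) matrix of standard normal draws.
#' @export
sample_latent <- function(n, latent_dim = 64) {
  matrix(stats::rnorm(n * latent_dim), n, latent_dim)
}

#' Build the generator network
#'
#' @param config a [gan_config()].
#' @return object of class `gan_generator`; apply it with
#'   [generate_images()]. The number of transposed-convolution layers is
#'   available as `$n_tconv_layers`.
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  s <- config$image_size %/% 16L
  b <- config$base_channels
  net <- nn_net(
    nn_linear(config$latent_dim, s * s * b),
    nn_reshape(s, s, b),
    nn_bn2d(b), nn_relu(),
    nn_convT(b, b %/% 2, k = 4), nn_bn2d(b %/% 2), nn_relu(),
    nn_convT(b %/% 2, b %/% 4, k = 4), nn_bn2d(b %/% 4), nn_relu(),
    nn_convT(b %/% 4, b %/% 8, k = 4), nn_bn2d(b %/% 8), nn_relu(),
    nn_convT(b %/% 8, config$out_channels, k = 4),
    nn_tanh()
  )
  structure(list(net = net, config = config,
                 n_tconv_layers = sum(vapply(net, function(l) l$type == "convT", NA))),
            class = "gan_generator")
}

#' Map latent vectors through a generator
#'
#' @param generator a `gan_generator`.
#' @param z latent matrix (n, latent_dim) or a single latent vector.
#' @param training if `FALSE` (default) batch-norm layers use their running
#'   statistics, making the output a deterministic function of `z`.
#' @return array (size, size, channels, n) with values in \[-1, 1\].
#' @export
generate_images <- function(generator, z, training = FALSE) {
  stopifnot(inherits(generator, "gan_generator"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != generator$config$latent_dim)
    stop("latent vectors must have length ", generator$config$latent_dim)
  nn_forward(generator$net, z, training = training)
}

#' Build the discriminator network
#'
#' @param config a [gan_config()].
#' @return object of class `gan_discriminator`; apply it with
#'   [discriminate()]. The number of convolution layers is available as
#'   `$n_conv_layers`.
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  s <- config$image_size %/% 16L
  b <- config$base_channels
  net <- nn_net(
    nn_conv(config$out_channels, b %/% 8, k = 4, stride = 2, pad = 1), nn_lrelu(),
    nn_conv(b %/% 8, b %/% 4, k = 4, stride = 2, pad = 1), nn_bn2d(b %/% 4), nn_lrelu(),
    nn_conv(b %/% 4, b %/% 2, k = 4, stride = 2, pad = 1), nn_bn2d(b %/% 2), nn_lrelu(),
    nn_conv(b %/% 2, b, k = 4, stride = 2, pad = 1), nn_bn2d(b), nn_lrelu(),
    nn_flatten(),
    nn_linear(s * s * b, 1)
  )
  structure(list(net = net, config = config,
                 n_conv_layers = sum(vapply(net, function(l) l$type == "conv", NA))),
            class = "gan_discriminator")
}

#' Score images with a discriminator
#'
#' @param discriminator a `gan_discriminator`.
#' @param images array (size, size, channels, n) in \[-1, 1\]; a single
#'   (size, size, channels) image is promoted to a batch of one.
#' @param training passed to batch-norm layers.
#' @return numeric vector of n probabilities, each strictly inside (0, 1).
#' @export
discriminate <- function(discriminator, images, training = FALSE) {
  stopifnot(inherits(discriminator, "gan_discriminator"))
  cfg <- discriminator$config
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  d <- dim(images)
  if (d[1] != cfg$image_size || d[2] != cfg$image_size || d[3] != cfg$out_channels)
    stop(sprintf("discriminator expects (%d,%d,%d) input, got (%d,%d,%d)",
                 cfg$image_size, cfg$image_size, cfg$out_channels, d[1], d[2], d[3]))
  logits <- nn_forward(discriminator$net, images, training = training)
  as.numeric(stats::plogis(logits))
}

#' Adversarial losses from discriminator outputs
#'
#' With real/fake label convention 1/0, the discriminator loss is the negated
#' two-sided log likelihood `-mean(log D(x) + log(1 - D(G(z))))`, so
#' minimizing it maximizes the adversarial objective; the generator loss is
#' the non-saturating `-mean(log D(G(z)))` (or `mean(log(1 - D(G(z))))` when
#' `saturating = TRUE`).
#'
#' @param d_real,d_fake probability vectors in (0, 1) (clamped away from the
#'   endpoints before taking logs).
#' @param saturating use the saturating generator loss.
#' @return list with `discriminator_loss` and `generator_loss`.
#' @export
#' @examples
#' gan_losses(0.5, 0.5)$discriminator_loss  # 2 log 2
gan_losses <- function(d_real, d_fake, saturating = FALSE) {
  if (length(d_real) == 0 || length(d_fake) == 0)
    stop("d_real and d_fake must be non-empty")
  eps <- 1e-7
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  list(discriminator_loss = -(mean(log(dr)) + mean(log(1 - df))),
       generator_loss = if (saturating) mean(log(1 - df)) else -mean(log(df)))
}

# Random-crop / random-flip / resize augmentation used for GAN training
# (applied identically across channels). Consumes RNG.
augment_to_size <- function(px, out_size, crop_frac, flip = TRUE) {
  d <- dim(px)
  side <- max(2L, round(crop_frac * min(d[1], d[2])))
  r0 <- sample.int(d[1] - side + 1L, 1) - 1L
  c0 <- sample.int(d[2] - side + 1L, 1) - 1L
  crop <- px[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  if (flip && stats::runif(1) < 0.5) crop <- crop[, rev(seq_len(side)), , drop = FALSE]
  resize_image(crop, out_size, out_size)
}

#' Train an unconditional GAN on one maturation class
#'
#' Alternates one discriminator update (real and generated halves) and one
#' generator update per minibatch, both with Adam. Training images are
#' augmented every epoch with random crop, random horizontal flip and resize
#' to `config$image_size`, then mapped to \[-1, 1\]. The whole run is a
#' deterministic function of `config$seed`.
#'
#' @param images list of `labeled_image`, all of the same class.
#' @param config a [gan_config()].
#' @param verbose print per-epoch losses every `verbose` epochs (0 = silent).
#' @return object of class `gan_bundle`: generator, discriminator, the class
#'   label, the config, and a per-epoch `history` data frame with mean
#'   discriminator and generator losses.
#' @export
train_image_gan <- function(images, config = gan_config(), verbose = 0) {
  if (length(images) < 1) stop("need at least one training image")
  cls <- unique(vapply(images, function(im) im$label, ""))
  if (length(cls) != 1)
    stop("all training images must share one class, got: ",
         paste(cls, collapse = ", "))
  pix <- lapply(images, function(im) im$pixels)
  train_gan_core(pix, cls, config, verbose)
}

# Shared adversarial loop for the image and video GANs. `pix` is a list of
# (H, W, C) arrays in [0, 1] with C == config$out_channels after augmentation.
train_gan_core <- function(pix, cls, config, verbose = 0) {
  with_seed(config$seed, {
    gen <- build_generator(config)
    disc <- build_discriminator(config)
    nn_adam_init(gen$net)
    nn_adam_init(disc$net)
    ema <- config$ema_decay %||% 0
    ema_state <- NULL
    n <- length(pix)
    hist_d <- hist_g <- numeric(config$epochs)
    t_d <- t_g <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      dl <- gl <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        B <- length(idx)
        xr <- array(0, c(config$image_size, config$image_size,
                         config$out_channels, B))
        for (j in seq_len(B))
          xr[, , , j] <- augment_to_size(pix[[idx[j]]], config$image_size,
                                         config$crop_frac,
                                         config$flip %||% TRUE)
        xr <- to_model_space(xr)
        # --- discriminator update ---
        z <- sample_latent(B, config$latent_dim)
        xf <- nn_forward(gen$net, z, training = TRUE)
        lr_real <- nn_forward(disc$net, xr, training = TRUE)
        br <- sigmoid_bce(lr_real, rep(1, B))
        nn_backward(disc$net, br$grad)
        gsave <- nn_collect_grads(disc$net)
        lr_fake <- nn_forward(disc$net, xf, training = TRUE)
        bf <- sigmoid_bce(lr_fake, rep(0, B))
        cur_d_loss <- br$loss + bf$loss
        if (cur_d_loss >= (config$d_loss_floor %||% 0)) {
          nn_backward(disc$net, bf$grad)
          nn_add_grads(disc$net, gsave)
          t_d <- t_d + 1L
          nn_adam_step(disc$net, t_d, config$learning_rate,
                       config$adam_beta1, config$adam_beta2)
        }
        # --- generator update ---
        z <- sample_latent(B, config$latent_dim)
        xf <- nn_forward(gen$net, z, training = TRUE)
        lg <- nn_forward(disc$net, xf, training = TRUE)
        p <- stats::plogis(lg)
        # d/dlogit of -mean(log p) is (p - 1)/B; of mean(log(1 - p)) is -p/B
        gl_grad <- if (config$saturating) -p / B else (p - 1) / B
        dxf <- nn_backward(disc$net, matrix(gl_grad, ncol = 1))
        nn_backward(gen$net, dxf)
        t_g <- t_g + 1L
        nn_adam_step(gen$net, t_g, config$learning_rate,
                     config$adam_beta1, config$adam_beta2)
        if (ema > 0) {
          st <- nn_state(gen$net)
          if (is.null(ema_state)) ema_state <- st
          else for (li in seq_along(st)) for (pn in names(st[[li]]))
            ema_state[[li]][[pn]] <- ema * ema_state[[li]][[pn]] +
              (1 - ema) * st[[li]][[pn]]
        }
        losses <- gan_losses(stats::plogis(lr_real), stats::plogis(lr_fake))
        dl[bi] <- losses$discriminator_loss
        gl[bi] <- gan_losses(0.5, p, saturating = config$saturating)$generator_loss
      }
      hist_d[ep] <- mean(dl)
      hist_g[ep] <- mean(gl)
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("[gan %s] epoch %d/%d  D=%.4f  G=%.4f",
                        cls, ep, config$epochs, hist_d[ep], hist_g[ep]))
    }
    gen_ema <- NULL
    if (!is.null(ema_state)) {
      gen_ema <- build_generator(config)
      nn_load_state(gen_ema$net, ema_state)
    }
    structure(list(generator = gen, generator_ema = gen_ema, class = cls,
                   discriminator = disc, config = config,
                   history = data.frame(epoch = seq_len(config$epochs),
                                        d_loss = hist_d, g_loss = hist_g)),
              class = "gan_bundle")
  })
}

#' @export
print.gan_bundle <- function(x, ...) {
  cat(sprintf("<gan_bundle class=%s  %d epochs  image_size=%d  final D=%.3f G=%.3f>\n",
              x$class, nrow(x$history), x$config$image_size,
              utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1)))
  invisible(x)
}

#' Sample synthetic labeled images from a trained bundle
#'
#' @param bundle a `gan_bundle`.
#' @param n number of images (>= 1).
#' @param seed integer seed for the latent draws.
#' @param use_ema sample from the weight-averaged generator when available.
#' @return list of `labeled_image` with the bundle's class, domain `"seen"`
#'   and provenance `"gan"` (pixels converted back to \[0, 1\] storage space).
#' @export
sample_synthetic_images <- function(bundle, n, seed = 1, use_ema = TRUE) {
  stopifnot(inherits(bundle, "gan_bundle"))
  if (n < 1) stop("n must be >= 1")
  gen <- if (use_ema && !is.null(bundle$generator_ema)) bundle$generator_ema
         else bundle$generator
  imgs <- with_seed(seed, {
    z <- sample_latent(n, bundle$config$latent_dim)
    generate_images(gen, z, training = FALSE)
  })
  lapply(seq_len(n), function(i)
    labeled_image(from_model_space(imgs[, , , i, drop = FALSE][, , , 1]),
                  label = bundle$class, domain = "seen", provenance = "gan"))
}

#' Build the per-class synthetic library
#'
#' Samples `per_class` images from each class bundle (the study default is
#' 320 per class, i.e. 960 in total for three classes).
#'
#' @param bundles named list of `gan_bundle`, one per maturation class.
#' @param per_class images per class (>= 1).
#' @param seed integer seed.
#' @return object of class `synthetic_library` with `images` and
#'   `per_class_count`.
#' @export
synthesize_class_library <- function(bundles, per_class = 320, seed = 1) {
  missing <- setdiff(MATURATION_CLASSES, names(bundles))
  if (length(missing))
    stop("missing bundle for class(es): ", paste(missing, collapse = ", "))
  if (per_class < 1) stop("per_class must be >= 1")
  images <- list()
  for (cls in MATURATION_CLASSES) {
    images <- c(images, sample_synthetic_images(
      bundles[[cls]], per_class, seed = derive_seed(seed, paste0("library_", cls))))
  }
  structure(list(images = images, per_class_count = per_class),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("<synthetic_library %d images (%d per class)>\n",
              length(x$images), x$per_class_count))
  invisible(x)
}

#' Save / load a GAN bundle
#'
#' Writes a directory with the network parameter blobs, a JSON metadata file
#' (class and config) and the training history as CSV.
#'
#' @param bundle a `gan_bundle`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly (`save_gan_bundle`); a `gan_bundle`
#'   (`load_gan_bundle`).
#' @export
save_gan_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(nn_state(bundle$generator$net), file.path(dir, "generator.rds"))
  if (!is.null(bundle$generator_ema))
    saveRDS(nn_state(bundle$generator_ema$net), file.path(dir, "generator_ema.rds"))
  saveRDS(nn_state(bundle$discriminator$net), file.path(dir, "discriminator.rds"))
  jsonlite::write_json(list(class = bundle$class,
                            config = unclass(bundle$config)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_gan_bundle
#' @export
load_gan_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  config <- do.call(gan_config, meta$config)
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  nn_load_state(gen$net, readRDS(file.path(dir, "generator.rds")))
  nn_load_state(disc$net, readRDS(file.path(dir, "discriminator.rds")))
  gen_ema <- NULL
  if (file.exists(file.path(dir, "generator_ema.rds"))) {
    gen_ema <- build_generator(config)
    nn_load_state(gen_ema$net, readRDS(file.path(dir, "generator_ema.rds")))
  }
  structure(list(generator = gen, generator_ema = gen_ema,
                 discriminator = disc, class = meta$class, config = config,
                 history = utils::read.csv(file.path(dir, "history.csv"))),
            class = "gan_bundle")
}
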