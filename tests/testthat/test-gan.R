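# Image GAN: architecture contracts, adversarial losses, training loop.

test_that("config defaults follow the training protocol", {
  cfg <- gan_config()
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(cfg$adam_beta1, 0.5)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$batch_size, 64)
  expect_equal(cfg$epochs, 2000)
  expect_equal(cfg$image_size, 128)
  expect_equal(cfg$latent_dim, 64)
  expect_error(gan_config(image_size = 100), "multiple of 16")
  expect_error(gan_config(learning_rate = 0))
})

test_that("generator maps 64-dim latents through exactly four transposed
           convolutions to a Tanh-bounded image", {
  cfg <- tiny_gan_config()
  set.seed(1)
  gen <- build_generator(cfg)
  expect_equal(gen$n_tconv_layers, 4L)
  z <- matrix(rnorm(3 * 64), 3, 64)
  out <- generate_images(gen, z)
  expect_equal(dim(out), c(32, 32, 3, 3))
  expect_true(all(out >= -1 & out <= 1))
  expect_identical(out, generate_images(gen, z))       # eval-mode determinism
  # a batch of one equals the first batch slice (up to BLAS summation order)
  expect_equal(generate_images(gen, z[1, ]), out[, , , 1, drop = FALSE],
               tolerance = 1e-12)
  expect_error(generate_images(gen, matrix(0, 1, 32)), "length 64")
  # full-size geometry: latent projects to 8x8 and grows 16 -> 32 -> 64 -> 128
  big <- build_generator(gan_config(base_channels = 8))
  zb <- matrix(0, 1, 64)
  expect_equal(dim(generate_images(big, zb)), c(128, 128, 3, 1))
})

test_that("discriminator has four convolution stages and emits per-image
           probabilities strictly inside (0, 1)", {
  cfg <- tiny_gan_config()
  set.seed(1)
  disc <- build_discriminator(cfg)
  expect_equal(disc$n_conv_layers, 4L)
  x <- array(runif(32 * 32 * 3 * 5, -1, 1), c(32, 32, 3, 5))
  p <- discriminate(disc, x)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  expect_length(discriminate(disc, x[, , , 1]), 1)     # single image promoted
  expect_error(discriminate(disc, array(0, c(16, 16, 3, 1))), "expects")
})

test_that("adversarial losses reproduce their closed forms", {
  # indifferent discriminator: D(x) = D(G(z)) = 1/2
  l <- gan_losses(0.5, 0.5)
  expect_equal(l$discriminator_loss, 2 * log(2), tolerance = 1e-6)
  expect_equal(l$generator_loss, log(2), tolerance = 1e-6)
  # perfect discriminator: loss tends to zero with epsilon
  for (eps in c(1e-3, 1e-5)) {
    expect_lt(gan_losses(1 - eps, eps)$discriminator_loss, 3 * eps)
  }
  # saturating form of the generator objective
  expect_equal(gan_losses(0.5, 0.5, saturating = TRUE)$generator_loss,
               log(0.5), tolerance = 1e-6)
  # vector inputs average
  expect_equal(gan_losses(c(0.5, 0.5), c(0.5, 0.5))$discriminator_loss,
               2 * log(2), tolerance = 1e-6)
  expect_error(gan_losses(numeric(0), 0.5), "non-empty")
})

test_that("training keeps one history record per epoch, learns, and is
           seed-reproducible", {
  imgs <- toy_dataset(4, size = 64)[1:8]          # 8 day2/day6 images
  imgs <- lapply(imgs, function(im) { im$domain <- "seen"; im })
  expect_error(train_image_gan(imgs, tiny_gan_config()), "one class")
  day2 <- Filter(function(im) im$label == "day2", toy_dataset(8, size = 64))
  b <- train_image_gan(day2, tiny_gan_config(epochs = 3, seed = 5))
  expect_equal(nrow(b$history), 3)
  expect_true(all(is.finite(b$history$d_loss)))
  expect_true(all(is.finite(b$history$g_loss)))
  b2 <- train_image_gan(day2, tiny_gan_config(epochs = 3, seed = 5))
  # identical draws; numerically equal up to BLAS thread-reduction order
  expect_equal(b$history, b2$history, tolerance = 1e-10)
  expect_equal(cardiogan:::nn_state(b$generator$net),
               cardiogan:::nn_state(b2$generator$net), tolerance = 1e-10)
  expect_error(train_image_gan(list(), tiny_gan_config()), "at least one")
})

test_that("the discriminator wins against a fresh generator on a fixed
           image set (median over 3 seeds)", {
  p <- make_class_presets(0)$day2
  imgs <- lapply(1:8, function(i)
    render_cell_field(p, 64, seed = i, label = "day2"))
  ratio <- sapply(1:3, function(s) {
    b <- train_image_gan(imgs, tiny_gan_config(epochs = 200, seed = s))
    mean(head(b$history$d_loss, 20)) / mean(b$history$d_loss[181:200])
  })
  expect_gt(median(ratio), 1)
})

test_that("synthetic sampling is deterministic, labeled and bounded", {
  day14 <- Filter(function(im) im$label == "day14", toy_dataset(4, size = 64))
  b <- train_image_gan(day14, tiny_gan_config(epochs = 2, seed = 2))
  s <- sample_synthetic_images(b, 5, seed = 7)
  expect_length(s, 5)
  expect_true(all(vapply(s, function(im) im$label == "day14", NA)))
  expect_true(all(vapply(s, function(im) im$provenance == "gan", NA)))
  expect_true(all(vapply(s, function(im)
    all(im$pixels >= 0 & im$pixels <= 1), NA)))
  s2 <- sample_synthetic_images(b, 5, seed = 7)
  expect_identical(s[[3]]$pixels, s2[[3]]$pixels)
  expect_error(sample_synthetic_images(b, 0), "n must be")
})

test_that("the class library is balanced across the three bundles", {
  ds <- toy_dataset(3, size = 64)
  bundles <- lapply(setNames(nm = c("day2", "day6", "day14")), function(cls)
    train_image_gan(Filter(function(im) im$label == cls, ds),
                    tiny_gan_config(epochs = 2, seed = 3)))
  lib <- synthesize_class_library(bundles, per_class = 4, seed = 1)
  expect_length(lib$images, 12)
  tab <- table(vapply(lib$images, function(im) im$label, ""))
  expect_true(all(tab == 4))
  expect_error(synthesize_class_library(bundles[1:2], 4), "missing bundle")
  one <- synthesize_class_library(bundles, per_class = 1, seed = 1)
  expect_length(one$images, 3)
})

test_that("bundles round-trip through their on-disk serialization", {
  day2 <- Filter(function(im) im$label == "day2", toy_dataset(3, size = 64))
  b <- train_image_gan(day2, tiny_gan_config(epochs = 2, seed = 4))
  d <- file.path(tempdir(), "bundle_rt")
  save_gan_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c("generator.rds", "meta.json",
                                             "history.csv")))))
  b2 <- load_gan_bundle(d)
  expect_equal(b2$class, "day2")
  s1 <- sample_synthetic_images(b, 3, seed = 5)
  s2 <- sample_synthetic_images(b2, 3, seed = 5)
  expect_equal(s1[[1]]$pixels, s2[[1]]$pixels, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
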