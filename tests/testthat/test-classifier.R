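# CNN classifier: architecture geometry, augmentation, dataset assembly,
# training and prediction.

test_that("the reference architecture reproduces the printed stage shapes", {
  spec <- classifier_spec()
  expect_equal(spec$activation_shapes[[1]], c(32, 48, 48))
  expect_equal(spec$activation_shapes[[2]], c(16, 24, 24))
  expect_equal(spec$activation_shapes[[3]], c(4, 12, 12))
  expect_equal(spec$flatten_dim, 576)
  set.seed(1)
  m <- build_cnn_classifier(spec)
  x <- to_model_space(array(runif(96 * 96 * 3), c(96, 96, 3, 1)))
  shapes <- list()
  for (l in m$net) {
    x <- cardiogan:::layer_forward(l, x, training = FALSE)
    if (l$type == "maxpool") shapes[[length(shapes) + 1]] <- dim(x)
  }
  expect_equal(shapes[[1]], c(48, 48, 32, 1))
  expect_equal(shapes[[2]], c(24, 24, 16, 1))
  expect_equal(shapes[[3]], c(12, 12, 4, 1))
  expect_equal(dim(x), c(1, 3))                     # final logits
})

test_that("predicted probability vectors live on the 3-simplex and are
           deterministic", {
  set.seed(2)
  m <- build_cnn_classifier(classifier_spec(input_size = 24))
  imgs <- toy_dataset(2, size = 32)
  p <- predict_proba(m, imgs)
  expect_equal(dim(p), c(6L, 3L))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p, predict_proba(m, imgs))
  # duplicated inputs give identical rows
  p2 <- predict_proba(m, c(imgs[1], imgs[1]))
  expect_equal(p2[1, ], p2[2, ])
})

test_that("random_crop_flip returns a contiguous sub-window and never touches
           channels", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  crop <- random_crop_flip(img, 96, seed = 4)
  expect_equal(dim(crop), c(96, 96, 3))
  expect_identical(crop, random_crop_flip(img, 96, seed = 4))
  # every cropped pixel occurs in the input (per channel, as a set)
  for (ch in 1:3)
    expect_true(all(crop[, , ch] %in% img[, , ch]))
  # a constant image stays constant under any crop/flip
  flat <- array(0.4, c(128, 128, 3))
  expect_true(all(random_crop_flip(flat, 96, seed = 1) == 0.4))
  expect_error(random_crop_flip(img[1:64, 1:64, , drop = FALSE], 96), "smaller")
})

test_that("training-set assembly reproduces the three-dataset design counts", {
  mk <- function(n, cls, prov = "phantom")
    lapply(seq_len(n), function(i)
      labeled_image(array(0.5, c(64, 64, 3)), cls, provenance = prov))
  # the study counts: 691 real + 960 synthetic = 1651 mixed,
  # 691 real + 960 extra real = 1651 large-real
  small <- c(mk(229, "day2"), mk(227, "day6"), mk(235, "day14"))
  extra <- c(mk(320, "day2"), mk(320, "day6"), mk(320, "day14"))
  syn <- c(mk(320, "day2", "gan"), mk(320, "day6", "gan"), mk(320, "day14", "gan"))
  tri <- assemble_training_sets(small, extra, syn)
  expect_length(tri$small_real, 691)
  expect_length(tri$large_real, 1651)
  expect_length(tri$mixed, 1651)
  expect_equal(length(tri$mixed), length(tri$small_real) + length(syn))
  # empty synthetic: mixed collapses to small_real
  tri0 <- assemble_training_sets(small[1:10], list(), list())
  expect_equal(length(tri0$mixed), 10)
  # label mismatch between sources errors
  expect_error(assemble_training_sets(mk(3, "day2"), mk(2, "day6")),
               "absent from small_real")
})

test_that("count conservation |mixed| = |small| + |synthetic| holds across
           random assembly sizes", {
  mk <- function(n, cls) lapply(seq_len(n), function(i)
    labeled_image(array(0.1, c(64, 64, 3)), cls))
  set.seed(11)
  for (rep in 1:5) {
    ns <- sample(1:40, 3)
    small <- c(mk(ns[1], "day2"), mk(ns[2], "day6"), mk(ns[3], "day14"))
    ks <- sample(0:30, 3)
    syn <- c(mk(ks[1], "day2"), mk(ks[2], "day6"), mk(ks[3], "day14"))
    tri <- assemble_training_sets(small, list(), syn)
    expect_length(tri$mixed, sum(ns) + sum(ks))
    expect_gte(length(tri$large_real), length(tri$small_real))
  }
})

test_that("training separates constant-intensity classes to perfect accuracy
           within 50 epochs", {
  ds <- toy_dataset(10, size = 64)
  cfg <- classifier_config(epochs = 50, learning_rate = 1e-3, seed = 3)
  m <- train_classifier(ds, cfg, spec = classifier_spec(input_size = 24))
  expect_equal(nrow(m$history), 50)
  expect_true(any(m$history$accuracy == 1))
  truth <- vapply(ds, function(im) im$label, "")
  expect_equal(mean(predict_class(m, ds) == truth), 1)
  expect_error(train_classifier(ds[1:10], cfg), "two classes")
})

test_that("config defaults follow the classifier training protocol", {
  cfg <- classifier_config()
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$adam_beta1, 0.9)
  expect_equal(cfg$adam_beta2, 0.999)
  expect_equal(cfg$batch_size, 64)
  expect_equal(cfg$epochs, 1000)
})

test_that("flattened feature dimensions match each architecture", {
  expect_equal(flatten_feature_dim("proposed"), 576L)     # 4 * 12 * 12
  expect_equal(flatten_feature_dim("fc_only"), 27648L)    # 3 * 96 * 96
  expect_equal(flatten_feature_dim("small_cnn"), 256L)    # 4 * 8 * 8
  expect_equal(flatten_feature_dim("disc_like"), 1024L)   # 4 * 16 * 16
  expect_error(flatten_feature_dim("resnet"))
})

test_that("ablation architectures have their stated geometry and emit
           3-class simplex vectors", {
  set.seed(5)
  # small_cnn at the reference size: activations (16,32,32) then (4,8,8)
  sc <- build_ablation_model("small_cnn")
  x <- array(runif(96 * 96 * 3, -1, 1), c(96, 96, 3, 1))
  shapes <- list()
  for (l in sc$net) {
    x <- cardiogan:::layer_forward(l, x, training = FALSE)
    if (l$type == "maxpool") shapes[[length(shapes) + 1]] <- dim(x)
  }
  expect_equal(shapes[[1]], c(32, 32, 16, 1))
  expect_equal(shapes[[2]], c(8, 8, 4, 1))
  expect_equal(sc$flatten_dim, 256L)
  # disc_like consumes the full 128-px image
  dl <- build_ablation_model("disc_like")
  expect_equal(dl$input_size, 128L)
  expect_equal(dl$flatten_dim, 1024L)
  # all three (fc_only scaled down to keep the test light) emit simplexes
  imgs <- toy_dataset(1, size = 64)
  for (m in list(build_ablation_model("fc_only", input_size = 24),
                 build_ablation_model("small_cnn", input_size = 24),
                 dl)) {
    p <- predict_proba(m, imgs)
    expect_equal(dim(p), c(3L, 3L))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  }
  expect_error(build_ablation_model("vgg"))
})
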