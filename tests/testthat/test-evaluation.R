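# Evaluation: confusion accounting, domain reports, PCA fidelity, baselines,
# feature maps.

oracle_model <- function(images) vapply(images, function(im) im$label, "")

test_that("confusion matrices count every sample exactly once", {
  cm <- confusion(c("day2", "day6", "day14"), c("day2", "day6", "day14"))
  expect_equal(unname(diag(cm)), rep(1L, 3))
  expect_equal(sum(cm), 3)
  cm2 <- confusion(c("day2", "day2"), c("day6", "day6"))
  expect_equal(unname(cm2["day2", "day6"]), 2L)
  expect_equal(sum(diag(cm2)), 0L)
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(5:50, 1)
    tr <- sample(c("day2", "day6", "day14"), n, replace = TRUE)
    pr <- sample(c("day2", "day6", "day14"), n, replace = TRUE)
    cm <- confusion(tr, pr)
    expect_equal(sum(cm), n)
    expect_equal(unname(rowSums(cm)),
                 as.numeric(table(factor(tr, levels = c("day2", "day6", "day14")))))
  }
  expect_error(confusion("day2", "day9"), "unknown label")
  expect_error(confusion(c("day2", "day6"), "day2"), "equal length")
})

test_that("domain reports pool accuracies sample-weighted", {
  seen <- c(lapply(1:5, function(i) const_image(0.2, "day2")),
            lapply(1:5, function(i) const_image(0.8, "day14")))
  unseen <- lapply(1:10, function(i)
    const_image(0.5, "day6", domain = "unseen"))
  r <- evaluate_domains(oracle_model, seen, unseen)
  expect_equal(r$seen_accuracy, 1)
  expect_equal(r$unseen_accuracy, 1)
  expect_equal(r$pooled_accuracy, 1)
  # constant-class predictor on a balanced 3-class set scores 1/3
  bal <- toy_dataset(4, size = 64)
  r2 <- evaluate_domains(function(im) rep("day2", length(im)), bal, bal)
  expect_equal(r2$seen_accuracy, 1 / 3, tolerance = 1e-9)
  # seen 10/10 and unseen 5/10 correct pools to 0.75
  half <- function(images) {
    out <- oracle_model(images)
    if (images[[1]]$domain == "unseen")
      out[1:5] <- c("day6", "day6", "day6", "day2", "day2")[1:5]
    out
  }
  seen10 <- lapply(1:10, function(i) const_image(0.2, "day2"))
  unseen10 <- lapply(1:10, function(i) const_image(0.2, "day14", domain = "unseen"))
  r3 <- evaluate_domains(half, seen10, unseen10)
  expect_equal(r3$pooled_accuracy, 0.75)
  expect_equal(r3$macro_accuracy, 0.75)
  expect_equal(sum(r3$confusion_seen) + sum(r3$confusion_unseen), 20)
  expect_error(evaluate_domains(oracle_model, list(), unseen10), "non-empty")
})

test_that("pca_embed agrees with a brute-force covariance eigendecomposition
           up to component sign", {
  set.seed(8)
  x <- matrix(rnorm(20 * 16), 20, 16)        # 20 random 16-pixel images
  r <- pca_embed(x, n_components = 3)
  # oracle: eigendecomposition of the sample covariance
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  for (k in 1:3) {
    v <- ev$vectors[, k]
    w <- r$loadings[, k]
    expect_lt(min(max(abs(w - v)), max(abs(w + v))), 1e-8)
    s <- xc %*% v
    expect_lt(min(max(abs(r$scores[, k] - s)), max(abs(r$scores[, k] + s))), 1e-8)
  }
  expect_equal(colMeans(r$scores), rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(r$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(r$explained_variance) <= 1e-12))
  expect_lte(sum(r$explained_variance), 1 + 1e-12)
  expect_error(pca_embed(x[1:3, ], n_components = 3), "smaller")
})

test_that("pca_embed featurizes image lists and returns 2-D scores with
           group tags", {
  ds <- make_image_dataset(make_class_presets(0), 5, unseen_shift = 1,
                           seed = 2, size = 64)
  r <- pca_embed(ds$images, n_components = 2)
  expect_equal(ncol(r$scores), 2)
  expect_equal(nrow(r$scores), 30)
  expect_length(r$groups, 30)
  expect_true(any(grepl("phantom/unseen/day14", r$groups)))
})

test_that("baselines report 4 methods x cycles and beat chance on separable
           phantoms", {
  p <- make_class_presets(0)
  tr <- make_image_dataset(p, 12, seed = 1, size = 64, domains = "seen")$images
  te <- make_image_dataset(p, 6, unseen_shift = 0.5, seed = 2, size = 64)
  seen <- Filter(function(im) im$domain == "seen", te$images)
  unseen <- Filter(function(im) im$domain == "unseen", te$images)
  # coarse 8x8 pixel-block features give every method (including Gaussian
  # naive Bayes, which drowns in 1024 per-pixel marginals) an informative,
  # identical representation
  b <- run_baselines(tr, seen, unseen, cycles = 3, seed = 5, feature_size = 8)
  expect_equal(nrow(b$results), 4 * 3)
  expect_setequal(unique(b$results$method),
                  c("SVM", "RandomForest", "KNN", "NaiveBayes"))
  expect_true(all(b$results$seen_accuracy >= 0 & b$results$seen_accuracy <= 1))
  med <- aggregate(seen_accuracy ~ method, b$results, median)
  expect_true(all(med$seen_accuracy > 1 / 3))
  expect_equal(formals(run_baselines)$cycles, 10)   # protocol default
  expect_error(run_baselines(tr, seen, unseen, cycles = 0), "cycles")
})

test_that("feature maps expose four normalized 12x12 channels of the last
           convolution stage", {
  set.seed(3)
  m <- build_cnn_classifier(classifier_spec())
  img <- render_cell_field(make_class_presets(0.5)$day14, 128, seed = 1,
                           label = "day14")
  fm <- feature_maps(m, img)
  expect_length(fm, 4)
  for (f in fm) {
    expect_equal(dim(f), c(12, 12))
    expect_gte(min(f), 0)
    expect_lte(max(f), 1)
  }
  fc <- build_ablation_model("fc_only", input_size = 24)
  expect_error(feature_maps(fc, img), "no convolution")
})

test_that("training on more real images never lowers the median pooled
           accuracy relative to the small real set (5 seeds)", {
  presets <- make_class_presets(0.7)
  pooled <- sapply(1:5, function(s) {
    small <- make_image_dataset(presets, 25, unseen_shift = 1,
                                seed = derive_seed(s, "lr_small"),
                                size = 64, domains = "seen")$images
    extra <- make_image_dataset(presets, 50, unseen_shift = 1,
                                seed = derive_seed(s, "lr_extra"),
                                size = 64, domains = "seen")$images
    te <- make_image_dataset(presets, 15, unseen_shift = 1,
                             seed = derive_seed(s, "lr_test"), size = 64)$images
    seen <- Filter(function(im) im$domain == "seen", te)
    unseen <- Filter(function(im) im$domain == "unseen", te)
    tri <- assemble_training_sets(small, extra, list())
    spec <- classifier_spec(input_size = 24)
    accs <- sapply(c("small_real", "large_real"), function(nm) {
      cfg <- classifier_config(epochs = 15, learning_rate = 1e-3,
                               seed = derive_seed(s, paste0("lr_", nm)))
      evaluate_domains(train_classifier(tri[[nm]], cfg, spec = spec),
                       seen, unseen)$pooled_accuracy
    })
    accs
  })
  expect_gte(median(pooled["large_real", ]), median(pooled["small_real", ]))
})
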