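# Evaluation: seen/unseen domain accuracy reports, confusion matrices, PCA
# distribution fidelity, conventional ML baselines, feature maps.

#' Confusion matrix (true class by row, predicted by column)
#'
#' @param true_labels,predicted_labels equal-length character vectors with
#'   values among the maturation classes.
#' @param classes class levels (default day2/day6/day14).
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      classes = MATURATION_CLASSES) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(true_labels, levels = classes),
             factor(predicted_labels, levels = classes))
  structure(unclass(m), dimnames = list(true = classes, predicted = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix  n=%d  accuracy=%.3f>\n", sum(x),
              sum(diag(x)) / max(1, sum(x))))
  print(unclass(x))
  invisible(x)
}

accuracy_of <- function(cm) sum(diag(cm)) / max(1, sum(cm))

# Resolve a "model" argument: a trained cnn_classifier or any function
# mapping a list of labeled_image to a character vector of predicted labels.
predict_labels <- function(model, images) {
  if (is.function(model)) model(images)
  else predict_class(model, images)
}

#' Seen/unseen domain evaluation report
#'
#' Evaluates a classifier on a seen-domain and an unseen-domain test set and
#' reports per-domain accuracy with confusion matrices. Two "total" accuracy
#' conventions are reported: `pooled_accuracy` weights every test sample
#' equally, `macro_accuracy` is the plain mean of the two domain accuracies.
#'
#' @param model a trained `cnn_classifier`, or a function mapping a list of
#'   `labeled_image` to predicted labels.
#' @param seen_test,unseen_test non-empty lists of `labeled_image`.
#' @return object of class `domain_report`.
#' @export
evaluate_domains <- function(model, seen_test, unseen_test) {
  if (length(seen_test) == 0 || length(unseen_test) == 0)
    stop("both test sets must be non-empty")
  truth_s <- vapply(seen_test, function(im) im$label, "")
  truth_u <- vapply(unseen_test, function(im) im$label, "")
  pred_s <- predict_labels(model, seen_test)
  pred_u <- predict_labels(model, unseen_test)
  cm_s <- confusion(truth_s, pred_s)
  cm_u <- confusion(truth_u, pred_u)
  n_s <- length(seen_test); n_u <- length(unseen_test)
  acc_s <- accuracy_of(cm_s); acc_u <- accuracy_of(cm_u)
  structure(list(
    seen_accuracy = acc_s, unseen_accuracy = acc_u,
    pooled_accuracy = (sum(diag(cm_s)) + sum(diag(cm_u))) / (n_s + n_u),
    macro_accuracy = (acc_s + acc_u) / 2,
    confusion_seen = cm_s, confusion_unseen = cm_u,
    n_seen = n_s, n_unseen = n_u),
    class = "domain_report")
}

#' @export
print.domain_report <- function(x, ...) {
  cat(sprintf(paste0("<domain_report  seen=%.3f (n=%d)  unseen=%.3f (n=%d)",
                     "  pooled=%.3f  macro=%.3f>\n"),
              x$seen_accuracy, x$n_seen, x$unseen_accuracy, x$n_unseen,
              x$pooled_accuracy, x$macro_accuracy))
  invisible(x)
}

#' Shared baseline/PCA featurization: 32 x 32 grayscale, flattened
#'
#' @param images list of `labeled_image`.
#' @param size resize target (default 32).
#' @return (n, size^2) numeric matrix.
#' @export
featurize_images <- function(images, size = 32) {
  n <- length(images)
  out <- matrix(0, n, size * size)
  for (i in seq_len(n)) {
    g <- resize_image(images[[i]]$pixels, size, size)
    out[i, ] <- as.numeric((g[, , 1] + g[, , 2] + g[, , 3]) / 3)
  }
  out
}

#' PCA embedding of image sets
#'
#' Featurizes images (32 x 32 grayscale flatten, as for the baselines),
#' mean-centers, and projects onto the leading principal components via
#' [stats::prcomp()]. Used to compare the feature distributions of real-seen,
#' GAN-synthetic and real-unseen images.
#'
#' @param images list of `labeled_image`, or a plain (n, p) numeric feature
#'   matrix (used as-is).
#' @param n_components number of components (default 2, the usual 2-D
#'   cluster view); must be < number of samples.
#' @param groups optional character vector of group tags (e.g.
#'   "real-seen/day2") stored alongside the scores.
#' @return object of class `pca_result` with orthonormal `loadings`,
#'   mean-centered `scores`, non-increasing `explained_variance` fractions,
#'   and `groups`.
#' @export
pca_embed <- function(images, n_components = 2, groups = NULL) {
  x <- if (is.matrix(images)) images else featurize_images(images)
  if (n_components >= nrow(x))
    stop("n_components must be smaller than the number of samples")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- p$sdev^2 / sum(p$sdev^2)
  if (is.null(groups) && !is.matrix(images))
    groups <- vapply(images, function(im)
      paste(im$provenance, im$domain, im$label, sep = "/"), "")
  structure(list(scores = p$x[, seq_len(n_components), drop = FALSE],
                 loadings = p$rotation[, seq_len(n_components), drop = FALSE],
                 explained_variance = ev[seq_len(n_components)],
                 groups = groups),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result  %d samples x %d components  var=%s>\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Conventional machine-learning baselines
#'
#' Fits SVM (RBF kernel), random forest, k-nearest neighbors (k = 5) and
#' Gaussian naive Bayes on the shared 32 x 32 grayscale pixel features and
#' reports seen/unseen/pooled accuracy per method and cycle. Each cycle
#' re-seeds the RNG and refits on a stratified 90% subsample of the training
#' set, so deterministic methods also show cycle-to-cycle spread.
#'
#' @param train_set list of `labeled_image`.
#' @param seen_test,unseen_test non-empty lists of `labeled_image`.
#' @param cycles number of repeat cycles (default 10).
#' @param seed integer seed.
#' @param subsample per-cycle stratified training fraction.
#' @param feature_size grayscale resize target for the shared featurization
#'   (default 32, i.e. 1024 pixel features; all four methods always see
#'   identical features).
#' @return object of class `baseline_report`: `results` (method x cycle data
#'   frame) and `summary` (mean and SD per method).
#' @export
run_baselines <- function(train_set, seen_test, unseen_test, cycles = 10,
                          seed = 1, subsample = 0.9, feature_size = 32) {
  if (cycles < 1) stop("cycles must be >= 1")
  if (!length(train_set) || !length(seen_test) || !length(unseen_test))
    stop("all datasets must be non-empty")
  xtr <- featurize_images(train_set, feature_size)
  ytr <- image_labels(train_set)
  xs <- featurize_images(seen_test, feature_size)
  ys <- image_labels(seen_test)
  xu <- featurize_images(unseen_test, feature_size)
  yu <- image_labels(unseen_test)
  methods <- c("SVM", "RandomForest", "KNN", "NaiveBayes")
  rows <- list()
  for (cy in seq_len(cycles)) {
    res <- with_seed(derive_seed(seed, sprintf("baseline_cycle_%d", cy)), {
      idx <- unlist(lapply(split(seq_along(ytr), ytr), function(ii)
        sample(ii, max(1, round(subsample * length(ii))))), use.names = FALSE)
      xc <- xtr[idx, , drop = FALSE]
      # tiny jitter guards Gaussian class-conditional variances against
      # degenerate constant features
      xcj <- xc + matrix(stats::rnorm(length(xc), 0, 1e-6), nrow(xc))
      yc <- droplevels(ytr[idx])
      fit_pred <- list(
        SVM = {
          m <- e1071::svm(xc, yc)
          list(s = stats::predict(m, xs), u = stats::predict(m, xu))
        },
        RandomForest = {
          m <- randomForest::randomForest(xc, yc, ntree = 200)
          list(s = stats::predict(m, xs), u = stats::predict(m, xu))
        },
        KNN = list(s = class::knn(xc, xs, yc, k = 5),
                   u = class::knn(xc, xu, yc, k = 5)),
        NaiveBayes = {
          m <- e1071::naiveBayes(xcj, yc)
          list(s = nb_predict_log(m, xs), u = nb_predict_log(m, xu))
        })
      fit_pred
    })
    for (m in methods) {
      ps <- as.character(res[[m]]$s); pu <- as.character(res[[m]]$u)
      cs <- sum(ps == as.character(ys)); cu <- sum(pu == as.character(yu))
      rows[[length(rows) + 1]] <- data.frame(
        method = m, cycle = cy,
        seen_accuracy = cs / length(ys),
        unseen_accuracy = cu / length(yu),
        pooled_accuracy = (cs + cu) / (length(ys) + length(yu)))
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$method), function(d)
    data.frame(method = d$method[1],
               seen_mean = mean(d$seen_accuracy), seen_sd = stats::sd(d$seen_accuracy),
               unseen_mean = mean(d$unseen_accuracy), unseen_sd = stats::sd(d$unseen_accuracy),
               pooled_mean = mean(d$pooled_accuracy), pooled_sd = stats::sd(d$pooled_accuracy))))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, cycles = cycles),
            class = "baseline_report")
}

# Log-space prediction from a fitted e1071::naiveBayes model. With ~1000
# pixel features the product of Gaussian densities underflows double
# precision inside predict(), collapsing every posterior to zero; summing
# log densities is exact arithmetic on the same fitted model.
nb_predict_log <- function(m, x) {
  classes <- names(m$apriori)
  ll <- matrix(log(as.numeric(m$apriori) / sum(m$apriori)),
               nrow(x), length(classes), byrow = TRUE)
  for (j in seq_along(m$tables)) {
    tab <- m$tables[[j]]
    for (k in seq_along(classes)) {
      ll[, k] <- ll[, k] + stats::dnorm(x[, j], tab[k, 1],
                                        max(tab[k, 2], 1e-4), log = TRUE)
    }
  }
  factor(classes[max.col(ll, ties.method = "first")], levels = classes)
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("<baseline_report  %d cycles>\n", x$cycles))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Feature maps of the last convolution stage
#'
#' Runs an image through the classifier up to (and including) the pooling
#' stage that follows the last convolution layer and returns each output
#' channel as a min-max normalized map in \[0, 1\] (brighter = stronger
#' activation). For the reference architecture this yields four 12 x 12 maps.
#'
#' @param model a trained convolutional `cnn_classifier` (the fully connected
#'   ablation has no convolution stage and is rejected).
#' @param image a `labeled_image` or (H, W, 3) storage-space array.
#' @return list of per-channel matrices.
#' @export
feature_maps <- function(model, image) {
  stopifnot(inherits(model, "cnn_classifier"))
  types <- vapply(model$net, function(l) l$type, "")
  if (!any(types == "conv"))
    stop("model '", model$name, "' has no convolution layers")
  last_conv <- max(which(types == "conv"))
  stop_at <- last_conv
  while (stop_at < length(types) &&
         types[stop_at + 1] %in% c("relu", "lrelu", "bn2d", "maxpool"))
    stop_at <- stop_at + 1
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  x <- resize_image(px, model$source_size)
  x <- center_crop(x, model$input_size)
  x <- to_model_space(x)
  dim(x) <- c(dim(x), 1)
  for (i in seq_len(stop_at)) x <- layer_forward(model$net[[i]], x, training = FALSE)
  nch <- dim(x)[3]
  lapply(seq_len(nch), function(c) {
    m <- x[, , c, 1]
    rng <- range(m)
    if (diff(rng) < 1e-12) matrix(0, nrow(m), ncol(m))
    else (m - rng[1]) / diff(rng)
  })
}
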