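# The scaled augmentation experiment: does mixing GAN-synthetic images into
# classifier training improve unseen-domain accuracy?
#
# The full-resolution protocol (128-px GAN, 96-px classifier crops, hundreds
# of epochs) is far beyond a desk-scale CPU budget, so the experiment runs a
# resolution-reduced replica of the pipeline: phantoms rendered at 96 px,
# GANs and classifiers at 32-px images (24-px crops), slimmed channel widths,
# and epoch counts in the tens. The study conditions themselves (difficulty
# 0.7, unseen shift of 1 SD, 60 real and 100 synthetic images per class,
# classifier epochs <= 150) are fixed; only the resolution and network width
# are scaled.

#' Scaled augmentation-benefit experiment
#'
#' Mirrors the single-dataset study design: one fixed seen-domain real
#' training set (`n_train_per_class` per class) and one GAN per class
#' trained on it, exactly once. Each replicate seed then draws fresh seen
#' and unseen test sets, re-samples `n_synth_per_class` synthetic images per
#' class from the trained generators, and re-trains the classifier (new
#' initialization and batch order) on the small-real set and on the mixed
#' (real + synthetic) set — optionally also on a large-real set with
#' `n_extra_per_class` additional real images — evaluating each model on
#' both domains.
#'
#' @param seed global seed; replicate seeds are derived from it.
#' @param n_seeds number of replicates (default 5).
#' @param difficulty phantom class-overlap difficulty.
#' @param unseen_shift unseen-domain shift in parameter SDs.
#' @param n_train_per_class,n_synth_per_class,n_test_per_class per-class
#'   counts for the real training set, synthetic library and each test set.
#' @param include_large also train on the large-real set.
#' @param n_extra_per_class extra real images per class for the large-real
#'   set.
#' @param render_size phantom render size (px).
#' @param image_size GAN output / classifier source size (px).
#' @param gan_epochs,gan_base,gan_batch,gan_lr,gan_floor GAN training
#'   epochs, base channel width, batch size, learning rate and
#'   discriminator-loss floor for the scaled runs.
#' @param clf_epochs classifier epochs (must be <= 150 to stay within the
#'   study protocol).
#' @param clf_lr classifier learning rate.
#' @param verbose print per-replicate progress.
#' @return object of class `augmentation_experiment`: `per_seed` data frame
#'   (one row per replicate and training set, with seen/unseen/pooled
#'   accuracy), `medians` (across-replicate median accuracies including the
#'   per-replicate unseen-accuracy gain of mixed over small-real training),
#'   the trained `bundles`, and `last`, the final replicate's models,
#'   reports, synthetic library and datasets (for figures).
#' @export
augmentation_experiment <- function(seed = 1, n_seeds = 5, difficulty = 0.7,
                                    unseen_shift = 1, n_train_per_class = 60,
                                    n_synth_per_class = 100,
                                    n_test_per_class = 40,
                                    include_large = FALSE,
                                    n_extra_per_class = 100,
                                    render_size = 96, image_size = 32,
                                    gan_epochs = 600, gan_base = 16,
                                    gan_batch = 30, gan_lr = 1e-3,
                                    gan_floor = 0.3, clf_epochs = 20,
                                    clf_lr = 1e-3, verbose = FALSE) {
  stopifnot(clf_epochs <= 150)
  presets <- make_class_presets(difficulty)
  crop <- round(image_size * 3 / 4)
  spec <- classifier_spec(input_size = crop)
  train_seen <- make_image_dataset(presets, n_train_per_class, unseen_shift,
                                   seed = derive_seed(seed, "phantom"),
                                   size = render_size, domains = "seen")$images
  if (verbose) message("[experiment] training per-class GANs")
  bundles <- list()
  for (cls in MATURATION_CLASSES) {
    cfg <- gan_config(image_size = image_size, base_channels = gan_base,
                      batch_size = gan_batch, epochs = gan_epochs,
                      learning_rate = gan_lr, d_loss_floor = gan_floor,
                      seed = derive_seed(seed, paste0("gan_", cls)))
    bundles[[cls]] <- train_image_gan(
      Filter(function(im) im$label == cls, train_seen), cfg)
  }
  rows <- list()
  last <- NULL
  for (r in seq_len(n_seeds)) {
    rs <- derive_seed(seed, sprintf("experiment_rep_%d", r))
    if (verbose) message(sprintf("[experiment] replicate %d/%d", r, n_seeds))
    tests <- make_image_dataset(presets, n_test_per_class, unseen_shift,
                                seed = derive_seed(rs, "phantom_test"),
                                size = render_size)$images
    seen_test <- Filter(function(im) im$domain == "seen", tests)
    unseen_test <- Filter(function(im) im$domain == "unseen", tests)
    lib <- synthesize_class_library(bundles, n_synth_per_class,
                                    seed = derive_seed(rs, "library"))
    extra <- if (include_large)
      make_image_dataset(presets, n_extra_per_class, unseen_shift,
                         seed = derive_seed(rs, "phantom_extra"),
                         size = render_size, domains = "seen")$images
    else list()
    triplet <- assemble_training_sets(train_seen, extra, lib)
    sets <- c("small_real", "mixed", if (include_large) "large_real")
    models <- list()
    reports <- list()
    for (nm in sets) {
      cfg <- classifier_config(learning_rate = clf_lr, epochs = clf_epochs,
                               seed = derive_seed(rs, paste0("clf_", nm)))
      m <- train_classifier(triplet[[nm]], cfg, spec = spec)
      rep <- evaluate_domains(m, seen_test, unseen_test)
      models[[nm]] <- m
      reports[[nm]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, train_set = nm, n_train = length(triplet[[nm]]),
        seen_accuracy = rep$seen_accuracy,
        unseen_accuracy = rep$unseen_accuracy,
        pooled_accuracy = rep$pooled_accuracy)
      if (verbose)
        message(sprintf("  %-10s seen=%.3f unseen=%.3f", nm,
                        rep$seen_accuracy, rep$unseen_accuracy))
    }
    last <- list(models = models, reports = reports, library = lib,
                 triplet = triplet, seen_test = seen_test,
                 unseen_test = unseen_test)
  }
  per_seed <- do.call(rbind, rows)
  med <- function(set, col) stats::median(per_seed[per_seed$train_set == set, col])
  medians <- list(
    seen_small = med("small_real", "seen_accuracy"),
    unseen_small = med("small_real", "unseen_accuracy"),
    seen_mixed = med("mixed", "seen_accuracy"),
    unseen_mixed = med("mixed", "unseen_accuracy"))
  if (include_large) {
    medians$seen_large <- med("large_real", "seen_accuracy")
    medians$unseen_large <- med("large_real", "unseen_accuracy")
    medians$pooled_large <- med("large_real", "pooled_accuracy")
    medians$pooled_small <- med("small_real", "pooled_accuracy")
  }
  diffs <- merge(
    per_seed[per_seed$train_set == "mixed", c("replicate", "unseen_accuracy")],
    per_seed[per_seed$train_set == "small_real", c("replicate", "unseen_accuracy")],
    by = "replicate", suffixes = c("_mixed", "_small"))
  medians$unseen_gain <- stats::median(
    diffs$unseen_accuracy_mixed - diffs$unseen_accuracy_small)
  structure(list(per_seed = per_seed, medians = medians, last = last,
                 bundles = bundles, train_seen = train_seen,
                 params = list(seed = seed, n_seeds = n_seeds,
                               difficulty = difficulty,
                               unseen_shift = unseen_shift,
                               n_train_per_class = n_train_per_class,
                               n_synth_per_class = n_synth_per_class,
                               image_size = image_size,
                               clf_epochs = clf_epochs)),
            class = "augmentation_experiment")
}

#' @export
print.augmentation_experiment <- function(x, ...) {
  m <- x$medians
  cat("<augmentation_experiment>\n")
  cat(sprintf("  median seen   small=%.3f  mixed=%.3f\n", m$seen_small, m$seen_mixed))
  cat(sprintf("  median unseen small=%.3f  mixed=%.3f  (gain %.3f)\n",
              m$unseen_small, m$unseen_mixed, m$unseen_gain))
  invisible(x)
}
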