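# Workbench: dataset I/O, experiment configuration, seeding, and the
# deterministic pipeline runner.

PIPELINE_STAGES <- c("phantom", "phantom_extra", "phantom_test",
                     "gan_day2", "gan_day6", "gan_day14", "video_gan",
                     "library", "classifier_small", "classifier_large",
                     "classifier_mixed", "evaluation", "baselines")

#' Derive the per-stage seeds of a pipeline run
#'
#' Sets the session RNG to `seed` and returns the named list of seeds each
#' pipeline stage draws from (see [derive_seed()]); distinct stages get
#' distinct streams, and the same global seed always yields the same list.
#'
#' @param seed non-negative integer global seed.
#' @return named list of integer stage seeds.
#' @export
set_global_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  set.seed(seed)
  stats::setNames(lapply(PIPELINE_STAGES, function(s) derive_seed(seed, s)),
                  PIPELINE_STAGES)
}

#' Write a labeled image dataset as PNG files plus a manifest
#'
#' Images are quantized to 8-bit RGB PNG; the manifest CSV has columns
#' `filename, label, domain, provenance, seed`.
#'
#' @param images list of `labeled_image`, a `phantom_image_set`, or a
#'   `synthetic_library`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param seed seed recorded in the manifest (the generating seed if the
#'   input is a `phantom_image_set`).
#' @return path of the manifest file, invisibly.
#' @export
write_image_dataset <- function(images, dir, prefix = "img", seed = NA) {
  if (inherits(images, "phantom_image_set")) {
    if (is.na(seed)) seed <- images$seed
    images <- images$images
  }
  if (inherits(images, "synthetic_library")) images <- images$images
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    fn <- sprintf("%s_%05d.png", prefix, i)
    png::writePNG(round(im$pixels * 255) / 255, file.path(dir, fn))
    rows[[i]] <- data.frame(filename = fn, label = im$label,
                            domain = im$domain, provenance = im$provenance,
                            seed = seed)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a labeled image dataset from a manifest
#'
#' @param manifest_path path to a manifest CSV written by
#'   [write_image_dataset()]; image paths are resolved relative to it.
#' @return list of `labeled_image` (empty, with a warning, for an empty
#'   manifest).
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) {
    warning("manifest is empty: ", manifest_path)
    return(list())
  }
  need <- c("filename", "label", "domain", "provenance")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(man$label), MATURATION_CLASSES)
  if (length(bad))
    stop("manifest contains unknown label(s): ", paste(bad, collapse = ", "))
  root <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(root, man$filename[i])
    if (!file.exists(path))
      stop(sprintf("manifest row %d: file not found: %s", i, man$filename[i]))
    px <- png::readPNG(path)
    if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
    if (dim(px)[3] > 3) px <- px[, , 1:3]
    labeled_image(px, label = man$label[i], domain = man$domain[i],
                  provenance = man$provenance[i])
  })
}

#' Experiment configuration
#'
#' Bundles every knob of the full pipeline. Defaults mirror the reference
#' protocol (320 synthetic images per class, 10 baseline cycles, 128-px GAN,
#' 96-px classifier crop); the `n_*` counts and epoch numbers are what one
#' scales down for desk-size runs.
#'
#' @param difficulty phantom class-overlap difficulty in \[0, 1\].
#' @param unseen_shift unseen-domain parameter shift (SD units).
#' @param n_train_per_class,n_extra_per_class,n_test_per_class phantom image
#'   counts per class for the GAN-training set, the extra-real set and each
#'   test set.
#' @param render_size phantom field render size in px.
#' @param gan a [gan_config()].
#' @param classifier a [classifier_config()].
#' @param classifier_input classifier crop size (see [classifier_spec()]).
#' @param synthetic_per_class GAN samples per class for the mixed set.
#' @param cycles baseline repeat cycles.
#' @param seed global seed.
#' @param out_dir artifact directory.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(difficulty = 0.7, unseen_shift = 1,
                              n_train_per_class = 60, n_extra_per_class = 100,
                              n_test_per_class = 40, render_size = 300,
                              gan = gan_config(), classifier = classifier_config(),
                              classifier_input = 96, synthetic_per_class = 320,
                              cycles = 10, seed = 1, out_dir = tempfile("cardiogan_run_")) {
  stopifnot(inherits(gan, "gan_config"), inherits(classifier, "classifier_config"),
            n_train_per_class >= 1, n_test_per_class >= 1, synthetic_per_class >= 1,
            cycles >= 1)
  structure(list(difficulty = difficulty, unseen_shift = unseen_shift,
                 n_train_per_class = n_train_per_class,
                 n_extra_per_class = n_extra_per_class,
                 n_test_per_class = n_test_per_class,
                 render_size = render_size, gan = gan, classifier = classifier,
                 classifier_input = classifier_input,
                 synthetic_per_class = synthetic_per_class, cycles = cycles,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_experiment_config` returns the config.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$gan <- unclass(x$gan)
  x$classifier <- unclass(x$classifier)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$gan <- do.call(gan_config, x$gan)
  x$classifier <- do.call(classifier_config, x$classifier)
  do.call(experiment_config, x)
}

domain_report_to_list <- function(r) {
  list(seen_accuracy = r$seen_accuracy, unseen_accuracy = r$unseen_accuracy,
       pooled_accuracy = r$pooled_accuracy, macro_accuracy = r$macro_accuracy,
       n_seen = r$n_seen, n_unseen = r$n_unseen,
       confusion_seen = unclass(r$confusion_seen),
       confusion_unseen = unclass(r$confusion_unseen))
}

#' Run the full augmentation pipeline
#'
#' Chains phantom generation (seen train / extra-real / seen+unseen test),
#' one GAN per class, synthetic-library sampling, three-dataset assembly,
#' three classifier trainings, domain evaluation, PCA and baselines, writing
#' every artifact (manifests, bundle directories, history CSVs, report JSONs
#' and figure PNGs) under `config$out_dir`. All randomness derives from
#' `config$seed`, so re-running an identical config reproduces the
#' domain-report JSONs byte for byte.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return object of class `run_record`: config snapshot, input manifest
#'   hash, timestamps, artifact paths, and the three `domain_report`s.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- set_global_seed(config$seed)
  t0 <- Sys.time()
  artifacts <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("[run] stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  presets <- make_class_presets(config$difficulty)
  train_set <- stage("phantom", {
    ds <- make_image_dataset(presets, config$n_train_per_class,
                             config$unseen_shift, seed = seeds$phantom,
                             size = config$render_size, domains = "seen")
    artifacts$train_manifest <- write_image_dataset(ds, file.path(out, "train_seen"))
    ds$images
  })
  extra_real <- stage("phantom_extra", {
    ds <- make_image_dataset(presets, config$n_extra_per_class,
                             config$unseen_shift, seed = seeds$phantom_extra,
                             size = config$render_size, domains = "seen")
    ds$images
  })
  tests <- stage("phantom_test", {
    ds <- make_image_dataset(presets, config$n_test_per_class,
                             config$unseen_shift, seed = seeds$phantom_test,
                             size = config$render_size)
    artifacts$test_manifest <- write_image_dataset(ds, file.path(out, "test"))
    ds$images
  })
  seen_test <- Filter(function(im) im$domain == "seen", tests)
  unseen_test <- Filter(function(im) im$domain == "unseen", tests)

  bundles <- list()
  for (cls in MATURATION_CLASSES) {
    bundles[[cls]] <- stage(paste0("gan_", cls), {
      imgs <- Filter(function(im) im$label == cls, train_set)
      cfg <- config$gan
      cfg$seed <- seeds[[paste0("gan_", cls)]]
      b <- train_image_gan(imgs, cfg)
      d <- file.path(out, paste0("gan_", cls))
      save_gan_bundle(b, d)
      artifacts[[paste0("gan_", cls)]] <- d
      b
    })
  }

  library_syn <- stage("library", {
    lib <- synthesize_class_library(bundles, config$synthetic_per_class,
                                    seed = seeds$library)
    artifacts$library_manifest <-
      write_image_dataset(lib, file.path(out, "synthetic"), prefix = "gan")
    lib
  })

  triplet <- assemble_training_sets(train_set, extra_real, library_syn)

  spec <- classifier_spec(input_size = config$classifier_input)
  models <- list()
  reports <- list()
  for (nm in c("small_real", "large_real", "mixed")) {
    key <- c(small_real = "classifier_small", large_real = "classifier_large",
             mixed = "classifier_mixed")[[nm]]
    models[[nm]] <- stage(key, {
      cfg <- config$classifier
      cfg$seed <- seeds[[key]]
      m <- train_classifier(triplet[[nm]], cfg, spec = spec)
      utils::write.csv(m$history,
                       file.path(out, paste0("history_", nm, ".csv")),
                       row.names = FALSE)
      m
    })
    reports[[nm]] <- stage("evaluation", {
      r <- evaluate_domains(models[[nm]], seen_test, unseen_test)
      p <- file.path(out, paste0("report_", nm, ".json"))
      jsonlite::write_json(domain_report_to_list(r), p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      artifacts[[paste0("report_", nm)]] <- p
      grDevices::png(file.path(out, paste0("confusion_", nm, ".png")),
                     width = 900, height = 450)
      graphics::par(mfrow = c(1, 2))
      plot(r$confusion_seen, main = paste(nm, "seen"))
      plot(r$confusion_unseen, main = paste(nm, "unseen"))
      grDevices::dev.off()
      r
    })
  }

  stage("pca", {
    sub <- function(x, n) x[seq_len(min(n, length(x)))]
    imgs <- c(sub(train_set, 150), sub(library_syn$images, 150),
              sub(unseen_test, 150))
    pr <- pca_embed(imgs, 2)
    utils::write.csv(data.frame(pr$scores, group = pr$groups),
                     file.path(out, "pca_scores.csv"), row.names = FALSE)
    grDevices::png(file.path(out, "pca.png"), width = 700, height = 600)
    plot(pr)
    grDevices::dev.off()
  })

  baselines <- stage("baselines", {
    b <- run_baselines(triplet$mixed, seen_test, unseen_test,
                       cycles = config$cycles, seed = seeds$baselines)
    utils::write.csv(b$results, file.path(out, "baselines.csv"),
                     row.names = FALSE)
    b
  })

  stage("figures", {
    pick <- function(src, cls) Filter(function(im) im$label == cls, src)[1:2]
    panel <- c(unlist(lapply(MATURATION_CLASSES, function(cl)
      pick(train_set, cl)), recursive = FALSE),
      unlist(lapply(MATURATION_CLASSES, function(cl)
        pick(library_syn$images, cl)), recursive = FALSE))
    save_image_panel(panel, file.path(out, "real_vs_synthetic.png"), ncol = 6)
    fm <- feature_maps(models$mixed, seen_test[[1]])
    save_feature_map_panel(seen_test[[1]], fm, file.path(out, "feature_maps.png"))
  })

  record <- structure(list(
    config = config,
    input_hash = unname(tools::md5sum(artifacts$train_manifest)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    artifacts = artifacts,
    triplet_sizes = vapply(c("small_real", "large_real", "mixed"),
                           function(nm) length(triplet[[nm]]), 0L),
    reports = reports,
    baselines = baselines),
    class = "run_record")
  saveRDS(record, file.path(out, "run_record.rds"))
  jsonlite::write_json(
    list(config = lapply(unclass(config), function(x)
           if (inherits(x, c("gan_config", "classifier_config"))) unclass(x) else x),
         input_hash = record$input_hash, started = record$started,
         finished = record$finished,
         triplet_sizes = as.list(record$triplet_sizes),
         artifacts = artifacts),
    file.path(out, "run_record.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record>\n  out:", x$config$out_dir, "\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-11s seen=%.3f  unseen=%.3f  pooled=%.3f\n",
                nm, r$seen_accuracy, r$unseen_accuracy, r$pooled_accuracy))
  }
  invisible(x)
}
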