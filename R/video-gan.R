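# Temporal GAN for 5-frame beating-cell clips.
#
# The five frames are modeled as the five channels of a single 2-D generator
# output of shape (64, 64, 5): the same four-layer (transposed) convolution
# machinery as the image GAN, with the latent projected to a 4 x 4 map. No
# recurrent or 3-D convolution machinery is involved; temporal structure is
# carried entirely by the channel dimension.

#' Video GAN configuration
#'
#' A [gan_config()] specialized to the clip contract: 64 x 64 frames, five
#' output channels (the temporal frames), otherwise the same optimizer
#' defaults as the image GAN.
#'
#' @param image_size frame side length (default 64).
#' @param epochs training epochs.
#' @param ... further arguments passed to [gan_config()] (learning rate,
#'   betas, batch size, base channels, seed, ...).
#' @return object of class `gan_config`.
#' @export
video_gan_config <- function(image_size = 64, epochs = 2000, ...) {
  gan_config(image_size = image_size, epochs = epochs, out_channels = 5, ...)
}

#' Build the video generator / discriminator
#'
#' The generator maps a 64-dim latent to a (size, size, 5) clip in \[-1, 1\]
#' through four stride-2 transposed convolutions with a final Tanh; the
#' discriminator maps a clip to a probability that it shows a genuine beating
#' cell. A discriminator built for clips rejects 3-channel image input with a
#' shape error.
#'
#' @param config a config from [video_gan_config()].
#' @return a `gan_generator` / `gan_discriminator` (shared classes with the
#'   image GAN; use [generate_images()] and [discriminate()]).
#' @export
build_video_generator <- function(config = video_gan_config()) {
  if (config$out_channels != 5)
    stop("video generator requires out_channels = 5")
  build_generator(config)
}

#' @rdname build_video_generator
#' @export
build_video_discriminator <- function(config = video_gan_config()) {
  if (config$out_channels != 5)
    stop("video discriminator requires out_channels = 5")
  build_discriminator(config)
}

#' Train the temporal GAN on beating-cell clips
#'
#' Same training contract as [train_image_gan()] applied to clips: per-epoch
#' random crop and random horizontal flip (applied identically across the
#' five frames, which are already grayscale) followed by resize to
#' `config$image_size`.
#'
#' @param clips list of `video_clip`.
#' @param config a [video_gan_config()].
#' @param verbose print per-epoch losses every `verbose` epochs.
#' @return a `gan_bundle` whose generator emits (size, size, 5) clips.
#' @export
train_video_gan <- function(clips, config = video_gan_config(), verbose = 0) {
  if (length(clips) < 1) stop("need at least one training clip")
  stopifnot(all(vapply(clips, inherits, NA, "video_clip")))
  pix <- lapply(clips, function(cl) cl$frames)
  train_gan_core(pix, "beating", config, verbose)
}

#' Sample synthetic beating clips from a trained video bundle
#'
#' @param bundle a `gan_bundle` from [train_video_gan()].
#' @param n number of clips.
#' @param seed integer seed.
#' @param use_ema sample from the weight-averaged generator when available.
#' @return list of `video_clip` with provenance `"gan"`.
#' @export
sample_synthetic_clips <- function(bundle, n, seed = 1, use_ema = TRUE) {
  stopifnot(inherits(bundle, "gan_bundle"), bundle$config$out_channels == 5)
  if (n < 1) stop("n must be >= 1")
  gen <- if (use_ema && !is.null(bundle$generator_ema)) bundle$generator_ema
         else bundle$generator
  out <- with_seed(seed, {
    z <- sample_latent(n, bundle$config$latent_dim)
    generate_images(gen, z, training = FALSE)
  })
  lapply(seq_len(n), function(i)
    video_clip(from_model_space(out[, , , i, drop = FALSE][, , , 1]),
               fps = 5, provenance = "gan"))
}

#' Write a clip as a PNG frame sequence
#'
#' Writes five sequentially numbered 8-bit grayscale PNGs
#' (`<stem>_f1.png` ... `<stem>_f5.png`) plus a small CSV manifest with the
#' frame order and the frame rate. The PNG path round-trips losslessly at
#' 8-bit depth (see [read_clip_frames()]).
#'
#' @param clip a `video_clip`.
#' @param stem output path stem (directory must exist or be creatable).
#' @return character vector of the five frame paths, invisibly.
#' @export
clip_to_video_file <- function(clip, stem) {
  stopifnot(inherits(clip, "video_clip"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s_f%d.png", stem, 1:5)
  for (t in 1:5) {
    q <- round(clip$frames[, , t] * 255) / 255
    png::writePNG(q, paths[t])
  }
  utils::write.csv(
    data.frame(frame = 1:5, filename = basename(paths), fps = clip$fps,
               duration_s = 5 / clip$fps),
    paste0(stem, "_manifest.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read a clip back from a PNG frame sequence
#' @param stem the path stem used by [clip_to_video_file()].
#' @param provenance provenance tag for the rebuilt clip.
#' @return a `video_clip`.
#' @export
read_clip_frames <- function(stem, provenance = "phantom") {
  frames <- array(0, c(0, 0, 5))
  for (t in 1:5) {
    f <- png::readPNG(sprintf("%s_f%d.png", stem, t))
    if (length(dim(f)) == 3) f <- f[, , 1]
    if (t == 1) frames <- array(0, c(nrow(f), ncol(f), 5))
    frames[, , t] <- f
  }
  video_clip(frames, fps = 5, provenance = provenance)
}
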