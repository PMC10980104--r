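# Shared helpers: seeding, image containers, resizing, pixel-space changes.

MATURATION_CLASSES <- c("day2", "day6", "day14")

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline (phantom generation, per-class GAN training,
#' classifier training, ...) must draw from distinct, reproducible random
#' streams. The derivation is a fixed polynomial hash of the stage name mixed
#' with the global seed, reduced modulo 2^31 - 1 so the result is always a
#' valid R integer seed.
#'
#' @param seed non-negative integer global seed.
#' @param stage character stage name.
#' @return integer seed, distinct across stage names with overwhelming
#'   probability.
#' @export
#' @examples
#' derive_seed(1, "phantom") != derive_seed(1, "gan_day2")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, is.character(stage))
  m <- 2147483647
  h <- seed %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert pixels between storage space [0, 1] and model space [-1, 1]
#'
#' Stored images (and 8-bit PNG files) live in \[0, 1\]; all networks consume
#' and produce \[-1, 1\] to match the generator's final Tanh.
#' @param x numeric array.
#' @return array of the same shape.
#' @export
to_model_space <- function(x) 2 * x - 1

#' @rdname to_model_space
#' @export
from_model_space <- function(x) clamp01((x + 1) / 2)

#' Construct a labeled image
#'
#' The basic image record of the pipeline: an (H, W, 3) pixel array in
#' \[0, 1\] with a maturation-stage label, a domain tag (`seen`/`unseen`) and
#' a provenance tag (`phantom` for simulator output, `gan` for synthetic
#' samples).
#'
#' @param pixels numeric (H, W, 3) array with values in \[0, 1\].
#' @param label one of `"day2"`, `"day6"`, `"day14"`.
#' @param domain `"seen"` or `"unseen"`.
#' @param provenance `"phantom"` or `"gan"`.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label, domain = "seen", provenance = "phantom") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [0, 1]")
  label <- match.arg(label, MATURATION_CLASSES)
  domain <- match.arg(domain, c("seen", "unseen"))
  provenance <- match.arg(provenance, c("phantom", "gan"))
  structure(list(pixels = pixels, label = label, domain = domain,
                 provenance = provenance),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image %dx%dx%d  label=%s  domain=%s  provenance=%s>\n",
              d[1], d[2], d[3], x$label, x$domain, x$provenance))
  invisible(x)
}

#' Construct a beating-cell video clip
#'
#' Five consecutive grayscale frames of one beating cell, stored as an
#' (H, W, 5) array in \[0, 1\] at a fixed frame rate of 5 frames per second
#' (one frame every 0.2 s).
#'
#' @param frames numeric (H, W, 5) array in \[0, 1\]; frames must be square.
#' @param fps frames per second (default 5).
#' @param provenance `"phantom"` or `"gan"`.
#' @return object of class `video_clip`.
#' @export
video_clip <- function(frames, fps = 5, provenance = "phantom") {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] != 5) stop("a video clip must have exactly 5 frames")
  if (dim(frames)[1] != dim(frames)[2]) stop("frames must be square")
  provenance <- match.arg(provenance, c("phantom", "gan"))
  structure(list(frames = frames, fps = fps, provenance = provenance),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip %dx%d x %d frames @ %g FPS  provenance=%s>\n",
              d[1], d[2], d[3], x$fps, x$provenance))
  invisible(x)
}

#' Bilinear image resize
#' @param x numeric array (H, W) or (H, W, C).
#' @param h,w target height and width.
#' @return resized array.
#' @export
resize_image <- function(x, h, w = h) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  y <- EBImage::resize(EBImage::Image(x), w = h, h = w)
  y <- as.array(EBImage::imageData(y))
  dim(y) <- c(h, w, if (length(d) == 3) d[3] else NULL)
  if (length(d) == 2) dim(y) <- c(h, w)
  y
}

#' Stack labeled images into a model-space batch array
#'
#' Resizes each image to `size` x `size` and converts to \[-1, 1\].
#' @param images list of `labeled_image`.
#' @param size target side length.
#' @return numeric array (size, size, 3, N).
#' @export
as_image_batch <- function(images, size) {
  n <- length(images)
  out <- array(0, c(size, size, 3, n))
  for (i in seq_len(n)) out[, , , i] <- resize_image(images[[i]]$pixels, size, size)
  to_model_space(out)
}

image_labels <- function(images) {
  factor(vapply(images, function(im) im$label, ""), levels = MATURATION_CLASSES)
}

#' Deterministic center crop
#' @param x (H, W, C) array.
#' @param size crop side length.
#' @return (size, size, C) array.
#' @export
center_crop <- function(x, size) {
  d <- dim(x)
  if (d[1] < size || d[2] < size) stop("input smaller than crop size")
  r0 <- (d[1] - size) %/% 2
  c0 <- (d[2] - size) %/% 2
  x[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}
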