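# Figure helpers: image panels, clip strips, confusion heatmaps, PCA
# scatter plots, feature-map panels, contractility traces.

img_raster <- function(px) {
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  grDevices::as.raster(clamp01(px))
}

#' Save a panel of images as one PNG
#'
#' @param images list of `labeled_image` (or raw (H, W, 3) arrays).
#' @param path output PNG path.
#' @param ncol panel columns.
#' @param labels optional character captions (defaults to
#'   `label/provenance`).
#' @return `path` invisibly.
#' @export
save_image_panel <- function(images, path, ncol = 5, labels = NULL) {
  n <- length(images)
  nrow <- ceiling(n / ncol)
  if (is.null(labels))
    labels <- vapply(images, function(im)
      if (inherits(im, "labeled_image")) paste(im$label, im$provenance) else "", "")
  grDevices::png(path, width = 160 * ncol, height = 175 * nrow)
  graphics::par(mfrow = c(nrow, ncol), mar = c(0.2, 0.2, 1.2, 0.2))
  for (i in seq_len(n)) {
    px <- if (inherits(images[[i]], "labeled_image")) images[[i]]$pixels else images[[i]]
    graphics::plot.new()
    graphics::rasterImage(img_raster(px), 0, 0, 1, 1)
    graphics::title(labels[i], cex.main = 0.9)
  }
  grDevices::dev.off()
  invisible(path)
}

#' Save a clip as a horizontal 5-frame strip
#' @param clip a `video_clip`.
#' @param path output PNG path.
#' @return `path` invisibly.
#' @export
save_clip_strip <- function(clip, path) {
  stopifnot(inherits(clip, "video_clip"))
  grDevices::png(path, width = 160 * 5, height = 175)
  graphics::par(mfrow = c(1, 5), mar = c(0.2, 0.2, 1.2, 0.2))
  for (t in 1:5) {
    graphics::plot.new()
    graphics::rasterImage(img_raster(clip$frames[, , t]), 0, 0, 1, 1)
    graphics::title(sprintf("t = %.1f s", (t - 1) / clip$fps), cex.main = 0.9)
  }
  grDevices::dev.off()
  invisible(path)
}

#' Save an input image next to its feature maps
#' @param image the input `labeled_image`.
#' @param maps list of matrices from [feature_maps()].
#' @param path output PNG path.
#' @return `path` invisibly.
#' @export
save_feature_map_panel <- function(image, maps, path) {
  n <- length(maps) + 1
  grDevices::png(path, width = 160 * n, height = 175)
  graphics::par(mfrow = c(1, n), mar = c(0.2, 0.2, 1.2, 0.2))
  graphics::plot.new()
  graphics::rasterImage(img_raster(image$pixels), 0, 0, 1, 1)
  graphics::title("input", cex.main = 0.9)
  for (i in seq_along(maps)) {
    graphics::plot.new()
    graphics::rasterImage(img_raster(maps[[i]]), 0, 0, 1, 1, interpolate = FALSE)
    graphics::title(paste("channel", i), cex.main = 0.9)
  }
  grDevices::dev.off()
  invisible(path)
}

#' @export
plot.confusion_matrix <- function(x, main = "confusion", ...) {
  m <- unclass(x)
  k <- nrow(m)
  graphics::image(1:k, 1:k, t(m[k:1, ]), axes = FALSE, xlab = "predicted",
                  ylab = "true", main = main,
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE))
  graphics::axis(1, at = 1:k, labels = colnames(m))
  graphics::axis(2, at = k:1, labels = rownames(m), las = 2)
  for (i in 1:k) for (j in 1:k)
    graphics::text(j, k + 1 - i, m[i, j],
                   col = if (m[i, j] > max(m) / 2) "white" else "black")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, main = "PCA of image features", ...) {
  g <- factor(x$groups %||% rep("all", nrow(x$scores)))
  cols <- grDevices::hcl.colors(max(3, nlevels(g)), "Dark 3")
  graphics::plot(x$scores[, 1], x$scores[, 2], col = cols[as.integer(g)],
                 pch = 19, cex = 0.7,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 main = main, ...)
  graphics::legend("topright", legend = levels(g), col = cols[seq_len(nlevels(g))],
                   pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
plot.contractility_trace <- function(x, main = "contractility trace", ...) {
  graphics::plot(x$times, x$magnitudes, type = "b", pch = 19, cex = 0.6,
                 xlab = "time (s)", ylab = "mean displacement (px)",
                 main = main, ...)
  if (length(x$peaks))
    graphics::points(x$times[x$peaks], x$magnitudes[x$peaks], col = "red",
                     pch = 17, cex = 1.1)
  invisible(x)
}
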