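# Procedural phantom microscopy simulator.
#
# Real recordings of cultured cardiomyocytes cannot be redistributed, so the
# package generates its own microscopy-like inputs: fields of textured,
# rotated ellipses over a noisy background, with class presets that encode
# the qualitative morphology of maturation stages (sparse small round cells
# early in culture; dense, elongated, aligned cells at day 14), plus 5-frame
# beating-cell clips with a known contraction amplitude.

#' Phantom generator parameters
#'
#' Parameters are expressed at a reference field size of 300 x 300 px (the
#' native acquisition crop size); when rendering at another size, areas are
#' scaled by `(size/300)^2` and texture length scales by `size/300`, so a
#' preset describes the same scene at any resolution.
#'
#' @param cell_density expected number of cells per field (Poisson mean).
#' @param cell_area_range length-2 numeric, min/max ellipse area in px^2 at
#'   the 300 px reference size; min must be > 0.
#' @param elongation_range length-2 numeric, min/max major/minor axis ratio;
#'   min must be >= 1.
#' @param alignment_kappa von Mises concentration of cell orientations
#'   (>= 0; 0 gives uniformly random orientation).
#' @param intensity_fg,intensity_bg mean foreground / background pixel level
#'   in \[0, 1\].
#' @param noise_sd additive Gaussian pixel noise standard deviation in \[0, 1\].
#' @param texture_scale within-cell intensity modulation length in px at the
#'   reference size.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(cell_density, cell_area_range, elongation_range,
                           alignment_kappa = 0, intensity_fg = 0.6,
                           intensity_bg = 0.2, noise_sd = 0.03,
                           texture_scale = 12) {
  stopifnot(cell_density >= 0,
            length(cell_area_range) == 2, cell_area_range[1] > 0,
            diff(cell_area_range) >= 0,
            length(elongation_range) == 2, elongation_range[1] >= 1,
            diff(elongation_range) >= 0,
            alignment_kappa >= 0, texture_scale > 0)
  for (v in c(intensity_fg, intensity_bg, noise_sd))
    if (v < 0 || v > 1) stop("intensities and noise_sd must lie in [0, 1]")
  structure(list(cell_density = cell_density,
                 cell_area_range = as.numeric(cell_area_range),
                 elongation_range = as.numeric(elongation_range),
                 alignment_kappa = alignment_kappa,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, texture_scale = texture_scale),
            class = "phantom_params")
}

#' Class presets for the three maturation stages
#'
#' Returns one [phantom_params()] per class, ordered so that cell density,
#' mean area and mean elongation all increase from day 2 to day 14.
#' `difficulty` widens the parameter overlap between day 2 and day 6 (the two
#' stages whose feature distributions overlap in practice): at 0 the day-2 and
#' day-6 area intervals are disjoint; at 1 they overlap over at least half of
#' the day-2 interval.
#'
#' @param difficulty numeric in \[0, 1\].
#' @return named list with elements `day2`, `day6`, `day14`.
#' @export
#' @examples
#' p <- make_class_presets(0.5)
#' p$day14$cell_density > p$day2$cell_density
make_class_presets <- function(difficulty = 0.5) {
  if (!is.numeric(difficulty) || length(difficulty) != 1 ||
      difficulty < 0 || difficulty > 1)
    stop("difficulty must be a single number in [0, 1]")
  d <- difficulty
  list(
    day2 = phantom_params(
      cell_density = 8, cell_area_range = c(300, 900),
      elongation_range = c(1.0, 1.6), alignment_kappa = 0.3,
      intensity_fg = 0.50, intensity_bg = 0.18, noise_sd = 0.04,
      texture_scale = 12),
    day6 = phantom_params(
      cell_density = 14 - 4 * d, cell_area_range = c(950 - 450 * d, 1800),
      elongation_range = c(1.4 - 0.25 * d, 2.2), alignment_kappa = 2 - d,
      intensity_fg = 0.55 - 0.03 * d, intensity_bg = 0.20, noise_sd = 0.04,
      texture_scale = 12),
    day14 = phantom_params(
      cell_density = 24, cell_area_range = c(1800, 3600),
      elongation_range = c(2.2, 3.6), alignment_kappa = 6,
      intensity_fg = 0.60, intensity_bg = 0.22, noise_sd = 0.04,
      texture_scale = 14)
  )
}

#' Shift a preset toward the unseen domain
#'
#' The unseen domain emulates a second cell batch: every generator parameter
#' mean is moved by `shift` standard deviations in a fixed direction (denser,
#' larger, more elongated, slightly brighter and noisier). For uniform range
#' parameters the standard deviation is `width/sqrt(12)`; for the Poisson
#' density it is `sqrt(density)`.
#'
#' @param params a `phantom_params` object.
#' @param shift non-negative shift in parameter standard deviations.
#' @return shifted `phantom_params`.
#' @export
shift_params <- function(params, shift) {
  stopifnot(inherits(params, "phantom_params"), shift >= 0)
  if (shift == 0) return(params)
  usd <- function(r) diff(r) / sqrt(12)
  p <- unclass(params)
  p$cell_density <- p$cell_density + shift * sqrt(p$cell_density)
  p$cell_area_range <- p$cell_area_range + shift * usd(p$cell_area_range)
  p$elongation_range <- p$elongation_range + shift * usd(p$elongation_range)
  p$intensity_fg <- min(0.95, p$intensity_fg + 0.04 * shift)
  p$intensity_bg <- min(0.90, p$intensity_bg + 0.03 * shift)
  p$noise_sd <- min(0.5, p$noise_sd + 0.01 * shift)
  do.call(phantom_params, p)
}

# Axial von Mises orientation sampler (Best-Fisher rejection scheme on the
# doubled angle); kappa = 0 degenerates to a uniform orientation in
# (-pi/2, pi/2].
rvonmises_axial <- function(n, kappa) {
  if (kappa <= 1e-12) return(stats::runif(n, -pi / 2, pi / 2))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      ccos <- kappa * (r - f)
      if (ccos * (2 - ccos) - u[2] > 0 || log(ccos / u[2]) + 1 - ccos >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out / 2
}

# Draw the cell table (centers, axes, orientation, texture phases) for one
# field. Areas and texture lengths are rescaled from the 300 px reference.
sample_cells <- function(params, size) {
  H <- size[1]; W <- size[2]
  area_scale <- (min(H, W) / 300)^2
  n <- stats::rpois(1, params$cell_density)
  if (n == 0)
    return(data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), phase1 = numeric(0),
                      phase2 = numeric(0), bright = numeric(0)))
  area <- stats::runif(n, params$cell_area_range[1], params$cell_area_range[2]) *
    area_scale
  elong <- stats::runif(n, params$elongation_range[1], params$elongation_range[2])
  theta <- rvonmises_axial(n, params$alignment_kappa)
  data.frame(
    cx = stats::runif(n, 1, W), cy = stats::runif(n, 1, H),
    a = sqrt(area * elong / pi), b = sqrt(area / (elong * pi)),
    theta = theta,
    phase1 = stats::runif(n, 0, 2 * pi), phase2 = stats::runif(n, 0, 2 * pi),
    bright = stats::runif(n, 0.92, 1.08))
}

#' Rasterize a table of elliptical cells onto a background
#'
#' Low-level renderer shared by [render_cell_field()] and the beating-clip
#' generator. Each cell is a rotated ellipse with a narrow soft edge and a
#' sinusoidal internal texture; overlapping cells compose by maximum.
#'
#' @param cells data frame with columns `cx, cy, a, b, theta, phase1, phase2,
#'   bright` (as produced internally; `a`/`b` are semi-axes in px).
#' @param size integer (H, W).
#' @param params `phantom_params` supplying intensities and texture scale.
#' @param texture_amp relative amplitude of the within-cell texture.
#' @return numeric (H, W) matrix in \[0, 1\], noise-free.
#' @export
rasterize_cells <- function(cells, size, params, texture_amp = 0.25) {
  H <- size[1]; W <- size[2]
  lin_scale <- min(H, W) / 300
  ts <- max(2, params$texture_scale * lin_scale)
  img <- matrix(params$intensity_bg, H, W)
  edge <- 0.08
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    ext <- ceiling(max(ce$a, ce$b)) + 2L
    rows <- max(1L, floor(ce$cy - ext)):min(H, ceiling(ce$cy + ext))
    colsr <- max(1L, floor(ce$cx - ext)):min(W, ceiling(ce$cx + ext))
    if (!length(rows) || !length(colsr)) next
    dy <- outer(rows - ce$cy, rep(1, length(colsr)))
    dx <- outer(rep(1, length(rows)), colsr - ce$cx)
    u <- (dx * cos(ce$theta) + dy * sin(ce$theta)) / ce$a
    v <- (-dx * sin(ce$theta) + dy * cos(ce$theta)) / ce$b
    r2 <- u^2 + v^2
    cov <- pmin(1, pmax(0, (1 - r2) / edge))
    if (!any(cov > 0)) next
    # two rotated, incommensurate gratings: an aperiodic-looking texture
    # with no translational self-similarity inside a block-match search
    g1 <- dx * cos(ce$phase1) + dy * sin(ce$phase1)
    g2 <- dx * cos(ce$phase2 + 1.1) + dy * sin(ce$phase2 + 1.1)
    tex <- 1 + texture_amp * (0.55 * sin(2 * pi * g1 / ts + 2 * ce$phase2) +
                              0.45 * sin(2 * pi * g2 / (0.63 * ts) + 2 * ce$phase1))
    val <- params$intensity_bg +
      (clamp01(params$intensity_fg * ce$bright * tex) - params$intensity_bg) * cov
    img[rows, colsr] <- pmax(img[rows, colsr], val)
  }
  img
}

#' Render one phantom cell-field image
#'
#' Draws a Poisson number of textured, rotated ellipses over a noisy
#' background and replicates the field into three identical color channels
#' before adding independent per-channel Gaussian noise. The output is a pure
#' function of `(params, size, seed)`.
#'
#' @param params a [phantom_params()] object.
#' @param size integer side length(s), at least 64; a scalar renders a square
#'   field.
#' @param seed integer seed.
#' @param label,domain passed to [labeled_image()].
#' @return a `labeled_image` with provenance `"phantom"`.
#' @export
render_cell_field <- function(params, size = 300, seed = 1, label = "day2",
                              domain = "seen") {
  stopifnot(inherits(params, "phantom_params"))
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 64)) stop("field size must be at least 64 px")
  pixels <- with_seed(seed, {
    cells <- sample_cells(params, size)
    base <- rasterize_cells(cells, size, params)
    px <- array(0, c(size[1], size[2], 3))
    for (ch in 1:3) {
      px[, , ch] <- clamp01(base +
        if (params$noise_sd > 0)
          matrix(stats::rnorm(prod(size), 0, params$noise_sd), size[1], size[2])
        else 0)
    }
    px
  })
  labeled_image(pixels, label = label, domain = domain, provenance = "phantom")
}

#' Generate a balanced seen/unseen phantom image dataset
#'
#' For each class, draws `n_per_class` seen-domain images from its preset and
#' the same number of unseen-domain images from the preset shifted by
#' `unseen_shift` parameter standard deviations (see [shift_params()]).
#' Per-image seeds are derived from `seed`, the class, the domain and the
#' image index, so regeneration is bitwise reproducible and independent of
#' evaluation order.
#'
#' @param presets named list of class presets as from [make_class_presets()].
#' @param n_per_class images per class per domain; either a single count or a
#'   vector of three per-class counts (in day2, day6, day14 order).
#' @param unseen_shift non-negative domain shift in parameter SDs.
#' @param seed integer seed.
#' @param size rendered field side length (default 300, the native
#'   acquisition crop).
#' @param domains which domains to render (default both). Per-image seeds
#'   depend only on (seed, class, domain, index), so the seen half of a
#'   two-domain set is bitwise identical to a seen-only set.
#' @return object of class `phantom_image_set` with elements `images` (list of
#'   `labeled_image`), `per_class_counts` (class x domain matrix), `seed`.
#' @export
make_image_dataset <- function(presets, n_per_class, unseen_shift = 0,
                               seed = 1, size = 300,
                               domains = c("seen", "unseen")) {
  domains <- match.arg(domains, several.ok = TRUE)
  if (length(presets) == 0) stop("presets must be a non-empty list")
  if (!all(MATURATION_CLASSES %in% names(presets)))
    stop("presets must contain day2, day6 and day14")
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1")
  if (unseen_shift < 0) stop("unseen_shift must be >= 0")
  counts <- if (length(n_per_class) == 1) rep(n_per_class, 3) else n_per_class
  stopifnot(length(counts) == 3)
  names(counts) <- MATURATION_CLASSES
  images <- list()
  tab <- matrix(0L, 3, 2, dimnames = list(MATURATION_CLASSES, c("seen", "unseen")))
  for (cls in MATURATION_CLASSES) {
    for (dom in domains) {
      p <- presets[[cls]]
      if (dom == "unseen") p <- shift_params(p, unseen_shift)
      for (i in seq_len(counts[[cls]])) {
        s <- derive_seed(seed, sprintf("phantom_%s_%s_%d", cls, dom, i))
        images[[length(images) + 1]] <-
          render_cell_field(p, size = size, seed = s, label = cls, domain = dom)
        tab[cls, dom] <- tab[cls, dom] + 1L
      }
    }
  }
  structure(list(images = images, per_class_counts = tab, seed = seed,
                 unseen_shift = unseen_shift),
            class = "phantom_image_set")
}

#' @export
print.phantom_image_set <- function(x, ...) {
  cat("<phantom_image_set>\n")
  print(x$per_class_counts)
  invisible(x)
}

# Bilinear sample of matrix `img` at fractional coordinates (y, x), clamped
# to the image border.
bilinear_sample <- function(img, y, x) {
  H <- nrow(img); W <- ncol(img)
  y <- pmin(pmax(as.numeric(y), 1), H); x <- pmin(pmax(as.numeric(x), 1), W)
  y0 <- pmin(floor(y), H - 1); x0 <- pmin(floor(x), W - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
}

#' Render a 5-frame beating-cell phantom clip
#'
#' A single textured cell is centered in the frame (a close-up view, so the
#' cell fills a fixed fraction of the field and only its shape, intensity and
#' texture come from `params`). The boundary contracts radially toward the
#' centroid with the per-frame displacement profile `(0, A/2, A, A/2, 0)`:
#' frame 3 is peak contraction and every material point moves by exactly the
#' profile displacement, so block-matching motion analysis should recover the
#' amplitude `A`.
#'
#' @param params a [phantom_params()] (elongation, intensities and texture
#'   are used).
#' @param amplitude peak contraction displacement A in px (>= 0).
#' @param seed integer seed.
#' @param size frame side length (default 64).
#' @return a `video_clip` with attribute `"amplitude"`.
#' @export
render_beating_clip <- function(params, amplitude = 2, seed = 1, size = 64) {
  stopifnot(inherits(params, "phantom_params"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  frames <- with_seed(seed, {
    elong <- stats::runif(1, params$elongation_range[1], params$elongation_range[2])
    theta <- rvonmises_axial(1, params$alignment_kappa)
    area <- 0.30 * size^2
    cells <- data.frame(cx = (size + 1) / 2, cy = (size + 1) / 2,
                        a = sqrt(area * elong / pi), b = sqrt(area / (elong * pi)),
                        theta = theta,
                        phase1 = stats::runif(1, 0, 2 * pi),
                        phase2 = stats::runif(1, 0, 2 * pi), bright = 1)
    tight <- params
    # high-contrast texture with a period longer than the block-match search
    # radius, so displacement estimates cannot alias
    tight$texture_scale <- 11 * 300 / size
    rest <- rasterize_cells(cells, c(size, size), tight, texture_amp = 0.5)
    disp <- amplitude * c(0, 0.5, 1, 0.5, 0)
    cy <- (size + 1) / 2; cx <- (size + 1) / 2
    gy <- matrix(seq_len(size), size, size)
    gx <- matrix(seq_len(size), size, size, byrow = TRUE)
    rho <- sqrt((gy - cy)^2 + (gx - cx)^2)
    uy <- ifelse(rho > 0, (gy - cy) / pmax(rho, 1e-9), 0)
    ux <- ifelse(rho > 0, (gx - cx) / pmax(rho, 1e-9), 0)
    fr <- array(0, c(size, size, 5))
    for (t in 1:5) {
      if (disp[t] == 0) {
        f <- rest
      } else {
        f <- matrix(bilinear_sample(rest, gy + disp[t] * uy, gx + disp[t] * ux),
                    size, size)
      }
      if (params$noise_sd > 0)
        f <- f + matrix(stats::rnorm(size^2, 0, params$noise_sd), size, size)
      fr[, , t] <- clamp01(f)
    }
    fr
  })
  structure(video_clip(frames, fps = 5, provenance = "phantom"),
            amplitude = amplitude)
}

#' Generate a dataset of beating-cell phantom clips
#'
#' Clip contraction amplitudes are drawn uniformly from `amplitude_range`
#' (px); per-clip seeds are derived from `seed` and the clip index.
#'
#' @param params a [phantom_params()].
#' @param n_clips number of clips (>= 1).
#' @param seed integer seed.
#' @param amplitude_range length-2 numeric, px.
#' @param size frame side length.
#' @return list of `video_clip` objects, each carrying its ground-truth
#'   `"amplitude"` attribute.
#' @export
make_clip_dataset <- function(params, n_clips, seed = 1,
                              amplitude_range = c(1, 4), size = 64) {
  if (n_clips < 1) stop("n_clips must be >= 1")
  amps <- with_seed(derive_seed(seed, "clip_amplitudes"),
                    stats::runif(n_clips, amplitude_range[1], amplitude_range[2]))
  lapply(seq_len(n_clips), function(i) {
    render_beating_clip(params, amplitude = amps[i],
                        seed = derive_seed(seed, sprintf("clip_%d", i)),
                        size = size)
  })
}
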