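# Phantom simulator: presets, rendering, datasets, beating clips.

test_that("class presets order morphology day2 < day6 < day14 and difficulty
           controls day2/day6 overlap", {
  for (d in c(0, 0.5, 1)) {
    p <- make_class_presets(d)
    expect_gt(p$day14$cell_density, p$day2$cell_density)
    expect_gt(mean(p$day14$cell_area_range), mean(p$day2$cell_area_range))
    expect_gt(mean(p$day14$elongation_range), mean(p$day2$elongation_range))
    expect_gt(mean(p$day6$cell_area_range), mean(p$day2$cell_area_range))
  }
  p0 <- make_class_presets(0)
  expect_lt(p0$day2$cell_area_range[2], p0$day6$cell_area_range[1])
  p1 <- make_class_presets(1)
  overlap <- min(p1$day2$cell_area_range[2], p1$day6$cell_area_range[2]) -
    max(p1$day2$cell_area_range[1], p1$day6$cell_area_range[1])
  expect_gte(overlap, 0.5 * diff(p1$day2$cell_area_range))
  expect_error(make_class_presets(1.2), "difficulty")
  expect_error(make_class_presets(-0.1), "difficulty")
})

test_that("rendering is deterministic and degenerates to a flat background", {
  p <- make_class_presets(0.5)$day6
  a <- render_cell_field(p, size = 80, seed = 42)
  b <- render_cell_field(p, size = 80, seed = 42)
  expect_identical(a$pixels, b$pixels)
  flat <- phantom_params(0, c(100, 200), c(1, 1.2), noise_sd = 0,
                         intensity_bg = 0.3)
  im <- render_cell_field(flat, size = 64, seed = 1)
  expect_true(all(im$pixels == 0.3))
  expect_error(render_cell_field(p, size = 32, seed = 1), "at least 64")
})

test_that("rasterized foreground area matches the analytic ellipse area", {
  # 20 non-overlapping cells of equal area A on a 5 x 4 grid
  p <- phantom_params(20, c(800, 800), c(1.5, 1.5), noise_sd = 0,
                      intensity_fg = 0.8, intensity_bg = 0.1)
  A <- 800
  centers <- expand.grid(cx = seq(40, 280, length.out = 5),
                         cy = seq(40, 260, length.out = 4))
  cells <- data.frame(cx = centers$cx, cy = centers$cy,
                      a = sqrt(A * 1.5 / pi), b = sqrt(A / (1.5 * pi)),
                      theta = seq(0, pi / 2, length.out = 20),
                      phase1 = 1, phase2 = 2, bright = 1)
  img <- rasterize_cells(cells, c(300, 300), p)
  mask_count <- sum(img > (0.8 + 0.1) / 2)
  expect_lt(abs(mask_count - 20 * A) / (20 * A), 0.10)
})

test_that("mean foreground fraction is non-decreasing in cell density", {
  fg_frac <- function(density, seed) {
    p <- phantom_params(density, c(600, 1200), c(1, 2), noise_sd = 0.02,
                        intensity_fg = 0.6, intensity_bg = 0.2)
    im <- render_cell_field(p, size = 96, seed = seed)
    mean(im$pixels > 0.4)
  }
  fr <- sapply(c(4, 12, 36), function(d) mean(sapply(1:10, fg_frac, density = d)))
  expect_true(all(diff(fr) > 0))
})

test_that("at difficulty 0 a foreground-fraction threshold separates day2
           from day14 with >= 90% accuracy", {
  p <- make_class_presets(0)
  frac <- function(preset, seed)
    mean(render_cell_field(preset, 64, seed)$pixels > 0.35)
  f2 <- sapply(1:100, frac, preset = p$day2)
  f14 <- sapply(101:200, frac, preset = p$day14)
  thr <- (median(f2) + median(f14)) / 2
  acc <- (sum(f2 < thr) + sum(f14 >= thr)) / 200
  expect_gte(acc, 0.9)
})

test_that("unseen_shift = 0 leaves generator parameters and intensity
           distributions unchanged", {
  p <- make_class_presets(0.5)$day6
  expect_identical(shift_params(p, 0), p)
  ds <- make_image_dataset(make_class_presets(0.5), 34, unseen_shift = 0,
                           seed = 3, size = 64)
  mu <- sapply(ds$images, function(im) mean(im$pixels))
  dom <- sapply(ds$images, function(im) im$domain)
  ks <- suppressWarnings(ks.test(mu[dom == "seen"], mu[dom == "unseen"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a positive unseen shift moves every shifted parameter in its fixed
           direction", {
  p <- make_class_presets(0.5)$day2
  q <- shift_params(p, 1)
  expect_gt(q$cell_density, p$cell_density)
  expect_true(all(q$cell_area_range > p$cell_area_range))
  expect_true(all(q$elongation_range > p$elongation_range))
  expect_gt(q$intensity_fg, p$intensity_fg)
})

test_that("image datasets are balanced, tagged, and reproduce the printed
           per-class acquisition counts", {
  presets <- make_class_presets(0.5)
  ds <- make_image_dataset(presets, 4, unseen_shift = 1, seed = 9, size = 64)
  expect_length(ds$images, 24)
  expect_true(all(ds$per_class_counts == 4))
  # the acquisition protocol's per-class counts: 229 + 227 + 235 = 691 seen
  counts <- c(229, 227, 235)
  expect_equal(sum(counts), 691)
  ds2 <- make_image_dataset(presets, counts, unseen_shift = 1, seed = 9,
                            size = 64, domains = "seen")
  expect_length(ds2$images, 691)
  expect_equal(unname(ds2$per_class_counts[, "seen"]), counts)
  # seen half of a two-domain set is bitwise identical to a seen-only set
  ds3 <- make_image_dataset(presets, 4, unseen_shift = 1, seed = 9, size = 64,
                            domains = "seen")
  seen <- Filter(function(im) im$domain == "seen", ds$images)
  expect_identical(seen[[1]]$pixels, ds3$images[[1]]$pixels)
  expect_error(make_image_dataset(list(), 4), "non-empty")
  expect_error(make_image_dataset(presets, 0), "n_per_class")
  expect_error(make_image_dataset(presets, 4, unseen_shift = -1), "unseen_shift")
})

test_that("beating clips contract radially with a stable centroid and
           deterministic frames", {
  p <- make_class_presets(0.5)$day6
  cl <- render_beating_clip(p, amplitude = 3, seed = 2)
  expect_s3_class(cl, "video_clip")
  expect_equal(dim(cl$frames), c(64, 64, 5))
  expect_identical(cl$frames,
                   render_beating_clip(p, amplitude = 3, seed = 2)$frames)
  # zero amplitude, zero noise: all frames identical
  p0 <- p; p0$noise_sd <- 0
  cl0 <- render_beating_clip(p0, amplitude = 0, seed = 2)
  for (t in 2:5) expect_identical(cl0$frames[, , t], cl0$frames[, , 1])
  # intensity centroid is preserved by the radial contraction
  centroid <- function(f) {
    w <- f - min(f)
    c(sum(row(f) * w), sum(col(f) * w)) / sum(w)
  }
  cents <- apply(cl$frames, 3, centroid)
  expect_lt(max(abs(cents - cents[, 1])), 0.5)
  expect_error(render_beating_clip(p, amplitude = -1), "amplitude")
})

test_that("clip datasets have the requested size and fixed frame count", {
  p <- make_class_presets(0.5)$day6
  # the beating-cell acquisition collected 124 single-cell clip groups
  clips <- make_clip_dataset(p, 124, seed = 1, size = 64)
  expect_length(clips, 124)
  expect_true(all(vapply(clips, function(cl) dim(cl$frames)[3] == 5, NA)))
  expect_true(all(vapply(clips, function(cl) all(dim(cl$frames)[1:2] == 64), NA)))
  one <- make_clip_dataset(p, 1, seed = 5)
  expect_identical(one[[1]]$frames, make_clip_dataset(p, 1, seed = 5)[[1]]$frames)
  expect_error(make_clip_dataset(p, 0), "n_clips")
})

test_that("labeled_image and video_clip validate their invariants", {
  expect_error(labeled_image(array(2, c(8, 8, 3)), "day2"), "0, 1")
  expect_error(labeled_image(array(0.5, c(8, 8, 3)), "day9"), "arg")
  expect_error(video_clip(array(0.5, c(8, 8, 4))), "exactly 5")
  expect_error(video_clip(array(0.5, c(8, 6, 5))), "square")
})
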