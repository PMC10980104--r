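# Contractile-motion quantification by block matching.

# 3x3 binomial filter ([1 2 1]/4 separably) with replicated borders.
binomial_smooth <- function(f) {
  pad <- rbind(f[1, , drop = FALSE], f, f[nrow(f), , drop = FALSE])
  f <- (pad[seq_len(nrow(f)), ] + 2 * pad[seq_len(nrow(f)) + 1, ] +
        pad[seq_len(nrow(f)) + 2, ]) / 4
  pad <- cbind(f[, 1, drop = FALSE], f, f[, ncol(f), drop = FALSE])
  (pad[, seq_len(ncol(f))] + 2 * pad[, seq_len(ncol(f)) + 1] +
    pad[, seq_len(ncol(f)) + 2]) / 4
}
#
# Displacements of a beating cell are estimated per frame with integer block
# matching (8 x 8 blocks, +/- 8 px search, sum-of-absolute-differences
# criterion); background blocks, identified by low pixel variance, are
# excluded from the mean. The per-frame mean displacement magnitude forms
# the contractility trace; the normalized contractile motion is the mean of
# the peak values observed within a 20 s window.

#' Contractility trace of a frame sequence
#'
#' Each frame after the first is compared to the reference (by default the
#' first frame, taken as the relaxed state, so the trace reads as contraction
#' displacement from rest; `reference = "consecutive"` compares successive
#' frames instead) and the mean displacement magnitude over foreground blocks
#' is recorded. Peaks are local maxima exceeding the mean plus two standard
#' deviations of the trace's lower half.
#'
#' @param frames a `video_clip`, an (H, W, T) array, or a list of (H, W)
#'   matrices; at least 2 frames.
#' @param fps frame rate (taken from a `video_clip` automatically).
#' @param reference `"first"` or `"consecutive"`.
#' @param block block side length in px.
#' @param search maximum displacement searched, px.
#' @param var_thresh minimum block pixel variance to count as foreground
#'   (the default rejects pure-noise background at the phantom noise level).
#' @param quality a nonzero displacement is only accepted when its
#'   sum-of-absolute-differences beats the zero-displacement value by this
#'   factor; unmatched (distorted) blocks are excluded from the mean.
#' @param smooth apply a 3 x 3 binomial filter to each frame before matching
#'   (suppresses sensor noise, which otherwise floods the SAD criterion).
#' @return object of class `contractility_trace`: `magnitudes` (px, one per
#'   compared frame), `times` (s), `fps`, `peaks` (indices into
#'   `magnitudes`), `n_foreground_blocks`.
#' @export
contractility_trace <- function(frames, fps = 5,
                                reference = c("first", "consecutive"),
                                block = 8, search = 8, var_thresh = 0.004,
                                quality = 0.7, smooth = TRUE) {
  reference <- match.arg(reference)
  if (inherits(frames, "video_clip")) {
    fps <- frames$fps
    frames <- frames$frames
  }
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  if (!is.list(frames) || length(frames) < 2)
    stop("need at least 2 frames")
  if (smooth) frames <- lapply(frames, binomial_smooth)
  nt <- length(frames)
  mags <- numeric(nt - 1)
  nfg <- integer(nt - 1)
  for (t in 2:nt) {
    ref <- if (reference == "first") frames[[1]] else frames[[t - 1]]
    bm <- cg_block_match(ref, frames[[t]], block, search, var_thresh, quality)
    ok <- bm[, 5] > 0
    nfg[t - 1] <- sum(ok)
    if (any(ok)) {
      m <- sqrt(bm[ok, 3]^2 + bm[ok, 4]^2)
      # robust rejection of mismatched blocks: magnitudes far above the
      # median block magnitude are spurious matches, not motion
      keep <- m <= stats::median(m) + max(2, 1.5 * stats::IQR(m))
      mags[t - 1] <- mean(m[keep])
    } else mags[t - 1] <- 0
  }
  structure(list(magnitudes = mags, times = seq_len(nt - 1) / fps, fps = fps,
                 peaks = find_peaks(mags), n_foreground_blocks = nfg,
                 reference = reference),
            class = "contractility_trace")
}

# Local maxima of a trace exceeding mean + 2 SD of its lower half (values at
# or below the median). Plateau maxima report their first index; the series
# ends count as maxima when the single neighbor is lower.
find_peaks <- function(x) {
  n <- length(x)
  if (n == 0 || all(x == 0)) return(integer(0))
  lower <- x[x <= stats::median(x)]
  thr <- mean(lower) + 2 * (if (length(lower) > 1) stats::sd(lower) else 0)
  is_max <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || x[i] > x[i - 1]
    right_ok <- i == n || x[i] >= x[i + 1]
    left_ok && right_ok
  }, NA)
  which(is_max & x > thr & x > 0)
}

#' @export
print.contractility_trace <- function(x, ...) {
  cat(sprintf("<contractility_trace  %d frames @ %g FPS  peak=%.2f px  %d peak(s)>\n",
              length(x$magnitudes) + 1, x$fps,
              if (length(x$magnitudes)) max(x$magnitudes) else 0,
              length(x$peaks)))
  invisible(x)
}

#' Normalized contractile motion
#'
#' The mean of all peak contraction magnitudes observed within the first
#' `window_s` seconds of the trace. A trace shorter than the window is used
#' in full with a warning; a trace with no detected peaks returns 0 with
#' attribute `no_peaks = TRUE`.
#'
#' @param trace a [contractility_trace()].
#' @param window_s observation window in seconds (default 20).
#' @return scalar px, with attribute `no_peaks` when no peaks were found.
#' @export
normalized_contractile_motion <- function(trace, window_s = 20) {
  stopifnot(inherits(trace, "contractility_trace"))
  if (max(trace$times) < window_s)
    warning(sprintf("trace spans %.1f s, shorter than the %g s window; using all of it",
                    max(trace$times), window_s))
  keep <- trace$peaks[trace$times[trace$peaks] <= window_s]
  if (length(keep) == 0)
    return(structure(0, no_peaks = TRUE))
  structure(mean(trace$magnitudes[keep]), no_peaks = FALSE)
}
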