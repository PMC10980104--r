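# Shared fixtures, all built in code at test time.

# A constant-intensity labeled image (the simplest separable toy input).
const_image <- function(level, label, size = 64, domain = "seen") {
  labeled_image(array(level, c(size, size, 3)), label, domain = domain)
}

# Three-class toy dataset with well-separated constant intensities.
toy_dataset <- function(n_per_class = 10, size = 64, jitter = 0.02, seed = 1) {
  with_seed(seed, {
    levels <- c(day2 = 0.2, day6 = 0.5, day14 = 0.8)
    out <- list()
    for (cls in names(levels)) {
      for (i in seq_len(n_per_class)) {
        out[[length(out) + 1]] <-
          const_image(levels[[cls]] + stats::runif(1, 0, jitter), cls, size)
      }
    }
    out
  })
}

# Small GAN config used across GAN tests: 32-px, slim, quick.
tiny_gan_config <- function(epochs = 3, seed = 1, ...) {
  gan_config(image_size = 32, base_channels = 16, batch_size = 8,
             epochs = epochs, seed = seed, ...)
}

# Finite-difference gradient of f at x (small inputs only).
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
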