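# Shared fixtures built once per test run, and small numeric utilities.

.fixtures <- new.env(parent = emptyenv())

# A seeded synthetic dataset on disk, reused across test files.
shared_dataset <- function(n = 24, seed = 11, canvas = 256,
                           tumor_fraction = 0.5) {
  key <- sprintf("ds_%d_%d_%d_%s", n, seed, canvas, tumor_fraction)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), key)
    sp <- slide_spec(seed = seed, canvas_px = canvas,
                     tumor_fraction = tumor_fraction)
    .fixtures[[key]] <- generate_dataset(sp, n, dir)
  }
  .fixtures[[key]]
}

# Central-difference numeric gradient of scalar f at matrix/vector x.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-12)
}

random_simplex <- function(C) {
  x <- stats::rexp(C)
  x / sum(x)
}

# simple uniform-ish RGB test image
rand_image <- function(H, W = H, seed = 1) {
  histomulti:::with_seed(seed, array(stats::runif(H * W * 3), c(H, W, 3)))
}

# internal helpers exercised directly by the tests
block_mean <- histomulti:::block_mean
with_seed <- histomulti:::with_seed

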