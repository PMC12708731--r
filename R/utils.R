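#' @keywords internal
"_PACKAGE"

# Deterministic seed mixing; keeps results < 2^31 so they are valid R seeds.
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Row-wise numerically stable softmax; accepts a vector or a matrix.
softmax <- function(z) {
  if (is.null(dim(z))) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

as_prob_matrix <- function(P) {
  if (is.null(dim(P))) matrix(P, nrow = 1) else as.matrix(P)
}

# Block mean over f x f blocks of a matrix or H x W x C array.
block_mean <- function(x, f) {
  if (length(dim(x)) == 3) {
    out <- array(0, c(dim(x)[1] %/% f, dim(x)[2] %/% f, dim(x)[3]))
    for (ch in seq_len(dim(x)[3])) out[, , ch] <- block_mean(x[, , ch], f)
    return(out)
  }
  H <- nrow(x) %/% f
  W <- ncol(x) %/% f
  x <- x[seq_len(H * f), seq_len(W * f), drop = FALSE]
  # sum over row-blocks, then column-blocks
  rb <- rowsum(x, rep(seq_len(H), each = f))
  cb <- t(rowsum(t(rb), rep(seq_len(W), each = f)))
  cb / (f * f)
}

block_max <- function(x, f) {
  H <- nrow(x) %/% f
  W <- ncol(x) %/% f
  out <- matrix(0, H, W)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    sub <- x[seq(i, by = f, length.out = H), seq(j, by = f, length.out = W)]
    out <- pmax(out, sub)
  }
  out
}

# Separable box blur with edge clamping; radius r in pixels.
blur_box <- function(m, r) {
  if (r < 1) return(m)
  k <- 2 * r + 1
  sm <- function(v) {
    p <- c(rep(v[1], r), v, rep(v[length(v)], r))
    cs <- cumsum(p)
    (cs[k:length(p)] - c(0, cs[seq_len(length(p) - k)])) / k
  }
  m2 <- apply(m, 2, sm)
  t(apply(m2, 1, sm))
}

quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255) / 255

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3
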