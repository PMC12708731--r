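test_that("voronoi tessellation handles degenerate inputs", {
  m0 <- voronoi_morphometry(data.frame(x = numeric(0), y = numeric(0)), 16)
  expect_true(m0$empty_flag)
  expect_true(all(m0$channels == 0))

  m1 <- voronoi_morphometry(data.frame(x = 7, y = 7), 16)
  expect_false(m1$empty_flag)
  expect_true(all(m1$channels[1, , ] == 0))  # constant area channel -> 0
  expect_true(all(m1$channels[3, , ] == 0))  # no neighbors
  expect_true(all(m1$regions == 1))
})

test_that("two-seed tessellation splits at the midline, matching the oracle", {
  n <- 16
  cen <- data.frame(x = c(0, n - 1), y = c(8, 8))
  m <- voronoi_morphometry(cen, n)
  # brute-force nearest-centroid oracle over every pixel
  oracle <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n) {
    d <- (c - 1 - cen$x)^2 + (r - 1 - cen$y)^2
    oracle[r, c] <- which.min(d)   # lowest index on ties
  }
  expect_identical(m$regions, oracle)
  expect_true(all(m$regions[, 1:8] == 1))
  expect_true(all(m$regions[, 9:16] == 2))
})

test_that("region areas sum to the patch area and match random oracles", {
  for (i in 1:10) {
    n <- 24
    k <- with_seed(i, sample(2:6, 1))
    cen <- with_seed(i + 20, data.frame(x = runif(k, 0, n - 1e-6),
                                        y = runif(k, 0, n - 1e-6)))
    m <- voronoi_morphometry(cen, n)
    areas <- tabulate(as.vector(m$regions), k)
    expect_equal(sum(areas), n * n)
    oracle <- matrix(0L, n, n)
    for (r in 1:n) for (c in 1:n)
      oracle[r, c] <- which.min((c - 1 - cen$x)^2 + (r - 1 - cen$y)^2)
    expect_identical(m$regions, oracle)
  }
})

test_that("morphometry maps export as 16-bit TIFF", {
  cen <- data.frame(x = c(3, 12), y = c(4, 10))
  m <- voronoi_morphometry(cen, 16)
  path <- tempfile(fileext = ".tiff")
  export_morphometry_tiff(m, path)
  back <- tiff::readTIFF(path)
  expect_equal(dim(back), c(16, 16, 3))
  expect_equal(back[, , 2], m$channels[2, , ], tolerance = 1e-4)
})

test_that("cross-modal attention degenerates correctly", {
  P <- attention_params(4, 3, seed = 1)
  E_img <- with_seed(2, matrix(rnorm(8), 2, 4))

  # all morph tokens identical -> uniform rows, F rows equal that V projection
  tok <- with_seed(3, rnorm(4))
  E_m <- rbind(tok, tok, tok)
  out <- cross_modal_attention(E_img, E_m, P)
  expect_equal(out$attn, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(out$F[1, ], as.numeric(tok %*% P$W_V), tolerance = 1e-12)

  # single morph token -> F = its V projection regardless of Q
  out1 <- cross_modal_attention(E_img, matrix(tok, 1), P)
  expect_equal(out1$F, rbind(tok %*% P$W_V, tok %*% P$W_V),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cross_modal_attention(E_img, matrix(rnorm(6), 2, 3), P),
               "mismatch")
})

test_that("fusion equals the explicit-loop oracle (hand case and random)", {
  # 2 image x 3 morph tokens, identity projections, d_k = 2
  P <- structure(list(W_Q = diag(2), W_K = diag(2), W_V = diag(2), d_k = 2L),
                 class = "attention_params")
  E_img <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  E_m <- matrix(c(1, 0, 0, 1, 1, 1), 3, byrow = TRUE)
  out <- cross_modal_attention(E_img, E_m, P)
  for (i in 1:2) {
    s <- numeric(3)
    for (k in 1:3) s[k] <- sum(E_img[i, ] * E_m[k, ]) / sqrt(2)
    a <- exp(s) / sum(exp(s))
    Fi <- rep(0, 2)
    for (k in 1:3) Fi <- Fi + a[k] * E_m[k, ]
    expect_equal(out$F[i, ], Fi, tolerance = 1e-12)
  }

  for (r in 1:20) {
    ni <- with_seed(r, sample(1:8, 1)); nm <- with_seed(r + 1, sample(1:8, 1))
    d <- 4; dk <- 3
    Pr <- attention_params(d, dk, seed = r)
    Ei <- with_seed(r + 2, matrix(rnorm(ni * d), ni))
    Em <- with_seed(r + 3, matrix(rnorm(nm * d), nm))
    out <- cross_modal_attention(Ei, Em, Pr)
    Q <- Ei %*% Pr$W_Q; K <- Em %*% Pr$W_K; V <- Em %*% Pr$W_V
    Fo <- matrix(0, ni, dk)
    for (i in seq_len(ni)) {
      s <- numeric(nm)
      for (k in seq_len(nm)) s[k] <- sum(Q[i, ] * K[k, ]) / sqrt(dk)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (k in seq_len(nm)) Fo[i, ] <- Fo[i, ] + a[k] * V[k, ]
    }
    expect_equal(out$F, Fo, tolerance = 1e-9)
    # permutation of morph tokens leaves F unchanged
    pm <- with_seed(r + 4, sample(nm))
    expect_equal(cross_modal_attention(Ei, Em[pm, , drop = FALSE], Pr)$F,
                 out$F, tolerance = 1e-9)
  }
})

test_that("classifier head behaves per closed forms", {
  hz <- classifier_head(3, 4, 3, zero = TRUE)
  expect_equal(classify(matrix(rnorm(6), 2, 3), hz), rep(1 / 3, 3))

  hd <- classifier_head(5, 8, 4, seed = 2)
  p <- classify(with_seed(3, matrix(rnorm(10), 2, 5)), hd)
  expect_equal(sum(p), 1, tolerance = 1e-6)

  # hand-set binary head: pooled scalar x -> logits (x, -x) -> sigma(2x)
  hb <- structure(list(W1 = matrix(c(1, -1), 1), b1 = c(0, 0),
                       W2 = matrix(c(1, -1, -1, 1), 2, byrow = TRUE),
                       b2 = c(0, 0)), class = "classifier_head")
  for (x in c(-1.3, -0.2, 0.4, 2.5)) {
    p <- classify(matrix(x, 1, 1), hb)
    expect_equal(p[1], 1 / (1 + exp(-2 * x)), tolerance = 1e-12)
  }
})

test_that("fused cross-entropy gradients pass finite-difference checks", {
  d <- 4; dk <- 3
  P <- attention_params(d, dk, seed = 5)
  head <- classifier_head(dk, 5, 2, seed = 6)
  E_img <- with_seed(7, matrix(rnorm(3 * d), 3))
  E_m <- with_seed(8, matrix(rnorm(4 * d), 4))
  g <- histomulti:::tdmm_ce_grad(E_img, E_m, P, head, label = 2L)
  for (nm in c("W_Q", "W_K", "W_V")) {
    f <- function(x) {
      P2 <- P; P2[[nm]] <- x
      histomulti:::tdmm_ce_grad(E_img, E_m, P2, head, 2L)$loss
    }
    expect_lt(rel_err(g[[paste0("d", nm)]], num_grad(f, P[[nm]])), 1e-4)
  }
  fW1 <- function(x) {
    h2 <- head; h2$W1 <- x
    histomulti:::tdmm_ce_grad(E_img, E_m, P, h2, 2L)$loss
  }
  expect_lt(rel_err(g$dW1, num_grad(fW1, head$W1)), 1e-4)
})
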