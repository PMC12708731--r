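test_that("cosine similarity closed forms", {
  a <- c(0.3, -1.2, 2)
  expect_equal(cosine_sim(a, a), 1)
  expect_equal(cosine_sim(a, -a), -1)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_sim(2 * a, 5 * a), 1)   # scale invariance
  expect_error(cosine_sim(c(0, 0), a), "zero")
})

test_that("uniform combined scores give loss ln N exactly", {
  n <- 5
  z <- matrix(rep(c(1, 2, 0.5), each = n), n)     # identical embeddings
  p <- matrix(0.5, n, 2)                          # centered -> positional 0
  b <- contrastive_batch(z, z, p, gamma = 0.3, tau = 0.07)
  expect_equal(cccra_loss(b), log(n), tolerance = 1e-9)
})

test_that("hand-computed softmax case with scores (2, 0, 0)", {
  # orthonormal embeddings, gamma 0, tau 0.5: scores are 2 for the positive,
  # 0 for the two negatives, for every anchor
  z <- diag(3)
  p <- matrix(0.5, 3, 2)
  b <- contrastive_batch(z, z, p, gamma = 0, tau = 0.5)
  expect_equal(cccra_loss(b), -log(exp(2) / (exp(2) + 2)), tolerance = 1e-12)
})

test_that("gamma = 0 agrees with an independent plain InfoNCE oracle", {
  for (r in 1:10) {
    n <- with_seed(r, sample(3:8, 1)); d <- 5
    z10 <- with_seed(r + 10, matrix(rnorm(n * d), n))
    z40 <- with_seed(r + 20, matrix(rnorm(n * d), n))
    p <- with_seed(r + 30, matrix(runif(n * 2), n))
    tau <- 0.07
    b <- contrastive_batch(z10, z40, p, gamma = 0, tau = tau)
    # oracle: explicit loops, textbook InfoNCE on cosine similarities
    csim <- function(a, bb) sum(a * bb) / sqrt(sum(a^2) * sum(bb^2))
    tot <- 0
    for (i in 1:n) {
      s <- vapply(1:n, function(k) csim(z10[i, ], z40[k, ]) / tau, 0)
      tot <- tot - log(exp(s[i]) / sum(exp(s)))
    }
    expect_equal(cccra_loss(b), tot / n, tolerance = 1e-9)
  }
})

test_that("raising the positive similarity never increases the loss", {
  n <- 4; d <- 6
  z10 <- with_seed(1, matrix(rnorm(n * d), n))
  z40 <- with_seed(2, matrix(rnorm(n * d), n))
  p <- with_seed(3, matrix(runif(n * 2), n))
  losses <- vapply(seq(0, 1, 0.25), function(w) {
    z40w <- (1 - w) * z40 + w * z10   # pull positives toward anchors
    cccra_loss(contrastive_batch(z10, z40w, p))
  }, 0)
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("positions carry signal when embeddings are uninformative", {
  n <- 6
  z <- matrix(rep(c(1, 1), each = n), n)   # all-equal embeddings
  pos <- with_seed(4, matrix(runif(n * 2, 0.05, 0.95), n))
  losses <- vapply(c(0, 0.15, 0.3, 0.6), function(g)
    cccra_loss(contrastive_batch(z, z, pos, pos, gamma = g, tau = 0.5)), 0)
  expect_equal(losses[1], log(n), tolerance = 1e-9)
  expect_true(all(diff(losses) < 0))   # strictly decreasing in gamma
})

test_that("embedding gradients match finite differences", {
  n <- 4; d <- 5
  z10 <- with_seed(5, matrix(rnorm(n * d), n))
  z40 <- with_seed(6, matrix(rnorm(n * d), n))
  p <- with_seed(7, matrix(runif(n * 2), n))
  b <- contrastive_batch(z10, z40, p, gamma = 0.3, tau = 0.2)
  g <- cccra_grad(b)
  f10 <- function(z) cccra_loss(contrastive_batch(z, z40, p, gamma = 0.3,
                                                  tau = 0.2))
  f40 <- function(z) cccra_loss(contrastive_batch(z10, z, p, gamma = 0.3,
                                                  tau = 0.2))
  expect_lt(rel_err(g$dz10, num_grad(f10, z10)), 1e-4)
  expect_lt(rel_err(g$dz40, num_grad(f40, z40)), 1e-4)
})

test_that("batch validation catches degenerate inputs", {
  z <- matrix(rnorm(4), 2)
  p <- matrix(0.5, 2, 2)
  expect_error(contrastive_batch(z[1, , drop = FALSE], z[1, , drop = FALSE],
                                 p[1, , drop = FALSE]), "2 entities")
  expect_error(contrastive_batch(z, z, p, tau = 0), "tau")
  zz <- z; zz[1, ] <- 0
  expect_error(contrastive_batch(zz, z, p), "zero")
})

test_that("optimizing the contrastive loss aligns paired embeddings", {
  # tiny two-branch linear projections trained by gradient descent
  n <- 12; d <- 6; dz <- 4
  F10 <- with_seed(8, matrix(rnorm(n * d), n))
  F40 <- F10 + with_seed(9, matrix(rnorm(n * d, sd = 0.3), n))
  pos <- with_seed(10, matrix(runif(n * 2), n))
  improved <- vapply(1:5, function(sd) {
    W10 <- with_seed(sd, matrix(rnorm(d * dz, sd = 0.3), d))
    W40 <- with_seed(sd + 50, matrix(rnorm(d * dz, sd = 0.3), d))
    pair_cos <- function() {
      z10 <- F10 %*% W10; z40 <- F40 %*% W40
      mean(vapply(1:n, function(i) cosine_sim(z10[i, ], z40[i, ]), 0))
    }
    before <- pair_cos()
    for (step in 1:200) {
      g <- cccra_grad(contrastive_batch(F10 %*% W10, F40 %*% W40, pos,
                                        gamma = 0.3, tau = 0.2))
      W10 <- W10 - 0.5 * t(F10) %*% g$dz10
      W40 <- W40 - 0.5 * t(F40) %*% g$dz40
    }
    pair_cos() > before
  }, TRUE)
  expect_gte(sum(improved), 4)
})
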