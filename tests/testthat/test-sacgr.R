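# small helpers for hand-built graphs
diag_blocks_mass <- function(M, t2n) {
  s <- 0
  for (a in seq_along(t2n)) for (b in seq_along(t2n))
    if (t2n[a] == t2n[b]) s <- s + M[a, b]
  s
}

grid_labels <- function(H, k) {
  img <- array(0.5, c(H, H, 3))
  generate_superpixels(img, k * k, "grid")
}

test_that("tissue graph on a constant 2x2 tiling has symmetric 0.5 weights", {
  lab <- grid_labels(8, 2)
  img <- array(0.5, c(8, 8, 3))
  G <- build_tissue_graph(lab, img)
  expect_equal(G$n_nodes, 4)
  for (i in 1:4) {
    expect_equal(sum(G$A[i, ] > 0), 2)            # corner nodes: 2 neighbors
    expect_equal(unname(G$A[i, G$A[i, ] > 0]), c(0.5, 0.5))
  }
  expect_true(isSymmetric(G$W))
  expect_true(all(diag(G$A) == 0))
})

test_that("a single superpixel yields a 1x1 zero graph", {
  lab <- matrix(0L, 6, 6)
  G <- build_tissue_graph(lab, array(0.2, c(6, 6, 3)))
  expect_equal(G$n_nodes, 1)
  expect_equal(G$W, matrix(0, 1, 1))
})

test_that("edge weights follow the Gaussian color kernel", {
  # three vertical stripes: black, black, white; bandwidth 100
  lab <- matrix(rep(c(0L, 1L, 2L), each = 4), 12, 12, byrow = TRUE)
  img <- array(0, c(12, 12, 3))
  img[, 9:12, ] <- 1
  G <- build_tissue_graph(lab, img, color_bandwidth = 100)
  expect_gt(G$W[1, 2], G$W[2, 3])
  expect_equal(G$W[1, 2] / G$W[2, 3], exp(3 * 255^2 / (2 * 100^2)),
               tolerance = 1e-9)
  expect_error(build_tissue_graph(matrix(c(0L, 2L), 1), array(0, c(1, 2, 3))),
               "contiguous")
})

test_that("sparsification caps each row at max_neighbors", {
  lab <- grid_labels(32, 4)      # 16 nodes
  img <- rand_image(32, seed = 6)
  G <- build_tissue_graph(lab, img, max_neighbors = 2)
  expect_true(all(rowSums(G$W > 0) <= 4))  # 2 kept + possible re-symmetrized
  G8 <- build_tissue_graph(lab, img, max_neighbors = 8)
  expect_true(all(rowSums(G8$W > 0) <= 8))
})

test_that("token assignment picks the majority superpixel with low-id ties", {
  lab <- grid_labels(64, 4)                 # aligned with 16 x 16 tokens
  asg <- assign_tokens(lab, c(4, 4), 16)
  # aligned grids: token k sits exactly over superpixel under it
  expect_equal(sort(asg$token_to_node), 0:15)

  const <- matrix(0L, 32, 32)
  expect_true(all(assign_tokens(const, c(2, 2), 16)$token_to_node == 0))

  # 60/40 split inside one token footprint
  lab2 <- matrix(0L, 16, 16)
  lab2[, 1:6] <- 1L   # 40% of columns... 6/16 = 37.5% label 1
  lab2[1, 16] <- 1L
  asg2 <- assign_tokens(lab2, c(1, 1), 16)
  counts <- table(lab2)
  expect_equal(asg2$token_to_node, as.integer(names(which.max(counts))))
  expect_error(assign_tokens(lab2, c(2, 2), 16), "match")
})

test_that("attention pooling equals a brute-force token-pair oracle", {
  # hand case: 4 tokens, 2 nodes
  attn <- matrix(c(0.4, 0.3, 0.2, 0.1,
                   0.1, 0.6, 0.2, 0.1,
                   0.25, 0.25, 0.25, 0.25,
                   0.05, 0.05, 0.2, 0.7), 4, 4, byrow = TRUE)
  arr <- array(0, c(1, 4, 4)); arr[1, , ] <- attn
  asg <- structure(list(token_to_node = c(0L, 0L, 1L, 1L),
                        n_tokens = 4L, n_nodes = 2L),
                   class = "token_assignment")
  aa <- attention_adjacency(list(arr), asg)
  M <- (attn + t(attn)) / 2
  oracle <- matrix(0, 2, 2)
  for (i in 0:1) for (j in 0:1) {
    ta <- which(asg$token_to_node == i); tb <- which(asg$token_to_node == j)
    s <- 0
    for (a in ta) for (b in tb) s <- s + M[a, b]
    oracle[i + 1, j + 1] <- s / (length(ta) * length(tb))
  }
  diag(oracle) <- 0
  expect_equal(aa$B_raw, oracle, tolerance = 1e-12)
  norm <- oracle / rowSums(oracle)
  expect_equal(aa$A_attn, norm, tolerance = 1e-12)

  # uniform attention with equal-size nodes -> uniform off-diagonal rows
  u <- array(1 / 4, c(1, 4, 4))
  au <- attention_adjacency(list(u), asg)
  off <- au$A_attn[row(au$A_attn) != col(au$A_attn)]
  expect_true(all(abs(off - off[1]) < 1e-12))

  # one token per node: pooling is identity on symmetrized zero-diagonal
  asg1 <- structure(list(token_to_node = 0:3, n_tokens = 4L, n_nodes = 4L),
                    class = "token_assignment")
  a1 <- attention_adjacency(list(arr), asg1)
  Mz <- M; diag(Mz) <- 0
  expect_equal(a1$B_raw, Mz, tolerance = 1e-12)
})

test_that("random attention pooling matches the oracle on many instances", {
  for (i in 1:25) {
    n_tok <- with_seed(i, sample(4:16, 1))
    n_nod <- with_seed(i + 1, sample(2:4, 1))
    attn <- with_seed(i + 2, {
      m <- matrix(rexp(n_tok * n_tok), n_tok)
      m / rowSums(m)
    })
    t2n <- with_seed(i + 3,
                     c(0:(n_nod - 1), sample(0:(n_nod - 1),
                                             n_tok - n_nod, replace = TRUE)))
    asg <- structure(list(token_to_node = t2n, n_tokens = n_tok,
                          n_nodes = n_nod), class = "token_assignment")
    arr <- array(0, c(1, n_tok, n_tok)); arr[1, , ] <- attn
    aa <- attention_adjacency(list(arr), asg)
    M <- (attn + t(attn)) / 2
    oracle <- matrix(0, n_nod, n_nod)
    for (a in seq_len(n_tok)) for (b in seq_len(n_tok))
      oracle[t2n[a] + 1, t2n[b] + 1] <- oracle[t2n[a] + 1, t2n[b] + 1] + M[a, b]
    cnt <- tabulate(t2n + 1, n_nod)
    oracle <- oracle / outer(cnt, cnt)
    diag(oracle) <- 0
    expect_equal(aa$B_raw, oracle, tolerance = 1e-9)
    # mass conservation of the pooled (pre-normalization) matrix
    expect_equal(sum(aa$B_raw * outer(cnt, cnt)),
                 sum(M) - sum(diag_blocks_mass(M, t2n)), tolerance = 1e-9)
  }
})

test_that("structural loss is the mean squared off-diagonal difference", {
  lab <- grid_labels(8, 2)
  G <- build_tissue_graph(lab, array(0.5, c(8, 8, 3)))
  expect_equal(sacgr_loss(G, G$A), 0)

  G2 <- list(n_nodes = 2, A = matrix(c(0, 1, 1, 0), 2))
  expect_equal(sacgr_loss(G2, matrix(0, 2, 2)), 1)

  A_attn <- G$A
  eps <- 1e-3
  A_attn[1, 2] <- A_attn[1, 2] + eps
  n <- G$n_nodes
  expect_equal(sacgr_loss(G, A_attn), eps^2 / (n * (n - 1)), tolerance = 1e-12)
})

test_that("structural loss is invariant to consistent node relabeling", {
  lab <- grid_labels(16, 3)
  img <- rand_image(16, seed = 7)
  G <- build_tissue_graph(lab, img)
  n <- G$n_nodes
  A_attn <- with_seed(8, {
    m <- matrix(rexp(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 0
    m / rowSums(m)
  })
  l0 <- sacgr_loss(G, A_attn)
  perm <- with_seed(9, sample(n))
  Gp <- G; Gp$A <- G$A[perm, perm]
  expect_equal(sacgr_loss(Gp, A_attn[perm, perm]), l0, tolerance = 1e-12)
})

test_that("attention-path gradient of the structural loss passes FD check", {
  lab <- grid_labels(32, 2)
  G <- build_tissue_graph(lab, rand_image(32, seed = 10))
  asg <- assign_tokens(lab, c(2, 2), 16)
  Tm <- with_seed(11, { m <- matrix(rexp(16), 4); m / rowSums(m) })
  sg <- histomulti:::sacgr_grad_token_attn(G, Tm, asg)
  f <- function(T_) histomulti:::sacgr_grad_token_attn(G, T_, asg)$loss
  expect_lt(rel_err(sg$dT, num_grad(f, Tm)), 1e-4)
})

test_that("smoothness loss matches a brute-force edge loop and its FD grad", {
  lab <- grid_labels(32, 2)
  G <- build_tissue_graph(lab, rand_image(32, seed = 12))
  asg <- assign_tokens(lab, c(2, 2), 16)

  feats_const <- matrix(1, 4, 5)
  expect_equal(smoothness_loss(feats_const, asg, G), 0)

  # 2 nodes, unit weight, unit feature distance
  G2 <- list(n_nodes = 2, W = matrix(c(0, 1, 1, 0), 2))
  asg2 <- structure(list(token_to_node = c(0L, 1L), n_tokens = 2L,
                         n_nodes = 2L), class = "token_assignment")
  f2 <- rbind(rep(0, 3), c(1, 0, 0))
  expect_equal(smoothness_loss(f2, asg2, G2), 1)

  feats <- with_seed(13, matrix(rnorm(4 * 6), 4, 6))
  got <- smoothness_loss(feats, asg, G)
  S <- histomulti:::node_indicator(asg)
  Fm <- (S %*% feats) / rowSums(S)
  num <- 0; den <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    num <- num + G$W[i, j] * sum((Fm[i, ] - Fm[j, ])^2)
    den <- den + G$W[i, j]
  }
  expect_equal(got, num / den, tolerance = 1e-12)

  sg <- histomulti:::smoothness_grad_tokens(feats, asg, G)
  f <- function(x) smoothness_loss(x, asg, G)
  expect_lt(rel_err(sg$dF, num_grad(f, feats)), 1e-4)
})

test_that("graph exports round-trip through JSON and CSV", {
  lab <- grid_labels(16, 2)
  G <- build_tissue_graph(lab, rand_image(16, seed = 14))
  ej <- tempfile(fileext = ".json"); nc <- tempfile(fileext = ".csv")
  edges <- export_tissue_graph(G, ej, nc)
  back <- jsonlite::read_json(ej, simplifyVector = TRUE)
  expect_equal(nrow(back), nrow(edges))
  nodes <- read.csv(nc)
  expect_equal(nrow(nodes), G$n_nodes)
})
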