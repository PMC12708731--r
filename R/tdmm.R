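#' Voronoi nuclear morphometry map
#'
#' Assigns every pixel to its nearest nucleus centroid (Euclidean; ties to
#' the lowest centroid index) — an exact discrete Voronoi tessellation —
#' and derives three per-pixel channels: (1) area of the owning region,
#' (2) distance to the nearest centroid, (3) number of distinct regions
#' 4-adjacent to the owning region. Each channel is min-max normalized to
#' `[0,1]` over the patch (a constant channel normalizes to 0). With no
#' centroids the map is all-zero and flagged empty.
#'
#' @param centroids Data frame with 0-based `x`, `y` columns.
#' @param patch_px Patch side (>= 1).
#' @return `morphometry_map` list: `channels` (`3 x H x W`), `regions`
#'   (pixel-to-centroid index matrix, 1-based; 0 when empty),
#'   `empty_flag`.
#' @export
voronoi_morphometry <- function(centroids, patch_px) {
  if (patch_px < 1) stop_invalid("patch_px must be >= 1")
  H <- W <- patch_px
  if (is.null(centroids) || nrow(centroids) == 0) {
    return(structure(list(channels = array(0, c(3, H, W)),
                          regions = matrix(0L, H, W), empty_flag = TRUE),
                     class = "morphometry_map"))
  }
  px_y <- rep(0:(H - 1), times = W)
  px_x <- rep(0:(W - 1), each = H)
  nc <- nrow(centroids)
  best_d <- rep(Inf, H * W)
  owner <- integer(H * W)
  for (k in seq_len(nc)) {      # ascending k, strict < keeps lowest index on ties
    d <- (px_x - centroids$x[k])^2 + (px_y - centroids$y[k])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    owner[upd] <- k
  }
  regions <- matrix(owner, H, W)
  area_per <- tabulate(owner, nc)
  # neighbor count: distinct regions 4-adjacent to each region
  nb <- matrix(FALSE, nc, nc)
  if (nc > 1) {
    a <- regions[-H, ]; b <- regions[-1, ]; d <- a != b
    if (any(d)) nb[cbind(a[d], b[d])] <- TRUE
    a <- regions[, -W]; b <- regions[, -1]; d <- a != b
    if (any(d)) nb[cbind(a[d], b[d])] <- TRUE
    nb <- nb | t(nb)
  }
  nbc <- rowSums(nb)
  mm <- function(m) {
    r <- range(m)
    if (r[2] - r[1] < 1e-12) return(m * 0)
    (m - r[1]) / (r[2] - r[1])
  }
  ch <- array(0, c(3, H, W))
  ch[1, , ] <- mm(matrix(area_per[owner], H, W))
  ch[2, , ] <- mm(matrix(sqrt(best_d), H, W))
  ch[3, , ] <- mm(matrix(nbc[owner], H, W))
  structure(list(channels = ch, regions = regions, empty_flag = FALSE),
            class = "morphometry_map")
}

#' Export a morphometry map as a 16-bit 3-channel TIFF
#' @param map A `morphometry_map`.
#' @param path Output path.
#' @export
export_morphometry_tiff <- function(map, path) {
  arr <- aperm(map$channels, c(2, 3, 1))
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  invisible(path)
}

#' Cross-modal attention parameters
#' @param d Shared embedding dimension of both modalities.
#' @param d_k Key/value projection dimension (>= 1).
#' @param seed Initialization seed.
#' @return `attention_params` list: `W_Q`, `W_K`, `W_V` (`d x d_k`), `d_k`.
#' @export
attention_params <- function(d, d_k, seed = 1L) {
  if (d_k < 1) stop_invalid("d_k must be >= 1")
  with_seed(mix_seed(seed, 29L),
            structure(list(W_Q = rand_mat(d, d_k, 1 / sqrt(d)),
                           W_K = rand_mat(d, d_k, 1 / sqrt(d)),
                           W_V = rand_mat(d, d_k, 1 / sqrt(d)),
                           d_k = as.integer(d_k)),
                      class = "attention_params"))
}

#' Cross-modal scaled-dot-product attention fusion
#'
#' `F = softmax(Q K' / sqrt(d_k)) V` with `Q = E_img W_Q`,
#' `K = E_morph W_K`, `V = E_morph W_V`: every image token attends over the
#' morphometry tokens, so the fused embedding has one row per image token
#' and is invariant to permutations of the morphometry tokens.
#'
#' @param E_img `n_img x d` image-token embeddings.
#' @param E_morph `n_morph x d` morphometry-token embeddings.
#' @param P An [attention_params()].
#' @return List `F` (`n_img x d_k`) and `attn` (`n_img x n_morph`).
#' @export
cross_modal_attention <- function(E_img, E_morph, P) {
  if (ncol(E_img) != nrow(P$W_Q) || ncol(E_morph) != nrow(P$W_K))
    stop_invalid("embedding dimension mismatch")
  Q <- E_img %*% P$W_Q
  K <- E_morph %*% P$W_K
  V <- E_morph %*% P$W_V
  A <- softmax(Q %*% t(K) / sqrt(P$d_k))
  if (is.null(dim(A))) A <- matrix(A, nrow = nrow(Q))
  dimnames(A) <- NULL
  list(F = unname(A %*% V), attn = A)
}

#' Two-layer perceptron classifier head
#' @param d_in Input dimension (fused embedding width).
#' @param hidden Hidden units.
#' @param n_classes Number of classes.
#' @param seed Initialization seed; `zero = TRUE` gives an all-zero head
#'   (uniform output).
#' @param zero Zero-initialize all weights.
#' @return `classifier_head` list `W1`, `b1`, `W2`, `b2`.
#' @export
classifier_head <- function(d_in, hidden = 32L, n_classes = 2L, seed = 1L,
                            zero = FALSE) {
  if (zero)
    return(structure(list(W1 = matrix(0, d_in, hidden), b1 = rep(0, hidden),
                          W2 = matrix(0, hidden, n_classes),
                          b2 = rep(0, n_classes)),
                     class = "classifier_head"))
  with_seed(mix_seed(seed, 31L),
            structure(list(W1 = rand_mat(d_in, hidden), b1 = rep(0, hidden),
                           W2 = rand_mat(hidden, n_classes, 1 / sqrt(hidden)),
                           b2 = rep(0, n_classes)),
                      class = "classifier_head"))
}

#' Classify a fused embedding
#'
#' Mean-pools the fused token rows, applies the two-layer ReLU perceptron
#' and a softmax.
#'
#' @param F Fused embedding (`n_img x d_k` matrix or the list returned by
#'   [cross_modal_attention()]).
#' @param head A [classifier_head()].
#' @return Class probability vector (sums to 1).
#' @export
classify <- function(F, head) {
  Fm <- if (is.list(F) && !is.null(F$F)) F$F else F
  x <- colMeans(as_prob_matrix(Fm) * 1)  # plain matrix mean-pool
  if (length(x) != nrow(head$W1)) stop_invalid("dimension mismatch")
  h <- pmax(as.numeric(x %*% head$W1) + head$b1, 0)
  z <- as.numeric(h %*% head$W2) + head$b2
  softmax(z)
}

# Fused classification loss (cross-entropy) with analytic gradients w.r.t.
# W_Q, W_K, W_V and the classifier head. `label` is a 1-based class index.
tdmm_ce_grad <- function(E_img, E_morph, P, head, label) {
  Q <- E_img %*% P$W_Q; K <- E_morph %*% P$W_K; V <- E_morph %*% P$W_V
  sc <- 1 / sqrt(P$d_k)
  S <- Q %*% t(K) * sc
  A <- softmax(S)
  if (is.null(dim(A))) A <- matrix(A, nrow = nrow(Q))
  F_ <- A %*% V
  x <- colMeans(F_)
  h_pre <- as.numeric(x %*% head$W1) + head$b1
  h <- pmax(h_pre, 0)
  z <- as.numeric(h %*% head$W2) + head$b2
  p <- softmax(z)
  loss <- -log(max(p[label], 1e-12))

  dz <- p
  dz[label] <- dz[label] - 1
  dW2 <- outer(h, dz)
  db2 <- dz
  dh <- as.numeric(head$W2 %*% dz) * (h_pre > 0)
  dW1 <- outer(x, dh)
  db1 <- dh
  dx <- as.numeric(head$W1 %*% dh)
  dF <- matrix(rep(dx / nrow(F_), each = nrow(F_)), nrow(F_))
  dA <- dF %*% t(V)
  dV <- t(A) %*% dF
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% K * sc
  dK <- t(dS) %*% Q * sc
  list(loss = loss, probs = p,
       dW_Q = t(E_img) %*% dQ, dW_K = t(E_morph) %*% dK,
       dW_V = t(E_morph) %*% dV,
       dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}
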