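#' Cosine similarity
#'
#' `sim(a, b) = a'b / (||a|| ||b||)`; symmetric and scale-invariant.
#' Errors on (near-)zero vectors.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na <= 1e-12 || nb <= 1e-12) stop_invalid("zero vector in cosine_sim")
  max(min(sum(a * b) / (na * nb), 1), -1)
}

# row-wise cosine similarity matrix between the rows of A and B; rows with
# (near-)zero norm yield similarity 0 (used for the centered positions of
# patches sitting exactly at the virtual-slide center).
cos_matrix <- function(A, B, zero_ok = FALSE) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (!zero_ok && (any(na <= 1e-12) || any(nb <= 1e-12)))
    stop_invalid("zero embedding vector")
  S <- (A %*% t(B)) / (pmax(na, 1e-12) %o% pmax(nb, 1e-12))
  if (zero_ok) {
    S[na <= 1e-12, ] <- 0
    S[, nb <= 1e-12] <- 0
  }
  S
}

#' Build a cross-magnification contrastive batch
#'
#' One row per entity: `z10`/`z40` are the two views' embeddings of the
#' same entity, `p10`/`p40` their positions (normalized `(row, col)` in
#' `[0,1]^2`). Positions are centered at `(0.5, 0.5)` before cosine
#' similarity so that raw coordinates do not degenerate to all-positive
#' similarities; an entity exactly at the center gets positional
#' similarity 0 to every candidate.
#'
#' @param z10,z40 `n x d` embedding matrices (non-zero rows, `n >= 2`).
#' @param p10,p40 `n x 2` position matrices; default both views share the
#'   same position.
#' @param gamma Positional sensitivity (>= 0; default 0.3).
#' @param tau InfoNCE temperature (> 0; default 0.07).
#' @return `contrastive_batch` list.
#' @export
contrastive_batch <- function(z10, z40, p10, p40 = p10, gamma = 0.3,
                              tau = 0.07) {
  z10 <- as.matrix(z10); z40 <- as.matrix(z40)
  p10 <- as.matrix(p10); p40 <- as.matrix(p40)
  if (nrow(z10) < 2) stop_invalid("need at least 2 entities per batch")
  if (nrow(z10) != nrow(z40) || nrow(z10) != nrow(p10))
    stop_invalid("row count mismatch")
  if (tau <= 0) stop_invalid("tau must be > 0")
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  if (any(sqrt(rowSums(z10^2)) <= 1e-12) || any(sqrt(rowSums(z40^2)) <= 1e-12))
    stop_invalid("zero embedding vector")
  structure(list(z10 = z10, z40 = z40, p10 = p10, p40 = p40,
                 gamma = gamma, tau = tau),
            class = "contrastive_batch")
}

#' Positional InfoNCE loss across magnifications
#'
#' For each anchor `i` (10x view), candidates are all entities' 40x views;
#' the combined score of candidate `k` is
#' `(sim(z10_i, z40_k) + gamma * sim(p10_i, p40_k)) / tau` and the loss is
#' the mean over anchors of `-log softmax` at the positive `k = i`. The
#' temperature divides both similarity terms (the standard InfoNCE form);
#' the denominator includes the positive.
#'
#' @param batch A [contrastive_batch()].
#' @return Non-negative scalar; `log(n)` when all combined scores are
#'   equal, approaching 0 as the positive dominates.
#' @export
cccra_loss <- function(batch) {
  cccra_grad(batch)$loss
}

#' Positional InfoNCE loss with analytic embedding gradients
#'
#' Same value as [cccra_loss()], plus gradients with respect to both
#' embedding matrices (positions are treated as data).
#'
#' @param batch A [contrastive_batch()].
#' @return List `loss`, `dz10`, `dz40`.
#' @export
cccra_grad <- function(batch) {
  n <- nrow(batch$z10)
  Se <- cos_matrix(batch$z10, batch$z40)
  Sp <- cos_matrix(batch$p10 - 0.5, batch$p40 - 0.5, zero_ok = TRUE)
  S <- (Se + batch$gamma * Sp) / batch$tau
  m <- apply(S, 1, max)
  E <- exp(S - m)
  soft <- E / rowSums(E)
  loss <- mean(-(S[cbind(1:n, 1:n)] - m - log(rowSums(E))))
  # dL/dS = (softmax - I) / n; chain through cosine rows
  dS <- (soft - diag(n)) / n / batch$tau
  na <- sqrt(rowSums(batch$z10^2)); nb <- sqrt(rowSums(batch$z40^2))
  A <- batch$z10 / na; B <- batch$z40 / nb       # unit rows
  # d sim(a_i, b_k) / d a_i = (b_k_hat - sim * a_i_hat) / ||a_i||
  dz10 <- (dS %*% B - rowSums(dS * Se) * A) / na
  dz40 <- (t(dS) %*% A - colSums(dS * Se) * B) / nb
  list(loss = loss, dz10 = dz10, dz40 = dz40)
}
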