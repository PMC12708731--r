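#' Dice coefficient between two binary masks
#'
#' `2 |P & T| / (|P| + |T|)`; both masks empty gives 1 by convention.
#' Symmetric in its arguments.
#'
#' @param pred_mask,true_mask Binary arrays of the same shape.
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(pred_mask, true_mask) {
  if (!all(dim(as.matrix(pred_mask)) == dim(as.matrix(true_mask))))
    stop_invalid("mask shape mismatch")
  p <- as.logical(pred_mask); t <- as.logical(true_mask)
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1.0)
  2 * sum(p & t) / denom
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation using midranks, so ties count 0.5; equals the
#' trapezoidal ROC area and is invariant to strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_invalid("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normalized mutual information between two label vectors
#'
#' `I(U;V) / sqrt(H(U) H(V))`; 1 for identical partitions up to
#' relabeling, 0 for independent ones. Two constant partitions give 1 by
#' convention (zero entropies).
#'
#' @param labels1,labels2 Equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) stop_invalid("length mismatch")
  tab <- table(labels1, labels2)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  hu <- ent(pi_); hv <- ent(pj_)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pj_))
    if (pij[i, j] > 0)
      mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  min(1, max(0, mi / sqrt(hu * hv)))
}

#' Cross-magnification embedding consistency (NMI)
#'
#' Clusters each view's embeddings with seeded k-means (10 restarts) and
#' returns the normalized mutual information between the two cluster-label
#' vectors. Identical embedding matrices give NMI 1 because the identical
#' seeded procedure produces identical clusterings.
#'
#' @param emb10,emb40 `n x d` embedding matrices, equal row counts.
#' @param k Number of clusters (>= 2, <= n).
#' @param seed RNG seed for both k-means runs.
#' @return NMI in `[0, 1]`.
#' @export
cross_mag_nmi <- function(emb10, emb40, k = 2L, seed = 1L) {
  emb10 <- as.matrix(emb10); emb40 <- as.matrix(emb40)
  if (nrow(emb10) != nrow(emb40)) stop_invalid("row count mismatch")
  if (k < 2) stop_invalid("k must be >= 2")
  if (nrow(emb10) < k) stop_invalid("fewer rows than clusters")
  km <- function(X) with_seed(mix_seed(seed, 37L),
                              stats::kmeans(X, centers = k, nstart = 10,
                                            iter.max = 50)$cluster)
  nmi(km(emb10), km(emb40))
}

#' Attention precision against a target mask
#'
#' Walks pixels in descending attention order until at least `mass` of the
#' total attention is covered, and returns the fraction of the selected
#' pixels that fall inside the target mask.
#'
#' @param attn_map Non-negative attention map (matrix), positive total.
#' @param target_mask Binary mask, same shape.
#' @param mass Attention mass to cover, in `(0, 1]` (default 0.2).
#' @return Precision in `[0, 1]`.
#' @export
attention_precision <- function(attn_map, target_mask, mass = 0.2) {
  a <- as.vector(attn_map); t <- as.logical(as.vector(target_mask))
  if (length(a) != length(t)) stop_invalid("shape mismatch")
  if (any(a < 0)) stop_invalid("attention must be non-negative")
  total <- sum(a)
  if (total <= 0) stop_invalid("zero total attention")
  if (mass <= 0 || mass > 1) stop_invalid("mass must be in (0,1]")
  ord <- order(a, decreasing = TRUE)
  cum <- cumsum(a[ord]) / total
  nsel <- which(cum >= mass - 1e-12)[1]
  sel <- ord[seq_len(nsel)]
  mean(t[sel])
}

# fraction of pooled, row-normalized attention-adjacency mass on node
# pairs NOT adjacent in the tissue graph (self mass excluded)
off_graph_attention_mass <- function(attn, assignment, G) {
  aa <- attention_adjacency(attn, assignment, "last")
  B <- aa$A_attn
  adj <- G$W > 0
  tot <- sum(B)
  if (tot <= 0) return(0)
  sum(B[!adj & row(B) != col(B)]) / tot
}
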