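#' Build a superpixel tissue graph
#'
#' Nodes are superpixels; an edge joins two superpixels sharing a
#' 4-connected pixel boundary, weighted by a Gaussian kernel on mean RGB
#' distance (0-255 scale), `exp(-||c_i - c_j||^2 / (2 * bandwidth^2))`.
#' Per row only the `max_neighbors` strongest edges are kept, the matrix is
#' re-symmetrized with the element-wise maximum, the diagonal zeroed, and a
#' row-normalized copy produced for comparison against attention.
#'
#' @param superpixel_labels Integer label matrix, labels contiguous from 0.
#' @param image Matching H x W x 3 array in `[0,1]`.
#' @param max_neighbors Sparsification cap per row (default 8).
#' @param color_bandwidth Gaussian bandwidth in 0-255 color units
#'   (default `0.2 * 255`).
#' @return `tissue_graph` list: `n_nodes`, `W` (symmetric sparsified
#'   weights), `A` (row-normalized `W`; rows with at least one neighbor sum
#'   to 1), `node_centroid` (`n x 2`, row/col), `node_color` (`n x 3`,
#'   0-255), `node_size`.
#' @export
build_tissue_graph <- function(superpixel_labels, image, max_neighbors = 8L,
                               color_bandwidth = 0.2 * 255) {
  lab <- superpixel_labels
  ids <- sort(unique(as.vector(lab)))
  n <- length(ids)
  if (!identical(ids, 0:(n - 1)) && !identical(as.integer(ids), 0:(n - 1)))
    stop_invalid("superpixel labels must be contiguous 0..n-1")
  H <- nrow(lab); W <- ncol(lab)
  lv <- as.vector(lab) + 1L
  px_r <- rep(seq_len(H), times = W); px_c <- rep(seq_len(W), each = H)
  node_size <- tabulate(lv, n)
  node_centroid <- cbind(row = rowsum(px_r, lv)[, 1] / node_size,
                         col = rowsum(px_c, lv)[, 1] / node_size)
  cols <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3])) * 255
  node_color <- rowsum(cols, lv) / node_size

  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    a <- lab[-H, ]; b <- lab[-1, ]            # vertical 4-neighbors
    d <- a != b
    if (any(d)) adj[cbind(a[d] + 1L, b[d] + 1L)] <- TRUE
    a <- lab[, -W]; b <- lab[, -1]            # horizontal 4-neighbors
    d <- a != b
    if (any(d)) adj[cbind(a[d] + 1L, b[d] + 1L)] <- TRUE
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE

  d2 <- unname(as.matrix(stats::dist(node_color)))^2
  Wm <- exp(-d2 / (2 * color_bandwidth^2)) * adj
  dimnames(Wm) <- NULL
  # keep top-max_neighbors per row, then re-symmetrize by the maximum
  if (n > 1) {
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nz <- which(Wm[i, ] > 0)
      if (length(nz) > max_neighbors)
        nz <- nz[order(Wm[i, nz], decreasing = TRUE)[seq_len(max_neighbors)]]
      keep[i, nz] <- TRUE
    }
    Wk <- Wm * keep
    Wm <- pmax(Wk, t(Wk))
  }
  diag(Wm) <- 0
  rs <- rowSums(Wm)
  A <- Wm / ifelse(rs > 0, rs, 1)
  structure(list(n_nodes = n, W = Wm, A = A, node_centroid = node_centroid,
                 node_color = node_color, node_size = node_size),
            class = "tissue_graph")
}

#' Assign ViT tokens to superpixels
#'
#' Each token takes the majority superpixel label inside its
#' `token_patch_px` square footprint; ties go to the smallest label id.
#'
#' @param superpixel_labels Label matrix (contiguous from 0).
#' @param token_grid `(rows, cols)` token layout.
#' @param token_patch_px Token footprint side; `token_grid *
#'   token_patch_px` must equal the label-map size.
#' @return `token_assignment` list: `token_to_node` (1 per token, 0-based
#'   node ids), `n_tokens`, `n_nodes`. Token order is column-major over the
#'   grid, matching [encode_cellular()].
#' @export
assign_tokens <- function(superpixel_labels, token_grid, token_patch_px) {
  H <- nrow(superpixel_labels); W <- ncol(superpixel_labels)
  gr <- token_grid[1]; gc <- token_grid[2]; p <- token_patch_px
  if (gr * p != H || gc * p != W)
    stop_invalid("token grid x patch size does not match label map")
  n_nodes <- max(superpixel_labels) + 1L
  t2n <- integer(gr * gc)
  t <- 1L
  for (tc in seq_len(gc)) for (tr in seq_len(gr)) {
    foot <- superpixel_labels[((tr - 1) * p + 1):(tr * p),
                              ((tc - 1) * p + 1):(tc * p)]
    cnt <- tabulate(as.vector(foot) + 1L, n_nodes)
    t2n[t] <- which.max(cnt) - 1L   # which.max takes the smallest on ties
    t <- t + 1L
  }
  structure(list(token_to_node = t2n, n_tokens = gr * gc, n_nodes = n_nodes),
            class = "token_assignment")
}

# pooling matrices for token -> node aggregation
node_indicator <- function(assignment) {
  S <- matrix(0, assignment$n_nodes, assignment$n_tokens)
  S[cbind(assignment$token_to_node + 1L, seq_len(assignment$n_tokens))] <- 1
  S
}

#' Pool token attention into a superpixel attention adjacency
#'
#' Averages the selected layers' head attentions into one token matrix,
#' symmetrizes it as `(T + T')/2`, pools to node pairs by the mean over
#' token pairs `(a in i, b in j)`, zeroes the diagonal and row-normalizes
#' rows with mass.
#'
#' @param attn List per layer of `heads x n x n` attention arrays (as
#'   returned by [encode_cellular()]), or a single such array.
#' @param assignment A [assign_tokens()] result.
#' @param layer_set `"last"` (default) or `"all"`.
#' @return `attention_adjacency` list: `A_attn` (`n_nodes x n_nodes`,
#'   symmetric pooling then row-normalized), `B_raw` (pooled, pre-
#'   normalization).
#' @export
attention_adjacency <- function(attn, assignment, layer_set = c("last", "all")) {
  layer_set <- match.arg(layer_set)
  if (!is.list(attn)) attn <- list(attn)
  sel <- if (layer_set == "last") attn[length(attn)] else attn
  n_tok <- dim(sel[[1]])[2]
  if (n_tok != assignment$n_tokens) stop_invalid("assignment/token count mismatch")
  Tm <- matrix(0, n_tok, n_tok)
  cnt <- 0
  for (L in sel) for (h in seq_len(dim(L)[1])) {
    Tm <- Tm + L[h, , ]
    cnt <- cnt + 1
  }
  Tm <- Tm / cnt
  M <- (Tm + t(Tm)) / 2
  S <- node_indicator(assignment)
  sz <- rowSums(S)
  B <- (S %*% M %*% t(S)) / pmax(outer(sz, sz), 1)
  B[sz == 0, ] <- 0; B[, sz == 0] <- 0
  diag(B) <- 0
  rs <- rowSums(B)
  A_attn <- B / ifelse(rs > 0, rs, 1)
  structure(list(A_attn = A_attn, B_raw = B), class = "attention_adjacency")
}

#' Structural attention loss
#'
#' Mean squared difference between the row-normalized tissue adjacency and
#' the row-normalized attention adjacency over all ordered off-diagonal
#' node pairs.
#'
#' @param G A [build_tissue_graph()] result.
#' @param A_attn An [attention_adjacency()] result or a plain matrix.
#' @return Non-negative scalar; zero iff the matrices agree off-diagonal.
#' @export
sacgr_loss <- function(G, A_attn) {
  Aa <- if (inherits(A_attn, "attention_adjacency")) A_attn$A_attn else A_attn
  n <- G$n_nodes
  if (!all(dim(Aa) == c(n, n))) stop_invalid("node count mismatch")
  if (n < 2) return(0)
  D <- (G$A - Aa)^2
  diag(D) <- 0
  sum(D) / (n * (n - 1))
}

#' Feature smoothness along tissue-graph edges
#'
#' Node features are the means of their tokens' features; the loss is
#' `sum_{i<j} W_ij ||f_i - f_j||^2 / sum_{i<j} W_ij` over the symmetric
#' sparsified weights. Nodes with no tokens are excluded with a warning.
#'
#' @param token_features `n_tokens x d` matrix (or a `token_sequence`).
#' @param assignment A [assign_tokens()] result.
#' @param G A [build_tissue_graph()] result.
#' @return Non-negative scalar; zero iff node means agree across every
#'   positive-weight edge.
#' @export
smoothness_loss <- function(token_features, assignment, G) {
  F_ <- if (inherits(token_features, "token_sequence")) token_features$tokens
        else token_features
  S <- node_indicator(assignment)
  sz <- rowSums(S)
  empty <- sz == 0
  if (any(empty)) warning("nodes without tokens excluded: ",
                          sum(empty), call. = FALSE)
  Fm <- (S %*% F_) / pmax(sz, 1)
  n <- G$n_nodes
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (empty[i] || empty[j] || G$W[i, j] == 0) next
    num <- num + G$W[i, j] * sum((Fm[i, ] - Fm[j, ])^2)
    den <- den + G$W[i, j]
  }
  if (den == 0) return(0)
  num / den
}

# sacgr loss with gradient w.r.t. the token-level attention matrix Tm
# (already head-averaged). Chain: M=(T+T')/2 -> pool -> zero diag ->
# row-normalize -> MSE against G$A.
sacgr_grad_token_attn <- function(G, Tm, assignment) {
  n_tok <- nrow(Tm)
  M <- (Tm + t(Tm)) / 2
  S <- node_indicator(assignment)
  sz <- rowSums(S)
  denom <- pmax(outer(sz, sz), 1)
  B <- (S %*% M %*% t(S)) / denom
  B[sz == 0, ] <- 0; B[, sz == 0] <- 0
  diag(B) <- 0
  rs <- rowSums(B)
  rsafe <- ifelse(rs > 0, rs, 1)
  A_attn <- B / rsafe
  n <- G$n_nodes
  D <- G$A - A_attn
  diag(D) <- 0
  npairs <- n * (n - 1)
  loss <- sum(D^2) / npairs
  dA <- -2 * D / npairs          # dL/dA_attn
  # row-normalization backprop: A = B / r, r = rowSums(B)
  dB <- dA / rsafe - rowSums(dA * A_attn) / rsafe
  dB[rs == 0, ] <- 0
  diag(dB) <- 0
  dB[sz == 0, ] <- 0; dB[, sz == 0] <- 0
  dM <- t(S) %*% (dB / denom) %*% S
  dT <- (dM + t(dM)) / 2
  list(loss = loss, A_attn = A_attn, dT = dT)
}

# smoothness loss with gradient w.r.t. token features
smoothness_grad_tokens <- function(token_features, assignment, G) {
  F_ <- if (inherits(token_features, "token_sequence")) token_features$tokens
        else token_features
  S <- node_indicator(assignment)
  sz <- rowSums(S)
  empty <- sz == 0
  Fm <- (S %*% F_) / pmax(sz, 1)
  n <- G$n_nodes
  num <- 0; den <- 0
  dFm <- matrix(0, n, ncol(F_))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    if (empty[i] || empty[j] || G$W[i, j] == 0) next
    diff <- Fm[i, ] - Fm[j, ]
    num <- num + G$W[i, j] * sum(diff^2)
    den <- den + G$W[i, j]
    dFm[i, ] <- dFm[i, ] + 2 * G$W[i, j] * diff
    dFm[j, ] <- dFm[j, ] - 2 * G$W[i, j] * diff
  }
  if (den == 0) return(list(loss = 0, dF = matrix(0, nrow(F_), ncol(F_))))
  dF <- t(S) %*% (dFm / pmax(sz, 1)) / den
  list(loss = num / den, dF = dF)
}

#' Export a tissue graph as an edge list and node table
#' @param G A `tissue_graph`.
#' @param edge_json,node_csv Output paths (either may be `NULL`).
#' @return Invisibly, the edge-list data.frame.
#' @export
export_tissue_graph <- function(G, edge_json = NULL, node_csv = NULL) {
  idx <- which(upper.tri(G$W) & G$W > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                      weight = G$W[idx])
  if (!is.null(edge_json))
    jsonlite::write_json(edges, edge_json, dataframe = "rows", digits = NA)
  if (!is.null(node_csv)) {
    nodes <- data.frame(node = seq_len(G$n_nodes) - 1L,
                        row = G$node_centroid[, 1], col = G$node_centroid[, 2],
                        r = G$node_color[, 1], g = G$node_color[, 2],
                        b = G$node_color[, 3])
    utils::write.csv(nodes, node_csv, row.names = FALSE)
  }
  invisible(edges)
}
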