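#' Configuration for a reference branch encoder
#'
#' The two branches mirror the dual-magnification design: a purely
#' convolutional context encoder for the 10x patch and a small vision
#' transformer for the 40x patch whose per-layer, per-head attention maps
#' are exposed for graph regularization. These are compact, randomly
#' initialized reference backbones; the paper-scale configuration
#' (hidden 768, 12 heads) is available through the same fields, the
#' defaults here are desk-scale.
#'
#' @param branch `"context10"` or `"cellular40"`.
#' @param hidden_dim Embedding width (divisible by `n_heads`).
#' @param n_heads Attention heads (cellular branch).
#' @param n_layers Transformer layers (cellular branch).
#' @param token_patch_px ViT patch side; the image side must be divisible
#'   by it.
#' @param dropout_rate Monte Carlo head dropout rate in `[0,1)`.
#' @param n_classes Number of output classes (>= 2).
#' @return `encoder_config` list.
#' @export
encoder_config <- function(branch = c("context10", "cellular40"),
                           hidden_dim = 64L, n_heads = 4L, n_layers = 2L,
                           token_patch_px = 16L, dropout_rate = 0.3,
                           n_classes = 2L) {
  branch <- match.arg(branch)
  if (hidden_dim %% n_heads != 0)
    stop_invalid("hidden_dim must be divisible by n_heads")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must be in [0,1)")
  if (n_classes < 2) stop_invalid("n_classes must be >= 2")
  structure(list(branch = branch, hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
                 token_patch_px = as.integer(token_patch_px),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes)),
            class = "encoder_config")
}

rand_mat <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

#' Initialize a context (10x) reference encoder
#'
#' Two valid 3x3 convolutions with stride 2 and ReLU, followed by a 1x1
#' projection to `hidden_dim`. Purely convolutional, so a shift of the
#' image by the total stride shifts interior feature cells by one.
#'
#' @param cfg [encoder_config()] with `branch = "context10"`.
#' @param seed Initialization seed.
#' @return Parameter list of class `context_encoder`.
#' @export
init_context_encoder <- function(cfg, seed = 1L) {
  stopifnot(cfg$branch == "context10")
  with_seed(mix_seed(seed, 7L), {
    c1 <- 16L; c2 <- 32L
    structure(list(
      W1 = rand_mat(27, c1), b1 = rep(0, c1),
      W2 = rand_mat(9 * c1, c2), b2 = rep(0, c2),
      Wp = rand_mat(c2, cfg$hidden_dim), bp = rep(0, cfg$hidden_dim),
      cfg = cfg
    ), class = "context_encoder")
  })
}

# im2col for valid convolution; returns (oh*ow) x (k*k*C), rows in
# column-major spatial order.
im2col <- function(x, k, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  oh <- (H - k) %/% stride + 1L
  ow <- (W - k) %/% stride + 1L
  rows <- (seq_len(oh) - 1L) * stride
  cols <- (seq_len(ow) - 1L) * stride
  out <- matrix(0, oh * ow, k * k * C)
  idx <- 1L
  for (ch in seq_len(C)) for (dc in 0:(k - 1)) for (dr in 0:(k - 1)) {
    out[, idx] <- as.vector(x[rows + dr + 1L, cols + dc + 1L, ch])
    idx <- idx + 1L
  }
  attr(out, "oshape") <- c(oh, ow)
  out
}

#' Encode a 10x patch into a spatial feature map
#' @param image10 H x W x 3 array in `[0,1]`.
#' @param params From [init_context_encoder()].
#' @return List with `values` (`channels x rows x cols`) and `pooled`
#'   (length `hidden_dim` spatial mean).
#' @export
encode_context <- function(image10, params) {
  if (!is_rgb_array(image10)) stop_invalid("image10 must be H x W x 3")
  x <- im2col(image10, 3L, 2L)
  o1 <- attr(x, "oshape")
  h1 <- pmax(x %*% params$W1 + rep(params$b1, each = nrow(x)), 0)
  a1 <- array(h1, c(o1[1], o1[2], ncol(h1)))
  x2 <- im2col(a1, 3L, 2L)
  o2 <- attr(x2, "oshape")
  h2 <- pmax(x2 %*% params$W2 + rep(params$b2, each = nrow(x2)), 0)
  z <- h2 %*% params$Wp + rep(params$bp, each = nrow(h2))
  vals <- aperm(array(z, c(o2[1], o2[2], ncol(z))), c(3, 1, 2))
  if (any(!is.finite(vals))) stop_invalid("non-finite feature map")
  list(values = vals, pooled = as.numeric(apply(vals, 1, mean)),
       grid = o2)
}

# sinusoidal positional encoding, size-agnostic
pos_encoding <- function(n_tokens, d) {
  pos <- seq_len(n_tokens) - 1
  i <- seq_len(d) - 1
  ang <- outer(pos, 1 / 10000^(2 * (i %/% 2) / d))
  pe <- matrix(0, n_tokens, d)
  even <- i %% 2 == 0
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe
}

#' Initialize a cellular (40x) reference transformer encoder
#' @param cfg [encoder_config()] with `branch = "cellular40"`.
#' @param seed Initialization seed.
#' @return Parameter list of class `cellular_encoder`; per layer, per head
#'   `Wq`, `Wk`, `Wv` (`hidden x hidden/n_heads`) plus an output mix `Wo`.
#' @export
init_cellular_encoder <- function(cfg, seed = 1L) {
  stopifnot(cfg$branch == "cellular40")
  with_seed(mix_seed(seed, 11L), {
    d <- cfg$hidden_dim; dh <- d %/% cfg$n_heads
    p <- cfg$token_patch_px
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      heads <- lapply(seq_len(cfg$n_heads), function(h)
        list(Wq = rand_mat(d, dh, 1 / sqrt(d)),
             Wk = rand_mat(d, dh, 1 / sqrt(d)),
             Wv = rand_mat(d, dh, 1 / sqrt(d))))
      list(heads = heads, Wo = rand_mat(d, d, 1 / sqrt(d)))
    })
    structure(list(Wembed = rand_mat(3 * p * p, d, 1 / sqrt(3 * p * p)),
                   layers = layers, cfg = cfg),
              class = "cellular_encoder")
  })
}

# One multi-head self-attention layer; returns new tokens and the per-head
# attention arrays.
attn_layer_forward <- function(X, layer, n_heads) {
  n <- nrow(X); d <- ncol(X); dh <- d %/% n_heads
  A <- array(0, c(n_heads, n, n))
  out <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    hp <- layer$heads[[h]]
    Q <- X %*% hp$Wq; K <- X %*% hp$Wk; V <- X %*% hp$Wv
    Ah <- softmax(Q %*% t(K) / sqrt(dh))
    A[h, , ] <- Ah
    out[, ((h - 1) * dh + 1):(h * dh)] <- Ah %*% V
  }
  list(tokens = X + out %*% layer$Wo, attn = A)
}

#' Encode a 40x patch into a token sequence with attention maps
#'
#' Non-overlapping `token_patch_px` patches are linearly embedded, given
#' sinusoidal positions, and passed through residual multi-head
#' self-attention layers. All per-layer, per-head attention matrices are
#' returned (each row a probability vector).
#'
#' @param image40 H x W x 3 array; side divisible by `token_patch_px`.
#' @param params From [init_cellular_encoder()].
#' @return List of class `token_sequence`: `tokens` (`n_tokens x hidden`),
#'   `token_grid` `(rows, cols)`, `attn` (list per layer of
#'   `heads x n x n` arrays), `last_input` (tokens entering the final
#'   layer) and `pooled`.
#' @export
encode_cellular <- function(image40, params) {
  cfg <- params$cfg
  if (!is_rgb_array(image40)) stop_invalid("image40 must be H x W x 3")
  H <- dim(image40)[1]; W <- dim(image40)[2]; p <- cfg$token_patch_px
  if (H %% p != 0 || W %% p != 0)
    stop_invalid("image side not divisible by token_patch_px")
  gr <- H %/% p; gc <- W %/% p; n <- gr * gc
  P <- matrix(0, n, 3 * p * p)
  t <- 1L
  for (tc in seq_len(gc)) for (tr in seq_len(gr)) {
    # token order column-major to match matrix vectorization
    P[t, ] <- as.vector(image40[((tr - 1) * p + 1):(tr * p),
                                ((tc - 1) * p + 1):(tc * p), ])
    t <- t + 1L
  }
  X <- P %*% params$Wembed + pos_encoding(n, cfg$hidden_dim)
  attn <- vector("list", cfg$n_layers)
  last_input <- X
  for (l in seq_len(cfg$n_layers)) {
    last_input <- X
    fw <- attn_layer_forward(X, params$layers[[l]], cfg$n_heads)
    X <- fw$tokens
    attn[[l]] <- fw$attn
  }
  structure(list(tokens = X, token_grid = c(rows = gr, cols = gc),
                 attn = attn, last_input = last_input,
                 pooled = colMeans(X)),
            class = "token_sequence")
}

#' Create a Monte Carlo dropout classification head
#' @param d Input feature dimension.
#' @param n_classes Number of classes.
#' @param seed Initialization seed.
#' @return List `W` (`d x n_classes`), `b`.
#' @export
new_mc_head <- function(d, n_classes, seed = 1L) {
  with_seed(mix_seed(seed, 13L),
            list(W = rand_mat(d, n_classes, 1 / sqrt(d)), b = rep(0, n_classes)))
}

#' Monte Carlo dropout forward passes
#'
#' Runs `T` stochastic forward passes of a linear + softmax head under
#' inverted dropout on the input features, the Monte Carlo approximation of
#' the predictive distribution. Dropout masks come from a dedicated
#' generator seeded by `seed`, so passes are reproducible; `dropout_rate =
#' 0` makes all passes identical.
#'
#' @param head From [new_mc_head()].
#' @param features Numeric vector (one unit) or `units x d` matrix.
#' @param T_passes Number of passes (>= 1).
#' @param dropout_rate In `[0,1)`.
#' @param seed RNG seed for the dropout masks.
#' @return `stochastic_passes` list: `passes` (list of probability vectors /
#'   `units x C` matrices), `T`, `seed`.
#' @export
mc_forward <- function(head, features, T_passes = 10L, dropout_rate = 0.3,
                       seed = 1L) {
  if (T_passes < 1) stop_invalid("T_passes must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must be in [0,1)")
  f <- if (is.null(dim(features))) matrix(features, nrow = 1) else features
  d <- ncol(f)
  one_unit <- is.null(dim(features))
  masks <- with_seed(mix_seed(seed, 17L), {
    lapply(seq_len(T_passes), function(t) {
      if (dropout_rate == 0) rep(1, d)
      else stats::rbinom(d, 1, 1 - dropout_rate) / (1 - dropout_rate)
    })
  })
  passes <- lapply(masks, function(mask) {
    z <- (f * rep(mask, each = nrow(f))) %*% head$W +
      rep(head$b, each = nrow(f))
    pr <- softmax(z)
    if (one_unit) as.numeric(pr) else pr
  })
  structure(list(passes = passes, T = T_passes, seed = seed,
                 dropout_rate = dropout_rate, masks = masks),
            class = "stochastic_passes")
}
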