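#' Texture entropy of a patch in bits
#'
#' Shannon entropy (base 2) of the histogram of grayscale luminance
#' `0.299 R + 0.587 G + 0.114 B`, rounded to integers 0-255 and binned
#' into `n_bins` equal bins. Bounded by 8 bits for the default 256-bin
#' 8-bit histogram; invariant to pixel permutations.
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param n_bins Histogram bins over 0-255 (default 256).
#' @return Entropy in bits.
#' @export
texture_entropy <- function(image, n_bins = 256L) {
  if (!is_rgb_array(image) || length(image) == 0)
    stop_invalid("image must be a non-empty H x W x 3 array")
  lum <- round((0.299 * image[, , 1] + 0.587 * image[, , 2] +
                  0.114 * image[, , 3]) * 255)
  bin <- pmin(floor(lum * n_bins / 256), n_bins - 1)
  p <- tabulate(as.vector(bin) + 1L, n_bins)
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Nuclei density variance over a subtile grid
#'
#' Partitions the patch into `grid x grid` subtiles (the last row/column
#' absorbs any remainder when `patch_px` is not divisible by `grid`),
#' computes per-subtile density = nucleus count / subtile pixel area, and
#' returns the population variance of the `grid^2` densities. Units are
#' nuclei per pixel.
#'
#' @param centroids Data frame with 0-based `x`, `y` columns (may be empty).
#' @param patch_px Patch side in pixels.
#' @param grid Subtile grid side (>= 1, default 8).
#' @return Non-negative variance.
#' @export
nuclei_density_variance <- function(centroids, patch_px, grid = 8L) {
  if (grid < 1) stop_invalid("grid must be >= 1")
  s <- patch_px %/% grid
  if (s < 1) stop_invalid("grid finer than the patch")
  edges <- c((0:(grid - 1)) * s, patch_px)     # last tile absorbs remainder
  sizes <- diff(edges)
  areas <- outer(sizes, sizes)
  counts <- matrix(0, grid, grid)
  if (nrow(centroids) > 0) {
    ti <- pmin(floor(centroids$y / s), grid - 1) + 1   # row tile
    tj <- pmin(floor(centroids$x / s), grid - 1) + 1   # col tile
    for (k in seq_along(ti)) counts[ti[k], tj[k]] <- counts[ti[k], tj[k]] + 1
  }
  dens <- counts / areas
  mean((dens - mean(dens))^2)
}

#' Patch complexity score
#'
#' `xi = lambda1 * E + lambda2 * var_nuc`: a linear blend of texture
#' entropy (bits) and nuclei-density variance. The default trainer weights
#' (`lambda1 = 1`, `lambda2 = 1000`) put both terms on an O(1) scale given
#' typical entropies of ~4 bits and density variances of ~1e-3.
#'
#' @param E Texture entropy (bits).
#' @param var_nuc Nuclei density variance.
#' @param lambda1,lambda2 Non-negative weights.
#' @return Complexity score.
#' @export
complexity_score <- function(E, var_nuc, lambda1 = 1, lambda2 = 1000) {
  if (lambda1 < 0 || lambda2 < 0) stop_invalid("weights must be >= 0")
  lambda1 * E + lambda2 * var_nuc
}

#' Curriculum scheduler state
#'
#' Holds the sigmoid steepness `beta`, the complexity threshold `mu_t`
#' (updated per epoch as an empirical quantile of the pool's scores), the
#' complexity weights, and the quantile ramp
#' `(start_quantile, end_quantile, ramp_epochs)`.
#'
#' @param beta Sigmoid steepness (> 0).
#' @param mu_t Initial threshold.
#' @param epoch Current epoch (0-based).
#' @param lambda1,lambda2 Complexity weights (see [complexity_score()]).
#' @param schedule Numeric `(start_quantile, end_quantile, ramp_epochs)`.
#' @param floor_prob Small positive sampling-weight floor.
#' @return `curriculum_state` list.
#' @export
curriculum_state <- function(beta = 1.0, mu_t = 0, epoch = 0L,
                             lambda1 = 1, lambda2 = 1000,
                             schedule = c(start_quantile = 0.2,
                                          end_quantile = 0.8,
                                          ramp_epochs = 5),
                             floor_prob = 0.05) {
  if (beta <= 0) stop_invalid("beta must be > 0")
  s <- unname(schedule)
  if (s[1] < 0 || s[1] > s[2] || s[2] > 1)
    stop_invalid("need 0 <= start_quantile <= end_quantile <= 1")
  structure(list(beta = beta, mu_t = mu_t, epoch = as.integer(epoch),
                 lambda1 = lambda1, lambda2 = lambda2,
                 schedule = c(start_quantile = s[1], end_quantile = s[2],
                              ramp_epochs = s[3]),
                 floor_prob = floor_prob),
            class = "curriculum_state")
}

#' Soft curriculum selection probability
#'
#' `P_select = 1 / (1 + exp(-beta * (xi - mu_t)))`: a sigmoid in the
#' complexity score, 0.5 exactly at the threshold, strictly increasing in
#' `xi`.
#'
#' @param xi Complexity score(s).
#' @param state A [curriculum_state()].
#' @return Probabilities in `(0, 1)`.
#' @export
selection_probability <- function(xi, state) {
  1 / (1 + exp(-state$beta * (xi - state$mu_t)))
}

#' Update the curriculum threshold from the pool's complexity scores
#'
#' Sets `mu_t` to the empirical quantile (linear interpolation, R type 7)
#' of the scores at `q(epoch)`, where `q` ramps linearly from
#' `start_quantile` to `end_quantile` over `ramp_epochs` and then
#' saturates.
#'
#' @param records Data frame with an `xi` column (or numeric vector).
#' @param state A [curriculum_state()]; its `epoch` selects the quantile.
#' @return Updated `curriculum_state` with new `mu_t`.
#' @export
update_threshold <- function(records, state) {
  xi <- if (is.data.frame(records)) records$xi else records
  if (length(xi) == 0) stop_invalid("empty records")
  s <- state$schedule
  frac <- if (s["ramp_epochs"] <= 0) 1 else min(1, state$epoch / s["ramp_epochs"])
  q <- s["start_quantile"] + frac * (s["end_quantile"] - s["start_quantile"])
  state$mu_t <- unname(stats::quantile(xi, q, type = 7))
  state
}

#' Sample a curriculum mini-batch
#'
#' Weighted sampling without replacement. Early in training weights follow
#' `1 - P_select` (easy samples dominate), blending linearly over the ramp
#' into `P_select` (hard samples dominate); `floor_prob` keeps every weight
#' positive. Deterministic given `seed`. `mode` can force either raw
#' weighting.
#'
#' @param records Data frame with `pair_id` and `xi` columns.
#' @param state A [curriculum_state()].
#' @param batch_size Number of ids to draw (<= rows).
#' @param seed RNG seed.
#' @param mode `"two_phase"` (default), `"anti"` (always `1 - P_select`) or
#'   `"pro"` (always `P_select`, the raw printed direction).
#' @return Vector of sampled `pair_id`s.
#' @export
sample_batch <- function(records, state, batch_size, seed = 1L,
                         mode = c("two_phase", "anti", "pro")) {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (batch_size > n) stop_invalid("batch_size exceeds pool size")
  ps <- selection_probability(records$xi, state)
  s <- state$schedule
  t <- if (s["ramp_epochs"] <= 0) 1 else min(1, state$epoch / s["ramp_epochs"])
  w <- switch(mode,
              two_phase = (1 - t) * (1 - ps) + t * ps,
              anti = 1 - ps,
              pro = ps) + state$floor_prob
  with_seed(mix_seed(seed, state$epoch, 23L),
            records$pair_id[sample.int(n, batch_size, prob = w)])
}

#' Complexity table for a dataset
#'
#' Computes, per pair, the 40x texture entropy, nuclei-density variance,
#' complexity score and selection probability — the per-patch inputs of
#' the curriculum scheduler.
#'
#' @param manifest Manifest from [generate_dataset()]/[read_manifest()].
#' @param state A [curriculum_state()].
#' @param csv Optional output CSV path
#'   (`pair_id,E_bits,var_nuc,xi,p_select`).
#' @return Data frame with those columns.
#' @export
complexity_table <- function(manifest, state = curriculum_state(), csv = NULL) {
  n <- length(manifest$records)
  out <- data.frame(pair_id = integer(n), E_bits = numeric(n),
                    var_nuc = numeric(n), xi = numeric(n),
                    p_select = numeric(n))
  for (i in seq_len(n)) {
    pair <- load_pair(manifest, i)
    E <- texture_entropy(pair$image40)
    v <- nuclei_density_variance(pair$centroids, nrow(pair$image40))
    out$pair_id[i] <- pair$pair_id
    out$E_bits[i] <- E
    out$var_nuc[i] <- v
    out$xi[i] <- complexity_score(E, v, state$lambda1, state$lambda2)
  }
  out$p_select <- selection_probability(out$xi, state)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
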