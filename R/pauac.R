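#' PAUAC configuration
#'
#' Uncertainty-aware cross-magnification consistency: Monte Carlo
#' predictive distributions from both branches are compared by KL
#' divergence, down-weighted where either branch is uncertain through
#' `w_j = exp(-alpha * (H_j10 + H_j40))` with entropies in nats inside the
#' weight (entropy is reported in bits everywhere else; the conversion
#' keeps `alpha` on the natural-log scale of the KL term).
#'
#' @param alpha Sharpness of the uncertainty down-weighting (>= 0; the
#'   value is not prescribed by the underlying design, default 1).
#' @param direction `"as_printed"` (KL(P10 || P40)) or `"symmetric"`.
#' @param unit_mode `"patch"` (one distribution per patch) or `"dense"`
#'   (per-pixel distributions on a shared unit grid).
#' @return `pauac_config` list.
#' @export
pauac_config <- function(alpha = 1.0,
                         direction = c("as_printed", "symmetric"),
                         unit_mode = c("patch", "dense")) {
  if (!is.finite(alpha) || alpha < 0) stop_invalid("alpha must be finite and >= 0")
  structure(list(alpha = alpha, direction = match.arg(direction),
                 unit_mode = match.arg(unit_mode)),
            class = "pauac_config")
}

#' Predictive distribution from Monte Carlo passes
#'
#' Element-wise mean of the `T` stochastic softmax outputs.
#'
#' @param passes A `stochastic_passes` object from [mc_forward()], or a
#'   plain list of probability vectors / matrices.
#' @return Mean distribution, same shape as one pass.
#' @export
predictive_distribution <- function(passes) {
  pl <- if (inherits(passes, "stochastic_passes")) passes$passes else passes
  if (length(pl) == 0) stop_invalid("empty pass list")
  Reduce(`+`, pl) / length(pl)
}

#' Predictive (Shannon) entropy in bits
#'
#' `H = -sum_c p_c log2 p_c` per unit with `0 log 0 := 0`; bounded by
#' `log2(n_classes)`, attained at the uniform distribution.
#'
#' @param P Probability vector (one unit) or `units x C` matrix.
#' @return Numeric vector of entropies (bits), one per unit.
#' @export
predictive_entropy <- function(P) {
  M <- as_prob_matrix(P)
  if (any(M < -1e-9)) stop_invalid("negative probabilities")
  M <- pmax(M, 0)
  terms <- ifelse(M > 0, M * log2(M), 0)
  as.numeric(-rowSums(terms))
}

#' Uncertainty-based consistency weight
#'
#' `w = exp(-alpha * (H10 + H40))` with entropies supplied in bits and
#' converted to nats inside the exponent. Equals 1 when both entropies are
#' zero or when `alpha = 0`, and decreases strictly in `H10 + H40`.
#'
#' @param H10,H40 Non-negative entropies in bits (vectorized).
#' @param cfg A [pauac_config()].
#' @return Weights in `(0, 1]`.
#' @export
consistency_weight <- function(H10, H40, cfg = pauac_config()) {
  if (any(H10 < 0) || any(H40 < 0)) stop_invalid("entropies must be >= 0")
  exp(-cfg$alpha * (H10 + H40) * log(2))
}

kl_rows <- function(P, Q, eps = 1e-12) {
  Qf <- pmax(Q, eps)
  rowSums(ifelse(P > 0, P * (log(pmax(P, eps)) - log(Qf)), 0))
}

#' Uncertainty-aware cross-magnification consistency loss
#'
#' Mean over units `j` of `w_j * KL(P10_j || P40_j)` (natural log, `1e-12`
#' flooring of the denominator distribution). Weights come from
#' [consistency_weight()] on the supplied (or recomputed) entropies. The
#' `symmetric` direction averages both KL orientations under the same
#' weights. The mean (rather than sum) over units makes the scale
#' batch-size invariant.
#'
#' @param P10,P40 Probability vectors or `units x C` matrices on matching
#'   unit grids.
#' @param H10,H40 Optional entropies in bits; recomputed from `P10`/`P40`
#'   when `NULL`.
#' @param cfg A [pauac_config()].
#' @return Non-negative scalar; zero iff `P10 == P40` on every unit.
#' @export
pauac_loss <- function(P10, P40, H10 = NULL, H40 = NULL,
                       cfg = pauac_config()) {
  M10 <- as_prob_matrix(P10); M40 <- as_prob_matrix(P40)
  if (!all(dim(M10) == dim(M40))) stop_invalid("unit grid / class mismatch")
  if (is.null(H10)) H10 <- predictive_entropy(M10)
  if (is.null(H40)) H40 <- predictive_entropy(M40)
  w <- consistency_weight(H10, H40, cfg)
  K <- if (cfg$direction == "symmetric")
    0.5 * (kl_rows(M10, M40) + kl_rows(M40, M10))
  else kl_rows(M10, M40)
  mean(w * K)
}

# Full analytic gradient of pauac_loss w.r.t. the probability matrices,
# including the dependence of the entropies (hence weights) on P.
pauac_grad_P <- function(P10, P40, cfg = pauac_config(), eps = 1e-12) {
  M10 <- as_prob_matrix(P10); M40 <- as_prob_matrix(P40)
  n <- nrow(M10)
  Hn10 <- -rowSums(ifelse(M10 > 0, M10 * log(pmax(M10, eps)), 0))
  Hn40 <- -rowSums(ifelse(M40 > 0, M40 * log(pmax(M40, eps)), 0))
  w <- exp(-cfg$alpha * (Hn10 + Hn40))
  l10 <- log(pmax(M10, eps)); l40 <- log(pmax(M40, eps))
  K1 <- rowSums(M10 * (l10 - l40))
  if (cfg$direction == "symmetric") {
    K2 <- rowSums(M40 * (l40 - l10))
    K <- 0.5 * (K1 + K2)
    dK10 <- 0.5 * ((l10 - l40 + 1) - M40 / pmax(M10, eps))
    dK40 <- 0.5 * (-M10 / pmax(M40, eps) + (l40 - l10 + 1))
  } else {
    K <- K1
    dK10 <- l10 - l40 + 1
    dK40 <- -M10 / pmax(M40, eps)
  }
  # dw/dp = w * alpha * (log p + 1)  (since dH_nats/dp = -(log p + 1))
  dw10 <- w * cfg$alpha * (l10 + 1)
  dw40 <- w * cfg$alpha * (l40 + 1)
  list(loss = mean(w * K),
       dP10 = (dw10 * K + w * dK10) / n,
       dP40 = (dw40 * K + w * dK40) / n)
}

# chain a per-probability gradient through a row-wise softmax
softmax_backprop <- function(P, dP) {
  s <- rowSums(dP * P)
  P * (dP - s)
}

#' PAUAC loss and analytic gradient with respect to branch logits
#'
#' Treats `P = softmax(z)` per branch and differentiates the full loss,
#' including the entropy-dependent weights. Used for gradient checking and
#' by the trainer.
#'
#' @param z10,z40 Logit matrices (`units x C`).
#' @param cfg A [pauac_config()].
#' @return List `loss`, `dz10`, `dz40`.
#' @export
pauac_loss_logits <- function(z10, z40, cfg = pauac_config()) {
  P10 <- softmax(as_prob_matrix(z10)); P40 <- softmax(as_prob_matrix(z40))
  g <- pauac_grad_P(P10, P40, cfg)
  list(loss = g$loss,
       dz10 = softmax_backprop(P10, g$dP10),
       dz40 = softmax_backprop(P40, g$dP40))
}
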