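#' Composite loss configuration
#'
#' Weights of the multi-term objective
#' `L_total = L_sup + lambda_pauac * L_PAUAC + lambda_sacgr * L_SACGR +
#' lambda_cccra * L_CCCRA`, together with the module parameters it passes
#' down. `smoothness_weight` scales the edge-smoothness companion of the
#' structural attention loss (default `0.1 * lambda_sacgr`).
#'
#' @param lambda_pauac,lambda_sacgr,lambda_cccra Non-negative weights.
#' @param alpha PAUAC sharpness.
#' @param beta Curriculum sigmoid steepness.
#' @param gamma Positional sensitivity (default 0.3).
#' @param tau InfoNCE temperature (default 0.07).
#' @param smoothness_weight Edge-smoothness weight; `NULL` means
#'   `0.1 * lambda_sacgr`.
#' @return `composite_loss_config` list.
#' @export
composite_loss_config <- function(lambda_pauac = 1.0, lambda_sacgr = 0.5,
                                  lambda_cccra = 0.5, alpha = 1.0,
                                  beta = 1.0, gamma = 0.3, tau = 0.07,
                                  smoothness_weight = NULL) {
  lams <- c(lambda_pauac, lambda_sacgr, lambda_cccra)
  if (any(!is.finite(lams)) || any(lams < 0))
    stop_invalid("invalid config: loss weights must be finite and >= 0")
  if (is.null(smoothness_weight)) smoothness_weight <- 0.1 * lambda_sacgr
  if (smoothness_weight < 0) stop_invalid("invalid config: smoothness_weight")
  structure(list(lambda_pauac = lambda_pauac, lambda_sacgr = lambda_sacgr,
                 lambda_cccra = lambda_cccra, alpha = alpha, beta = beta,
                 gamma = gamma, tau = tau,
                 smoothness_weight = smoothness_weight),
            class = "composite_loss_config")
}

#' Total composite training loss
#'
#' The exact linear combination
#' `L_sup + lambda_pauac * l_pauac + lambda_sacgr * l_sacgr +
#' lambda_cccra * l_cccra`. Ablation modes correspond to zeroing exactly
#' one weight.
#'
#' @param l_sup,l_pauac,l_sacgr,l_cccra Finite loss components.
#' @param cfg A [composite_loss_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(l_sup, l_pauac, l_sacgr, l_cccra,
                       cfg = composite_loss_config()) {
  comps <- c(l_sup, l_pauac, l_sacgr, l_cccra)
  if (any(!is.finite(comps))) stop_invalid("loss components must be finite")
  l_sup + cfg$lambda_pauac * l_pauac + cfg$lambda_sacgr * l_sacgr +
    cfg$lambda_cccra * l_cccra
}

#' Trainer configuration
#'
#' AdamW with linear warm-up followed by cosine decay; early stopping on
#' validation Dice when the manifest carries masks, otherwise on
#' validation AUC.
#'
#' @param lr Peak learning rate (default 1e-4 at paper scale; desk-scale
#'   runs typically use a larger value such as 1e-2 for the tiny heads).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param betas Adam moment decays (default `c(0.9, 0.999)`).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param warmup_epochs Linear warm-up epochs (< epochs).
#' @param T_mc Monte Carlo passes per head (default 10).
#' @param seed Master seed for init, data order and dropout.
#' @param early_stop_metric `"auto"`, `"dice"` or `"auc"`.
#' @return `train_config` list.
#' @export
train_config <- function(lr = 1e-2, weight_decay = 0.01,
                         betas = c(0.9, 0.999), batch_size = 16L,
                         epochs = 10L, warmup_epochs = 2L, T_mc = 10L,
                         seed = 1L, early_stop_metric = "auto") {
  if (lr <= 0) stop_invalid("lr must be > 0")
  if (warmup_epochs >= epochs) stop_invalid("warmup_epochs must be < epochs")
  structure(list(lr = lr, weight_decay = weight_decay, betas = betas,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 T_mc = as.integer(T_mc), seed = as.integer(seed),
                 early_stop_metric = early_stop_metric),
            class = "train_config")
}

#' Desk-scale model configuration
#' @param hidden_dim Branch embedding width.
#' @param n_heads,n_layers ViT shape.
#' @param token_patch_px ViT patch side.
#' @param d_k Cross-modal key/value dimension.
#' @param d_z Contrastive projection dimension.
#' @param mlp_hidden Classifier hidden units.
#' @param n_segments Superpixels per 40x patch.
#' @param dropout_rate MC head dropout.
#' @param n_classes Classes.
#' @return `model_config` list.
#' @export
model_config <- function(hidden_dim = 32L, n_heads = 4L, n_layers = 2L,
                         token_patch_px = 16L, d_k = 16L, d_z = 8L,
                         mlp_hidden = 16L, n_segments = 12L,
                         dropout_rate = 0.3, n_classes = 2L) {
  structure(as.list(environment()), class = "model_config")
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, opt, lr, wd, betas, eps = 1e-8) {
  opt$t <- opt$t + 1
  b1 <- betas[1]; b2 <- betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mh <- opt$m[[nm]] / (1 - b1^opt$t)
    vh <- opt$v[[nm]] / (1 - b2^opt$t)
    params[[nm]] <- params[[nm]] - lr * (mh / (sqrt(vh) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, opt = opt)
}

lr_at <- function(epoch, cfg) {
  if (epoch < cfg$warmup_epochs) return(cfg$lr * (epoch + 1) / cfg$warmup_epochs)
  prog <- (epoch - cfg$warmup_epochs) / max(1, cfg$epochs - cfg$warmup_epochs)
  cfg$lr * 0.5 * (1 + cos(pi * prog))
}

# ---- data preparation ------------------------------------------------------

pair_split <- function(pair_ids, val_every = 5L) {
  h <- (as.numeric(pair_ids) * 2654435761) %% 2^31
  val <- (h %% val_every) == 0
  if (all(val) || !any(val)) val <- seq_along(pair_ids) %% val_every == 0
  val
}

token_mask <- function(mask, grid, p) {
  out <- matrix(0, grid[1], grid[2])
  for (tc in seq_len(grid[2])) for (tr in seq_len(grid[1]))
    out[tr, tc] <- as.numeric(mean(mask[((tr - 1) * p + 1):(tr * p),
                                        ((tc - 1) * p + 1):(tc * p)]) > 0.5)
  out
}

# For each 40x token, the co-registered cell of the 10x context feature
# map: the token center is mapped through the crop offset into 10x pixels
# and then to the nearest conv-grid cell (two stride-2 valid 3x3 convs =
# stride 4, receptive-field center 4j + 3). Returns the n_tokens x hidden
# cell features and the token-center positions normalized to [0,1]^2.
context_cells_at_tokens <- function(cm, pr, grid, p) {
  vals <- cm$values
  nr <- dim(vals)[2]; nc <- dim(vals)[3]
  n_tok <- grid[1] * grid[2]
  cells <- matrix(0, n_tok, dim(vals)[1])
  pos <- matrix(0, n_tok, 2)
  side40 <- grid[1] * p
  t <- 1L
  for (tc in seq_len(grid[2])) for (tr in seq_len(grid[1])) {
    cy40 <- (tr - 0.5) * p; cx40 <- (tc - 0.5) * p          # 40x px
    cy10 <- pr$crop_offset[1] + cy40 / 4                     # 10x px
    cx10 <- pr$crop_offset[2] + cx40 / 4
    j <- min(max(round((cy10 - 3) / 4), 0), nr - 1)
    k <- min(max(round((cx10 - 3) / 4), 0), nc - 1)
    cells[t, ] <- vals[, j + 1, k + 1]
    pos[t, ] <- c(cy40 / side40, cx40 / side40)
    t <- t + 1L
  }
  list(cells = cells, pos = pos)
}

# morphometry map -> token embeddings via per-token channel means and a
# frozen linear embedding
morph_tokens <- function(map, grid, p, Wm) {
  M <- matrix(0, grid[1] * grid[2], 3)
  t <- 1L
  for (tc in seq_len(grid[2])) for (tr in seq_len(grid[1])) {
    for (ch in 1:3)
      M[t, ch] <- mean(map$channels[ch, ((tr - 1) * p + 1):(tr * p),
                                    ((tc - 1) * p + 1):(tc * p)])
    t <- t + 1L
  }
  M %*% Wm + pos_encoding(nrow(M), ncol(Wm))
}

# Freeze the full per-pair representation once per (data, encoder seed):
# everything the training loop touches repeatedly but that does not change
# with the trainable parameters. Memoized per (manifest, model, seed) so
# ablation modes sharing a seed reuse the frozen encoding.
.prep_cache <- new.env(parent = emptyenv())

prepare_pairs <- function(manifest, model_cfg, seed) {
  key <- paste(manifest$dir, length(manifest$records),
               paste(unlist(model_cfg), collapse = ","), seed, sep = "|")
  cached <- .prep_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- prepare_pairs_impl(manifest, model_cfg, seed)
  .prep_cache[[key]] <- out
  out
}

prepare_pairs_impl <- function(manifest, model_cfg, seed) {
  n <- length(manifest$records)
  cfg10 <- encoder_config("context10", hidden_dim = model_cfg$hidden_dim,
                          n_heads = model_cfg$n_heads,
                          dropout_rate = model_cfg$dropout_rate,
                          n_classes = model_cfg$n_classes)
  cfg40 <- encoder_config("cellular40", hidden_dim = model_cfg$hidden_dim,
                          n_heads = model_cfg$n_heads,
                          n_layers = model_cfg$n_layers,
                          token_patch_px = model_cfg$token_patch_px,
                          dropout_rate = model_cfg$dropout_rate,
                          n_classes = model_cfg$n_classes)
  enc10 <- init_context_encoder(cfg10, seed)
  enc40 <- init_cellular_encoder(cfg40, seed)
  Wm <- with_seed(mix_seed(seed, 41L),
                  rand_mat(3, model_cfg$hidden_dim, 1))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- load_pair(manifest, i)
    ts <- encode_cellular(pr$image40, enc40)
    cm <- encode_context(pr$image10, enc10)
    ct <- context_cells_at_tokens(cm, pr, ts$token_grid,
                                  cfg40$token_patch_px)
    sp <- generate_superpixels(pr$image40, model_cfg$n_segments, "slic")
    G <- build_tissue_graph(sp, pr$image40)
    asg <- assign_tokens(sp, ts$token_grid, cfg40$token_patch_px)
    mm <- voronoi_morphometry(pr$centroids, nrow(pr$image40))
    E_morph <- morph_tokens(mm, ts$token_grid, cfg40$token_patch_px, Wm)
    pairs[[i]] <- list(
      pair_id = pr$pair_id,
      label = if (pr$label == "tumor") 2L else 1L,
      f10 = cm$pooled,
      X_L = ts$last_input,
      f40 = colMeans(ts$last_input),
      E_morph = E_morph,
      G = G, assignment = asg,
      token_grid = ts$token_grid,
      tok_mask = token_mask(pr$mask40, ts$token_grid, cfg40$token_patch_px),
      has_mask = TRUE,
      E = texture_entropy(pr$image40),
      var_nuc = nuclei_density_variance(pr$centroids, nrow(pr$image40)),
      Z10cell = ct$cells, tok_pos = ct$pos)
  }
  list(pairs = pairs, enc10 = enc10, enc40 = enc40, Wm = Wm,
       cfg40 = cfg40, cfg10 = cfg10)
}

init_trainable <- function(model_cfg, enc40, seed) {
  d <- model_cfg$hidden_dim; C <- model_cfg$n_classes
  h10 <- new_mc_head(d, C, mix_seed(seed, 1L))
  h40 <- new_mc_head(d, C, mix_seed(seed, 2L))
  td <- attention_params(d, model_cfg$d_k, mix_seed(seed, 3L))
  hd <- classifier_head(model_cfg$d_k, model_cfg$mlp_hidden, C,
                        mix_seed(seed, 4L))
  last <- enc40$layers[[length(enc40$layers)]]
  params <- list(h10.W = h10$W, h10.b = h10$b, h40.W = h40$W, h40.b = h40$b,
                 td.WQ = td$W_Q, td.WK = td$W_K, td.WV = td$W_V,
                 td.W1 = hd$W1, td.b1 = hd$b1, td.W2 = hd$W2, td.b2 = hd$b2)
  with_seed(mix_seed(seed, 5L), {
    params$cz.W10 <- rand_mat(d, model_cfg$d_z, 1 / sqrt(d))
    params$cz.W40 <- rand_mat(d, model_cfg$d_z, 1 / sqrt(d))
  })
  for (h in seq_along(last$heads)) {
    params[[paste0("vit.Wq", h)]] <- last$heads[[h]]$Wq
    params[[paste0("vit.Wk", h)]] <- last$heads[[h]]$Wk
    params[[paste0("vit.Wv", h)]] <- last$heads[[h]]$Wv
  }
  params$vit.Wo <- last$Wo     # kept frozen (no gradient accumulated)
  params
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# last-layer attention for one pair under the current trainable parameters
last_layer_attn <- function(pair, params, n_heads) {
  X <- pair$X_L
  d <- ncol(X); dh <- d %/% n_heads
  sc <- 1 / sqrt(dh)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    Q <- X %*% params[[paste0("vit.Wq", h)]]
    K <- X %*% params[[paste0("vit.Wk", h)]]
    A <- softmax(Q %*% t(K) * sc)
    heads[[h]] <- list(A = A, Q = Q, K = K)
  }
  heads
}

branch_ce_dP <- function(P, label) {
  dP <- P * 0
  dP[label] <- -1 / max(P[label], 1e-12)
  dP
}

# backprop a dL/dP (mean-of-passes distribution) into head weight grads
mc_backprop <- function(f, sp, dP) {
  dW <- NULL; db <- NULL
  Tn <- sp$T
  for (t in seq_len(Tn)) {
    p <- sp$passes[[t]]
    dz <- p * (dP - sum(dP * p)) / Tn
    fm <- f * sp$masks[[t]]
    w <- outer(fm, dz)
    if (is.null(dW)) { dW <- w; db <- dz } else { dW <- dW + w; db <- db + dz }
  }
  list(dW = dW, db = db)
}

#' Train the multiscale model on a synthetic manifest
#'
#' Desk-scale trainer: the reference encoders stay frozen at their random
#' initialization while the Monte Carlo heads, the last transformer
#' layer's attention projections, the contrastive projections and the
#' cross-modal fusion block + classifier are optimized with AdamW under
#' the composite objective. Batches are drawn by the entropy-driven
#' curriculum sampler. Fully seeded: identical seeds give identical logs.
#'
#' @param manifest Dataset manifest ([generate_dataset()] /
#'   [read_manifest()]).
#' @param model_cfg A [model_config()].
#' @param loss_cfg A [composite_loss_config()].
#' @param train_cfg A [train_config()].
#' @param out_dir Run directory (created); receives `log.jsonl`,
#'   `metrics.json`, `complexity.csv`, `config.resolved.yaml` and the best
#'   checkpoint.
#' @return Invisibly, a list with `out_dir`, per-epoch `log`, final
#'   `metrics`, trained `params` and the frozen `prep` representation.
#' @export
train <- function(manifest, model_cfg = model_config(),
                  loss_cfg = composite_loss_config(),
                  train_cfg = train_config(),
                  out_dir = tempfile("run")) {
  if (length(manifest$records) < 2) stop_invalid("empty or degenerate manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_pairs(manifest, model_cfg, train_cfg$seed)
  pairs <- prep$pairs
  n <- length(pairs)
  val <- pair_split(vapply(pairs, `[[`, 0, "pair_id"))
  if (!any(val) || all(val)) stop_invalid("empty train/val split")
  tr_idx <- which(!val); va_idx <- which(val)

  cur <- curriculum_state(beta = loss_cfg$beta,
                          schedule = c(0.2, 0.8, max(1, train_cfg$epochs %/% 2)))
  pool <- data.frame(pair_id = seq_along(tr_idx),
                     xi = vapply(pairs[tr_idx], function(p)
                       complexity_score(p$E, p$var_nuc, cur$lambda1,
                                        cur$lambda2), 0))

  params <- init_trainable(model_cfg, prep$enc40, train_cfg$seed)
  opt <- adamw_init(params)
  nb <- max(1L, length(tr_idx) %/% train_cfg$batch_size)
  bs <- min(train_cfg$batch_size, length(tr_idx))
  use_dice <- train_cfg$early_stop_metric == "dice" ||
    (train_cfg$early_stop_metric == "auto" &&
       all(vapply(pairs, `[[`, TRUE, "has_mask")))

  log <- list()
  best <- -Inf; best_params <- params; best_epoch <- -1L
  for (epoch in 0:(train_cfg$epochs - 1)) {
    cur$epoch <- epoch
    cur <- update_threshold(pool, cur)
    lr <- lr_at(epoch, train_cfg)
    comps <- c(sup = 0, pauac = 0, sacgr = 0, cccra = 0, smooth = 0)
    batch_xi <- numeric(0)
    for (b in seq_len(nb)) {
      ids <- sample_batch(pool, cur, bs, seed = mix_seed(train_cfg$seed, b, 53L))
      batch <- pairs[tr_idx[ids]]
      batch_xi <- c(batch_xi, mean(pool$xi[ids]))
      res <- batch_grads(batch, params, model_cfg, loss_cfg, train_cfg,
                         epoch, b)
      comps <- comps + res$comps / nb
      st <- adamw_step(params, res$grads, opt, lr, train_cfg$weight_decay,
                       train_cfg$betas)
      params <- st$params; opt <- st$opt
    }
    ev <- evaluate_pairs(pairs[va_idx], params, model_cfg, loss_cfg,
                         mc_seed = mix_seed(train_cfg$seed, 997L))
    metric <- if (use_dice) ev$dice else ev$auc
    if (!is.finite(metric)) metric <- ev$dice
    if (metric >= best) { best <- metric; best_params <- params; best_epoch <- epoch }
    entry <- list(epoch = epoch, lr = lr, mu_t = cur$mu_t,
                  mean_batch_xi = mean(batch_xi),
                  `loss/sup` = comps[["sup"]], `loss/pauac` = comps[["pauac"]],
                  `loss/sacgr` = comps[["sacgr"]],
                  `loss/cccra` = comps[["cccra"]],
                  `loss/smooth` = comps[["smooth"]],
                  `loss/total` = total_loss(comps[["sup"]], comps[["pauac"]],
                                            comps[["sacgr"]], comps[["cccra"]],
                                            loss_cfg) +
                    loss_cfg$smoothness_weight * comps[["smooth"]],
                  dice = ev$dice, auc = ev$auc, nmi = ev$nmi,
                  attention_precision = ev$attention_precision,
                  `entropy10/mean` = ev$mean_entropy10,
                  `entropy40/mean` = ev$mean_entropy40,
                  val_kl = ev$val_kl, off_graph_mass = ev$off_graph_mass)
    log[[length(log) + 1]] <- entry
  }
  metrics <- evaluate_pairs(pairs[va_idx], best_params, model_cfg, loss_cfg,
                            mc_seed = mix_seed(train_cfg$seed, 997L))
  metrics$best_epoch <- best_epoch
  writeLines(vapply(log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), ""),
    file.path(out_dir, "log.jsonl"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  ct <- data.frame(pair_id = pool$pair_id,
                   E_bits = vapply(pairs[tr_idx], `[[`, 0, "E"),
                   var_nuc = vapply(pairs[tr_idx], `[[`, 0, "var_nuc"),
                   xi = pool$xi,
                   p_select = selection_probability(pool$xi, cur))
  utils::write.csv(ct, file.path(out_dir, "complexity.csv"), row.names = FALSE)
  yaml::write_yaml(list(model = unclass(model_cfg), loss = unclass(loss_cfg),
                        train = unclass(train_cfg)),
                   file.path(out_dir, "config.resolved.yaml"))
  saveRDS(best_params, file.path(out_dir, "best_params.rds"))
  invisible(list(out_dir = out_dir, log = log, metrics = metrics,
                 params = best_params, prep = prep, val_idx = va_idx))
}

# gradients and loss components for one mini-batch
batch_grads <- function(batch, params, model_cfg, loss_cfg, train_cfg,
                        epoch, bidx) {
  grads <- zero_like(params)
  grads$vit.Wo <- NULL
  nB <- length(batch)
  C <- model_cfg$n_classes
  l_sup <- l_pauac <- l_sacgr <- l_smooth <- 0
  h10 <- list(W = params$h10.W, b = params$h10.b)
  h40 <- list(W = params$h40.W, b = params$h40.b)
  tdP <- structure(list(W_Q = params$td.WQ, W_K = params$td.WK,
                        W_V = params$td.WV, d_k = model_cfg$d_k),
                   class = "attention_params")
  tdH <- structure(list(W1 = params$td.W1, b1 = params$td.b1,
                        W2 = params$td.W2, b2 = params$td.b2),
                   class = "classifier_head")
  pcfg <- pauac_config(alpha = loss_cfg$alpha)
  n_heads <- model_cfg$n_heads
  dh <- model_cfg$hidden_dim %/% n_heads
  sc <- 1 / sqrt(dh)

  for (k in seq_len(nB)) {
    pr <- batch[[k]]
    ms <- mix_seed(train_cfg$seed, epoch, bidx, k)
    sp10 <- mc_forward(h10, pr$f10, train_cfg$T_mc, model_cfg$dropout_rate,
                       mix_seed(ms, 1L))
    sp40 <- mc_forward(h40, pr$f40, train_cfg$T_mc, model_cfg$dropout_rate,
                       mix_seed(ms, 2L))
    P10 <- predictive_distribution(sp10)
    P40 <- predictive_distribution(sp40)

    # supervised: fused CE + 0.5 * branch CEs
    td <- tdmm_ce_grad(pr$X_L, pr$E_morph, tdP, tdH, pr$label)
    l_sup <- l_sup + td$loss / nB
    for (nm in c("dW_Q", "dW_K", "dW_V"))
      grads[[sub("d", "td.", sub("_", "", nm))]] <-
        grads[[sub("d", "td.", sub("_", "", nm))]] + td[[nm]] / nB
    grads$td.W1 <- grads$td.W1 + td$dW1 / nB
    grads$td.b1 <- grads$td.b1 + td$db1 / nB
    grads$td.W2 <- grads$td.W2 + td$dW2 / nB
    grads$td.b2 <- grads$td.b2 + td$db2 / nB

    ce10 <- -log(max(P10[pr$label], 1e-12))
    ce40 <- -log(max(P40[pr$label], 1e-12))
    l_sup <- l_sup + 0.5 * (ce10 + ce40) / nB
    dP10 <- 0.5 * branch_ce_dP(P10, pr$label)
    dP40 <- 0.5 * branch_ce_dP(P40, pr$label)

    if (loss_cfg$lambda_pauac > 0) {
      pg <- pauac_grad_P(P10, P40, pcfg)
      l_pauac <- l_pauac + pg$loss / nB
      dP10 <- dP10 + loss_cfg$lambda_pauac * as.numeric(pg$dP10)
      dP40 <- dP40 + loss_cfg$lambda_pauac * as.numeric(pg$dP40)
    }
    g10 <- mc_backprop(pr$f10, sp10, dP10)
    g40 <- mc_backprop(pr$f40, sp40, dP40)
    grads$h10.W <- grads$h10.W + g10$dW / nB
    grads$h10.b <- grads$h10.b + g10$db / nB
    grads$h40.W <- grads$h40.W + g40$dW / nB
    grads$h40.b <- grads$h40.b + g40$db / nB

    if (loss_cfg$lambda_sacgr > 0) {
      heads <- last_layer_attn(pr, params, n_heads)
      Tm <- Reduce(`+`, lapply(heads, `[[`, "A")) / n_heads
      sg <- sacgr_grad_token_attn(pr$G, Tm, pr$assignment)
      l_sacgr <- l_sacgr + sg$loss / nB
      dA_heads <- lapply(seq_len(n_heads), function(h)
        loss_cfg$lambda_sacgr * sg$dT / n_heads)

      if (loss_cfg$smoothness_weight > 0) {
        # tokens after the last layer under current params
        X <- pr$X_L
        Vh <- lapply(seq_len(n_heads), function(h)
          X %*% params[[paste0("vit.Wv", h)]])
        outc <- do.call(cbind, lapply(seq_len(n_heads), function(h)
          heads[[h]]$A %*% Vh[[h]]))
        Y <- X + outc %*% params$vit.Wo
        smg <- smoothness_grad_tokens(Y, pr$assignment, pr$G)
        l_smooth <- l_smooth + smg$loss / nB
        # the smoothness companion shapes token features only (value
        # projections); attention shape is left to the structural loss
        dout <- (loss_cfg$smoothness_weight * smg$dF) %*% t(params$vit.Wo)
        for (h in seq_len(n_heads)) {
          colsel <- ((h - 1) * dh + 1):(h * dh)
          dHV <- dout[, colsel, drop = FALSE]
          grads[[paste0("vit.Wv", h)]] <- grads[[paste0("vit.Wv", h)]] +
            t(X) %*% (t(heads[[h]]$A) %*% dHV) / nB
        }
      }
      for (h in seq_len(n_heads)) {
        A <- heads[[h]]$A
        dA <- dA_heads[[h]]
        dS <- A * (dA - rowSums(dA * A))
        grads[[paste0("vit.Wq", h)]] <- grads[[paste0("vit.Wq", h)]] +
          t(pr$X_L) %*% (dS %*% heads[[h]]$K * sc) / nB
        grads[[paste0("vit.Wk", h)]] <- grads[[paste0("vit.Wk", h)]] +
          t(pr$X_L) %*% (t(dS) %*% heads[[h]]$Q * sc) / nB
      }
    }
  }

  # cell-level contrastive alignment: within each pair, every 40x token and
  # its co-registered 10x context cell form a positive; the pair's other
  # tokens are the negatives, with token-center positions as the positional
  # signal
  l_cccra <- 0
  if (loss_cfg$lambda_cccra > 0) {
    for (k in seq_len(nB)) {
      pr <- batch[[k]]
      z10 <- pr$Z10cell %*% params$cz.W10
      z40 <- pr$X_L %*% params$cz.W40
      if (min(rowSums(z10^2), rowSums(z40^2)) <= 1e-20) next
      cb <- contrastive_batch(z10, z40, pr$tok_pos, pr$tok_pos,
                              gamma = loss_cfg$gamma, tau = loss_cfg$tau)
      cg <- cccra_grad(cb)
      l_cccra <- l_cccra + cg$loss / nB
      grads$cz.W10 <- grads$cz.W10 +
        loss_cfg$lambda_cccra * t(pr$Z10cell) %*% cg$dz10 / nB
      grads$cz.W40 <- grads$cz.W40 +
        loss_cfg$lambda_cccra * t(pr$X_L) %*% cg$dz40 / nB
    }
  }
  # parameter groups whose losses are switched off receive no update at all
  # (not even weight decay), so ablation modes leave them at initialization
  if (loss_cfg$lambda_sacgr <= 0 && loss_cfg$smoothness_weight <= 0)
    for (nm in grep("^vit\\.", names(grads), value = TRUE)) grads[nm] <- list(NULL)
  if (loss_cfg$lambda_cccra <= 0) {
    grads["cz.W10"] <- list(NULL)
    grads["cz.W40"] <- list(NULL)
  }
  list(grads = grads,
       comps = c(sup = l_sup, pauac = l_pauac, sacgr = l_sacgr,
                 cccra = l_cccra, smooth = l_smooth))
}

# evaluation over a set of prepared pairs under given parameters
evaluate_pairs <- function(pairs, params, model_cfg, loss_cfg, mc_seed = 1L) {
  h10 <- list(W = params$h10.W, b = params$h10.b)
  h40 <- list(W = params$h40.W, b = params$h40.b)
  tdP <- structure(list(W_Q = params$td.WQ, W_K = params$td.WK,
                        W_V = params$td.WV, d_k = model_cfg$d_k),
                   class = "attention_params")
  tdH <- structure(list(W1 = params$td.W1, b1 = params$td.b1,
                        W2 = params$td.W2, b2 = params$td.b2),
                   class = "classifier_head")
  n <- length(pairs)
  scores <- numeric(n); labels <- integer(n)
  H10s <- H40s <- kls <- ogm <- numeric(n)
  ap <- numeric(0)
  pred_tok <- true_tok <- numeric(0)
  z10 <- matrix(0, n, model_cfg$d_z); z40 <- matrix(0, n, model_cfg$d_z)
  pcfg <- pauac_config(alpha = loss_cfg$alpha)
  for (i in seq_len(n)) {
    pr <- pairs[[i]]
    sp10 <- mc_forward(h10, pr$f10, 10L, model_cfg$dropout_rate,
                       mix_seed(mc_seed, i, 1L))
    sp40 <- mc_forward(h40, pr$f40, 10L, model_cfg$dropout_rate,
                       mix_seed(mc_seed, i, 2L))
    P10 <- predictive_distribution(sp10); P40 <- predictive_distribution(sp40)
    H10s[i] <- predictive_entropy(P10); H40s[i] <- predictive_entropy(P40)
    kls[i] <- kl_rows(matrix(P10, 1), matrix(P40, 1))
    fu <- cross_modal_attention(pr$X_L, pr$E_morph, tdP)
    pfused <- classify(fu$F, tdH)
    scores[i] <- pfused[2]
    labels[i] <- pr$label - 1L
    # token-level dense prediction from the 40x head (dropout off)
    ztok <- pr$X_L %*% h40$W + rep(h40$b, each = nrow(pr$X_L))
    ptok <- softmax(ztok)[, 2]
    pred_tok <- c(pred_tok, as.numeric(ptok > 0.5))
    true_tok <- c(true_tok, as.vector(pr$tok_mask))
    heads <- last_layer_attn(pr, params, model_cfg$n_heads)
    attn_list <- list(array(unlist(lapply(heads, `[[`, "A")),
                            c(nrow(pr$X_L), nrow(pr$X_L), model_cfg$n_heads)))
    attn_arr <- aperm(attn_list[[1]], c(3, 1, 2))
    ogm[i] <- off_graph_attention_mass(list(attn_arr), pr$assignment, pr$G)
    if (labels[i] == 1 && any(pr$tok_mask > 0)) {
      tok_imp <- colMeans(Reduce(`+`, lapply(heads, `[[`, "A")) /
                            model_cfg$n_heads)
      imp <- matrix(tok_imp, pr$token_grid[1], pr$token_grid[2])
      ap <- c(ap, attention_precision(imp, pr$tok_mask, 0.2))
    }
    z10[i, ] <- colMeans(pr$Z10cell %*% params$cz.W10)
    z40[i, ] <- colMeans(pr$X_L %*% params$cz.W40)
  }
  auc_val <- if (length(unique(labels)) > 1) auc(scores, labels) else NA_real_
  # embedding consistency is measured at cell level, where the contrastive
  # alignment operates: all validation tokens of each view are clustered
  Z10t <- do.call(rbind, lapply(pairs, function(p) p$Z10cell %*% params$cz.W10))
  Z40t <- do.call(rbind, lapply(pairs, function(p) p$X_L %*% params$cz.W40))
  nmi_val <- if (nrow(Z10t) > 2)
    tryCatch(cross_mag_nmi(Z10t, Z40t, k = 2, seed = mc_seed),
             error = function(e) NA_real_)
  else NA_real_
  list(dice = dice(pred_tok, true_tok), auc = auc_val, nmi = nmi_val,
       attention_precision = if (length(ap)) mean(ap) else NA_real_,
       mean_entropy10 = mean(H10s), mean_entropy40 = mean(H40s),
       val_kl = mean(kls), off_graph_mass = mean(ogm),
       n_val = n)
}

#' Run the module-ablation harness
#'
#' Trains one run per `mode x seed`, where each mode zeroes exactly one
#' composite-loss weight (`no_pauac`, `no_sacgr`, `no_cccra`) or none
#' (`full`), and summarizes the final validation metrics per mode with
#' median and IQR over seeds.
#'
#' @param manifest Dataset manifest.
#' @param model_cfg,loss_cfg,train_cfg Base configurations.
#' @param modes Subset of `c("full", "no_pauac", "no_sacgr", "no_cccra")`.
#' @param seeds Integer vector of seeds.
#' @param out_dir Output directory; receives `ablation.csv`.
#' @return List with `runs` (per-run metrics data.frame) and `summary`
#'   (per-mode medians/IQRs).
#' @export
ablate <- function(manifest, model_cfg = model_config(),
                   loss_cfg = composite_loss_config(),
                   train_cfg = train_config(),
                   modes = c("full", "no_pauac", "no_sacgr", "no_cccra"),
                   seeds = 1:3, out_dir = tempfile("ablate")) {
  known <- c("full", "no_pauac", "no_sacgr", "no_cccra")
  if (!all(modes %in% known)) stop_invalid("unknown ablation mode")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (mode in modes) for (sd in seeds) {
    lc <- loss_cfg
    if (mode == "no_pauac") lc$lambda_pauac <- 0
    if (mode == "no_sacgr") { lc$lambda_sacgr <- 0; lc$smoothness_weight <- 0 }
    if (mode == "no_cccra") lc$lambda_cccra <- 0
    tc <- train_cfg; tc$seed <- as.integer(sd)
    fit <- train(manifest, model_cfg, lc, tc,
                 out_dir = file.path(out_dir, sprintf("%s_seed%d", mode, sd)))
    m <- fit$metrics
    # training-dynamics quantities are read from the final epoch's state;
    # headline classification metrics from the early-stop checkpoint
    fin <- fit$log[[length(fit$log)]]
    rows[[length(rows) + 1]] <-
      data.frame(mode = mode, seed = sd, dice = m$dice, auc = m$auc,
                 nmi = fin$nmi, attention_precision = m$attention_precision,
                 val_kl = fin$val_kl, off_graph_mass = fin$off_graph_mass)
  }
  runs <- do.call(rbind, rows)
  num <- c("dice", "auc", "nmi", "attention_precision", "val_kl",
           "off_graph_mass")
  summ <- do.call(rbind, lapply(split(runs, runs$mode), function(df) {
    out <- data.frame(mode = df$mode[1])
    for (v in num) {
      out[[paste0(v, "_median")]] <- stats::median(df[[v]], na.rm = TRUE)
      out[[paste0(v, "_iqr")]] <- stats::IQR(df[[v]], na.rm = TRUE)
    }
    out
  }))
  utils::write.csv(runs, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  list(runs = runs, summary = summ)
}
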