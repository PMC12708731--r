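#' Specification for the synthetic paired-magnification H&E generator
#'
#' Describes one family of synthetic slides: canvas size, nuclear counts and
#' geometry, tumor prevalence, stain palette and noise level. The generator
#' renders a high-resolution canvas (the 40x frame), derives the 40x patch as
#' the central crop at native resolution and the 10x patch as the 4x
#' block-mean downsample of the whole canvas, so the two views are
#' co-registered by construction (a 4x linear scale separates 10x and 40x
#' objectives).
#'
#' Tumor patches contain an elliptical tumor blob with denser, more
#' pleomorphic nuclei; `pleomorphism` multiplies the radius and eccentricity
#' variability inside the blob. Identical `spec` + seed give bit-identical
#' output.
#'
#' @param seed Integer base seed; combined with each `pair_id`.
#' @param canvas_px Side of the high-resolution rendering canvas in 40x
#'   pixels (must be a positive multiple of 16; default 512, giving 128 px
#'   patches at both magnifications).
#' @param n_nuclei_normal,n_nuclei_tumor Nuclei rendered per patch outside /
#'   inside the tumor blob.
#' @param tumor_fraction Probability that a patch carries a tumor blob.
#' @param nucleus_radius_px Length-2 numeric `(mean, sd)` of the nucleus
#'   radius at 40x scale.
#' @param pleomorphism Non-negative multiplier of radius/eccentricity
#'   variability in tumor regions.
#' @param stain_palette List with `eosin` (background) and `hematoxylin`
#'   (nuclei) RGB triplets in `[0,1]`.
#' @param noise_sd Standard deviation of per-pixel additive noise.
#' @return An object of class `slide_spec`.
#' @examples
#' sp <- slide_spec(seed = 1, canvas_px = 128)
#' pair <- generate_patch_pair(sp, 1)
#' dim(pair$image10)
#' @export
slide_spec <- function(seed = 1L, canvas_px = 512L,
                       n_nuclei_normal = 60L, n_nuclei_tumor = 180L,
                       tumor_fraction = 0.5,
                       nucleus_radius_px = c(6, 1.5),
                       pleomorphism = 1.5,
                       stain_palette = list(eosin = c(0.93, 0.77, 0.85),
                                            hematoxylin = c(0.34, 0.21, 0.55)),
                       noise_sd = 0.03) {
  if (!is.numeric(canvas_px) || length(canvas_px) != 1 || canvas_px <= 0)
    stop_invalid("invalid spec: canvas_px must be a positive integer")
  if (canvas_px %% 16 != 0)
    stop_invalid("invalid spec: canvas_px must be a multiple of 16")
  if (n_nuclei_normal < 0 || n_nuclei_tumor < 0)
    stop_invalid("invalid spec: nucleus counts must be >= 0")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop_invalid("invalid spec: tumor_fraction must be in [0,1]")
  if (pleomorphism < 0) stop_invalid("invalid spec: pleomorphism must be >= 0")
  if (noise_sd < 0) stop_invalid("invalid spec: noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), canvas_px = as.integer(canvas_px),
                 n_nuclei_normal = as.integer(n_nuclei_normal),
                 n_nuclei_tumor = as.integer(n_nuclei_tumor),
                 tumor_fraction = tumor_fraction,
                 nucleus_radius_px = as.numeric(nucleus_radius_px),
                 pleomorphism = pleomorphism,
                 stain_palette = stain_palette,
                 noise_sd = noise_sd),
            class = "slide_spec")
}

# Rasterize one filled, rotated ellipse into `img` (H x W x 3) and `mask`
# support matrix; returns the modified image. Coordinates are 0-based
# (x = column, y = row).
draw_ellipse <- function(img, cx, cy, a, b, theta, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(a, b)
  r0 <- max(1, floor(cy - r) + 1); r1 <- min(H, ceiling(cy + r) + 1)
  c0 <- max(1, floor(cx - r) + 1); c1 <- min(W, ceiling(cx + r) + 1)
  if (r0 > r1 || c0 > c1) return(img)
  ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u * u + v * v) <= 1
  if (!any(inside)) return(img)
  for (ch in 1:3) {
    sub <- img[r0:r1, c0:c1, ch]
    sub[inside] <- color[ch]
    img[r0:r1, c0:c1, ch] <- sub
  }
  img
}

#' Generate one co-registered 10x/40x synthetic patch pair
#'
#' Renders a high-resolution canvas with an eosin-toned textured background
#' and hematoxylin-toned elliptical nuclei, optionally with an elliptical
#' tumor blob (denser, more pleomorphic nuclei). The 40x patch is the
#' central `canvas_px/4` crop at native resolution; the 10x patch is the 4x
#' block-mean downsample of the full canvas, so the 40x field of view is the
#' central quarter-side region of the 10x patch.
#'
#' @param spec A [slide_spec()].
#' @param pair_id Integer id; combined with `spec$seed` for determinism.
#' @return A list of class `multires_patch_pair` with elements `image10`,
#'   `image40` (H x W x 3 arrays in `[0,1]`, 8-bit quantized), `mask10`,
#'   `mask40` (binary matrices, 1 = tumor), `centroids` (data.frame
#'   `x,y,radius,cls` in the 40x frame, 0-based), `all_nuclei` (same columns
#'   in canvas coordinates, every rendered nucleus), `label`
#'   (`"tumor"`/`"normal"`), `crop_offset` (0-based `(row, col)` of the 40x
#'   field of view inside the 10x patch, in 10x pixels) and `pair_id`.
#' @export
generate_patch_pair <- function(spec, pair_id) {
  stopifnot(inherits(spec, "slide_spec"))
  C <- spec$canvas_px
  with_seed(mix_seed(spec$seed, pair_id, 101L), {
    eo <- spec$stain_palette$eosin
    hx <- spec$stain_palette$hematoxylin

    field <- matrix(stats::rnorm(C * C), C, C)
    field <- blur_box(field, max(2, C %/% 32))
    field <- field / max(stats::sd(field), 1e-8)
    canvas <- array(0, c(C, C, 3))
    for (ch in 1:3)
      canvas[, , ch] <- eo[ch] + 0.05 * field +
        stats::rnorm(C * C, sd = spec$noise_sd)

    # tumor blob: ellipse centered inside the central 40x field of view so
    # that a blob always intersects the 40x mask
    has_tumor <- stats::runif(1) < spec$tumor_fraction
    tmask <- matrix(0, C, C)
    blob <- NULL
    if (has_tumor) {
      cx <- stats::runif(1, 3 * C / 8, 5 * C / 8)
      cy <- stats::runif(1, 3 * C / 8, 5 * C / 8)
      a <- stats::runif(1, C / 8, C / 4)
      b <- stats::runif(1, C / 8, C / 4)
      th <- stats::runif(1, 0, pi)
      blob <- list(cx = cx, cy = cy, a = a, b = b, th = th)
      ys <- outer(0:(C - 1), rep(1, C)); xs <- t(ys)
      u <- ((xs - cx) * cos(th) + (ys - cy) * sin(th)) / a
      v <- (-(xs - cx) * sin(th) + (ys - cy) * cos(th)) / b
      tmask[u * u + v * v <= 1] <- 1
      # subtle eosinophilic shift inside the blob so texture differs
      for (ch in 1:3)
        canvas[, , ch] <- canvas[, , ch] - 0.03 * tmask
    }

    in_blob <- function(x, y) {
      if (is.null(blob)) return(rep(FALSE, length(x)))
      u <- ((x - blob$cx) * cos(blob$th) + (y - blob$cy) * sin(blob$th)) / blob$a
      v <- (-(x - blob$cx) * sin(blob$th) + (y - blob$cy) * cos(blob$th)) / blob$b
      u * u + v * v <= 1
    }

    mu <- spec$nucleus_radius_px[1]; sdev <- spec$nucleus_radius_px[2]
    nx <- ny <- nr <- necc <- nth <- numeric(0)
    ncls <- character(0)
    if (spec$n_nuclei_normal > 0) {
      n <- spec$n_nuclei_normal
      nx <- stats::runif(n, 0, C - 1e-9)
      ny <- stats::runif(n, 0, C - 1e-9)
      nr <- pmax(1.5, stats::rnorm(n, mu, sdev))
      necc <- pmax(0.4, pmin(1, stats::rnorm(n, 0.85, 0.07)))
      nth <- stats::runif(n, 0, pi)
      ncls <- rep("normal", n)
    }
    if (has_tumor && spec$n_nuclei_tumor > 0) {
      n <- spec$n_nuclei_tumor
      # uniform sampling inside the blob ellipse
      rad <- sqrt(stats::runif(n)); ang <- stats::runif(n, 0, 2 * pi)
      ex <- rad * cos(ang) * blob$a; ey <- rad * sin(ang) * blob$b
      tx <- blob$cx + ex * cos(blob$th) - ey * sin(blob$th)
      ty <- blob$cy + ex * sin(blob$th) + ey * cos(blob$th)
      keep <- tx >= 0 & tx < C & ty >= 0 & ty < C
      n <- sum(keep)
      pf <- 1 + spec$pleomorphism
      nx <- c(nx, tx[keep]); ny <- c(ny, ty[keep])
      nr <- c(nr, pmax(1.5, stats::rnorm(n, mu * 1.15, sdev * pf)))
      necc <- c(necc, pmax(0.3, pmin(1, stats::rnorm(n, 0.8, 0.07 * pf))))
      nth <- c(nth, stats::runif(n, 0, pi))
      ncls <- c(ncls, rep("tumor", n))
    }
    # class follows the tumor mask, so centroid/mask coherence holds even for
    # "normal-pool" nuclei that happen to land inside the blob
    if (length(nx)) ncls[in_blob(nx, ny)] <- "tumor"

    for (i in seq_along(nx)) {
      col <- pmin(pmax(hx + stats::rnorm(3, sd = 0.03), 0), 1)
      canvas <- draw_ellipse(canvas, nx[i], ny[i], nr[i], nr[i] * necc[i],
                             nth[i], col)
    }

    canvas <- quantize8(canvas)
    q <- C %/% 4                       # patch side at both magnifications
    off <- 3 * C %/% 8                 # 0-based crop origin in canvas px
    image10 <- quantize8(block_mean(canvas, 4))
    image40 <- canvas[(off + 1):(off + q), (off + 1):(off + q), , drop = FALSE]
    mask40 <- tmask[(off + 1):(off + q), (off + 1):(off + q)]
    mask10 <- block_max(tmask, 4)

    inside <- if (length(nx)) nx >= off & nx < off + q & ny >= off & ny < off + q
              else logical(0)
    centroids <- data.frame(x = nx[inside] - off, y = ny[inside] - off,
                            radius = nr[inside], cls = ncls[inside],
                            stringsAsFactors = FALSE)
    all_nuclei <- data.frame(x = nx, y = ny, radius = nr, cls = ncls,
                             stringsAsFactors = FALSE)

    structure(list(
      image10 = image10, image40 = image40,
      mask10 = mask10, mask40 = mask40,
      centroids = centroids, all_nuclei = all_nuclei,
      label = if (any(mask40 > 0)) "tumor" else "normal",
      crop_offset = c(row = 3 * C %/% 32, col = 3 * C %/% 32),
      pair_id = pair_id
    ), class = "multires_patch_pair")
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes, for each pair, the 10x/40x images and masks as PNG, the in-frame
#' centroid table as CSV (`x,y,radius,cls`, 40x frame, 0-based), and a JSON
#' manifest listing all records with paths relative to the manifest.
#'
#' @param spec A [slide_spec()].
#' @param n_pairs Number of patch pairs (>= 1).
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a list (invisibly also written to
#'   `manifest.json`).
#' @export
generate_dataset <- function(spec, n_pairs, out_dir) {
  stopifnot(inherits(spec, "slide_spec"))
  if (n_pairs < 1) stop_invalid("n_pairs must be >= 1")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_invalid("cannot create output dir '%s'", out_dir)
  records <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pair <- generate_patch_pair(spec, i)
    base <- sprintf("pair_%04d", i)
    paths <- list(image10 = paste0(base, "_image10.png"),
                  image40 = paste0(base, "_image40.png"),
                  mask10 = paste0(base, "_mask10.png"),
                  mask40 = paste0(base, "_mask40.png"),
                  centroids = paste0(base, "_centroids.csv"))
    png::writePNG(pair$image10, file.path(out_dir, paths$image10))
    png::writePNG(pair$image40, file.path(out_dir, paths$image40))
    png::writePNG(pair$mask10, file.path(out_dir, paths$mask10))
    png::writePNG(pair$mask40, file.path(out_dir, paths$mask40))
    utils::write.csv(pair$centroids, file.path(out_dir, paths$centroids),
                     row.names = FALSE)
    records[[i]] <- c(list(pair_id = i, label = pair$label,
                           seed = mix_seed(spec$seed, i, 101L)), paths)
  }
  manifest <- list(spec = unclass(spec), records = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$dir <- out_dir
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param path Path to `manifest.json` or to its directory.
#' @return Manifest list with a `dir` element added.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$dir <- dirname(normalizePath(path))
  m
}

#' Load one patch pair from a manifest record
#' @param manifest Manifest list from [read_manifest()] or
#'   [generate_dataset()].
#' @param i Record index.
#' @return A `multires_patch_pair` (without `all_nuclei`).
#' @export
load_pair <- function(manifest, i) {
  rec <- manifest$records[[i]]
  rd <- function(p) png::readPNG(file.path(manifest$dir, p))
  cen <- utils::read.csv(file.path(manifest$dir, rec$centroids),
                         stringsAsFactors = FALSE)
  C <- manifest$spec$canvas_px
  structure(list(image10 = rd(rec$image10), image40 = rd(rec$image40),
                 mask10 = round(rd(rec$mask10)), mask40 = round(rd(rec$mask40)),
                 centroids = cen, label = rec$label,
                 crop_offset = c(row = 3 * C %/% 32, col = 3 * C %/% 32),
                 pair_id = rec$pair_id),
            class = "multires_patch_pair")
}

#' Superpixel segmentation (SLIC or regular grid)
#'
#' `grid` tiles the image into `ceiling(sqrt(n_segments))^2` rectangles and
#' is the dependency-free fallback; `slic` runs a compact SLIC: cluster
#' centers seeded on a regular grid, iterated local k-means under the joint
#' color + spatial distance `d = ||c_i - c_p||^2 + m^2 * (||s_i - s_p|| / S)^2`
#' with grid interval `S = sqrt(HW/n)` and compactness `m` in color units.
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param n_segments Target number of superpixels (>= 1, <= pixel count).
#' @param method `"slic"` or `"grid"`.
#' @param compactness SLIC spatial regularization in color units.
#' @param iterations SLIC iterations.
#' @return Integer label matrix, labels contiguous from 0.
#' @export
generate_superpixels <- function(image, n_segments, method = c("slic", "grid"),
                                 compactness = 0.05, iterations = 10) {
  method <- match.arg(method)
  if (!is_rgb_array(image)) stop_invalid("image must be an H x W x 3 array")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (n_segments < 1) stop_invalid("n_segments must be >= 1")
  if (n_segments > H * W) stop_invalid("n_segments exceeds pixel count")
  if (method == "grid") {
    k <- ceiling(sqrt(n_segments))
    br <- floor((seq_len(H) - 1) * k / H)
    bc <- floor((seq_len(W) - 1) * k / W)
    return(matrix(as.integer(rep(br, times = W) * k + rep(bc, each = H)),
                  H, W))
  }
  # SLIC: over-seed slightly, iterate local k-means, then merge adjacent
  # clusters of closest mean color back down to n_segments
  S <- sqrt(H * W / n_segments)
  gr <- max(1, round(H / S)); gc <- max(1, round(W / S))
  while (gr * gc < n_segments) {
    if (H / gr >= W / gc) gr <- gr + 1 else gc <- gc + 1
  }
  if (gr * gc == n_segments && n_segments > 1) {
    # one extra seed row/column of slack for the color-driven merge stage
    if (H / gr >= W / gc) gr <- gr + 1 else gc <- gc + 1
  }
  cy <- (seq_len(gr) - 0.5) * H / gr
  cx <- (seq_len(gc) - 0.5) * W / gc
  centers <- expand.grid(y = cy, x = cx)
  nc <- nrow(centers)
  ccol <- matrix(0, nc, 3)
  for (j in seq_len(nc))
    ccol[j, ] <- image[round(centers$y[j]), round(centers$x[j]), ]
  px_y <- rep(seq_len(H), times = W); px_x <- rep(seq_len(W), each = H)
  imgm <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  lab <- rep(1L, H * W)
  best <- rep(Inf, H * W)
  for (it in seq_len(iterations)) {
    best[] <- Inf
    for (j in seq_len(nc)) {
      r0 <- max(1, floor(centers$y[j] - 2 * S)); r1 <- min(H, ceiling(centers$y[j] + 2 * S))
      c0 <- max(1, floor(centers$x[j] - 2 * S)); c1 <- min(W, ceiling(centers$x[j] + 2 * S))
      idx <- as.vector(outer(r0:r1, ((c0:c1) - 1) * H, `+`))
      dc <- (imgm[idx, 1] - ccol[j, 1])^2 + (imgm[idx, 2] - ccol[j, 2])^2 +
        (imgm[idx, 3] - ccol[j, 3])^2
      ds <- ((px_y[idx] - centers$y[j])^2 + (px_x[idx] - centers$x[j])^2) / S^2
      d <- dc + compactness^2 * ds
      upd <- d < best[idx]
      best[idx[upd]] <- d[upd]
      lab[idx[upd]] <- j
    }
    # any pixel outside all windows: nearest center spatially
    miss <- !is.finite(best)
    if (any(miss)) {
      for (i in which(miss)) {
        d <- (px_y[i] - centers$y)^2 + (px_x[i] - centers$x)^2
        lab[i] <- which.min(d)
      }
    }
    for (j in seq_len(nc)) {
      sel <- lab == j
      if (!any(sel)) next
      centers$y[j] <- mean(px_y[sel]); centers$x[j] <- mean(px_x[sel])
      ccol[j, ] <- colMeans(imgm[sel, , drop = FALSE])
    }
  }
  lab <- as.integer(factor(lab))
  labm <- matrix(lab, H, W)
  # merge spatially adjacent clusters with the closest mean colors until at
  # most n_segments remain
  repeat {
    ids <- sort(unique(lab))
    k <- length(ids)
    if (k <= n_segments) break
    labm <- matrix(match(lab, ids), H, W)
    lab <- as.vector(labm)
    mc <- rowsum(imgm, lab) / as.vector(table(lab))
    adj <- matrix(FALSE, k, k)
    a <- labm[-H, ]; b <- labm[-1, ]; d <- a != b
    if (any(d)) adj[cbind(a[d], b[d])] <- TRUE
    a <- labm[, -W]; b <- labm[, -1]; d <- a != b
    if (any(d)) adj[cbind(a[d], b[d])] <- TRUE
    adj <- adj | t(adj)
    dist2 <- as.matrix(stats::dist(mc))^2
    dist2[!adj] <- Inf
    diag(dist2) <- Inf
    if (!any(is.finite(dist2))) break
    pair <- which(dist2 == min(dist2), arr.ind = TRUE)[1, ]
    lab[lab == pair[2]] <- pair[1]
  }
  matrix(as.integer(factor(lab)) - 1L, H, W)
}

#' Plot a synthetic patch pair
#' @param pair A `multires_patch_pair`.
#' @param ... Unused.
#' @export
plot_patch_pair <- function(pair, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in c("image10", "image40")) {
    img <- pair[[nm]]
    graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "",
                   main = paste0(nm, " (", pair$label, ")"))
    graphics::rasterImage(img, 0, 0, 1, 1)
  }
  invisible(pair)
}
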