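test_that("tumor_fraction = 0 yields only normal labels and empty masks", {
  sp <- slide_spec(seed = 3, canvas_px = 128, tumor_fraction = 0)
  for (i in 1:4) {
    pair <- generate_patch_pair(sp, i)
    expect_identical(pair$label, "normal")
    expect_true(all(pair$mask10 == 0) && all(pair$mask40 == 0))
  }
})

test_that("generation is deterministic in (spec, pair_id)", {
  sp <- slide_spec(seed = 9, canvas_px = 128)
  a <- generate_patch_pair(sp, 2)
  b <- generate_patch_pair(sp, 2)
  expect_identical(a, b)
  expect_false(identical(a$image40,
                         generate_patch_pair(sp, 3)$image40))
})

test_that("in-frame centroid table matches a recount over the crop window", {
  sp <- slide_spec(seed = 5, canvas_px = 128, n_nuclei_normal = 50,
                   pleomorphism = 0, tumor_fraction = 0)
  pair <- generate_patch_pair(sp, 1)
  C <- sp$canvas_px; off <- 3 * C / 8; q <- C / 4
  nuc <- pair$all_nuclei
  inside <- nuc$x >= off & nuc$x < off + q & nuc$y >= off & nuc$y < off + q
  expect_equal(nrow(pair$centroids), sum(inside))
  expect_true(all(pair$centroids$x >= 0 & pair$centroids$x < q))
  expect_true(all(pair$centroids$radius > 0))
})

test_that("40x and 10x views are co-registered within 8/255 per channel", {
  sp <- slide_spec(seed = 21, canvas_px = 256)
  errs <- vapply(1:10, function(i) {
    pair <- generate_patch_pair(sp, i)
    ds <- block_mean(pair$image40, 4)
    off <- pair$crop_offset
    crop <- pair$image10[(off[1] + 1):(off[1] + dim(ds)[1]),
                         (off[2] + 1):(off[2] + dim(ds)[2]), , drop = FALSE]
    mean(abs(ds - crop))
  }, 0)
  expect_true(all(errs <= 8 / 255))
})

test_that("label is tumor exactly when the 40x mask has positives", {
  sp <- slide_spec(seed = 7, canvas_px = 128, tumor_fraction = 0.6)
  for (i in 1:8) {
    pair <- generate_patch_pair(sp, i)
    expect_identical(pair$label == "tumor", any(pair$mask40 > 0))
  }
})

test_that("tumor-class centroids lie inside the radius-dilated tumor mask", {
  sp <- slide_spec(seed = 13, canvas_px = 128, tumor_fraction = 1)
  pair <- generate_patch_pair(sp, 1)
  cen <- pair$centroids[pair$centroids$cls == "tumor", ]
  expect_gt(nrow(cen), 0)
  q <- nrow(pair$mask40)
  pos <- which(pair$mask40 > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(cen))) {
    d <- sqrt(min((pos[, 1] - 1 - cen$y[k])^2 + (pos[, 2] - 1 - cen$x[k])^2))
    expect_lte(d, cen$radius[k] + 1)
  }
})

test_that("generate_dataset writes a reproducible manifest and files", {
  sp <- slide_spec(seed = 31, canvas_px = 128, tumor_fraction = 0.5)
  d1 <- file.path(tempdir(), "ds_repro_a")
  d2 <- file.path(tempdir(), "ds_repro_b")
  m1 <- generate_dataset(sp, 8, d1)
  m2 <- generate_dataset(sp, 8, d2)
  expect_length(m1$records, 8)
  labs1 <- vapply(m1$records, `[[`, "", "label")
  labs2 <- vapply(m2$records, `[[`, "", "label")
  expect_identical(labs1, labs2)
  # byte-identical images across runs with the same seed
  f1 <- file.path(d1, m1$records[[1]]$image40)
  f2 <- file.path(d2, m2$records[[1]]$image40)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  one <- generate_dataset(sp, 1, file.path(tempdir(), "ds_one"))
  files <- setdiff(list.files(file.path(tempdir(), "ds_one")), "manifest.json")
  expect_length(files, 5)

  # a different seed changes at least one image byte-wise
  sp2 <- slide_spec(seed = 32, canvas_px = 128, tumor_fraction = 0.5)
  d3 <- file.path(tempdir(), "ds_repro_c")
  m3 <- generate_dataset(sp2, 8, d3)
  same <- vapply(seq_len(8), function(i) {
    fa <- file.path(d1, m1$records[[i]]$image40)
    fb <- file.path(d3, m3$records[[i]]$image40)
    identical(readBin(fa, "raw", file.size(fa)),
              readBin(fb, "raw", file.size(fb)))
  }, TRUE)
  expect_false(all(same))
})

test_that("manifest round-trips through JSON and pairs reload from disk", {
  man <- shared_dataset()
  man2 <- read_manifest(man$dir)
  expect_equal(length(man2$records), length(man$records))
  pair <- load_pair(man2, 1)
  gen <- generate_patch_pair(do.call(slide_spec, man$spec[
    setdiff(names(man$spec), "stain_palette")]), 1)
  expect_equal(dim(pair$image40), dim(gen$image40))
  expect_equal(pair$label, gen$label)
  expect_equal(max(abs(pair$image40 - gen$image40)), 0, tolerance = 1e-9)
})

test_that("grid superpixels tile the image exactly", {
  img <- array(0.5, c(512, 512, 3))
  lab <- generate_superpixels(img, 16, "grid")
  expect_identical(sort(unique(as.vector(lab))), 0:15)
  for (l in 0:15) expect_equal(sum(lab == l), 128 * 128)
  # each label forms a 128 x 128 rectangle
  idx <- which(lab == 5, arr.ind = TRUE)
  expect_equal(diff(range(idx[, 1])) + 1, 128)
  expect_equal(diff(range(idx[, 2])) + 1, 128)

  expect_true(all(generate_superpixels(img[1:64, 1:64, , drop = FALSE],
                                       1, "grid") == 0))
})

test_that("slic separates a two-tone image into color-coherent regions", {
  img <- array(0, c(64, 64, 3))
  img[, 33:64, ] <- 1
  lab <- generate_superpixels(img, 2, "slic")
  ids <- sort(unique(as.vector(lab)))
  expect_identical(ids, 0:(length(ids) - 1))   # contiguous labels
  means <- vapply(ids, function(l)
    mean(img[, , 1][lab == l]), 0)
  expect_gt(max(means) - min(means), stats::sd(as.vector(img[, , 1])))
})

test_that("invalid generator arguments raise errors", {
  expect_error(slide_spec(canvas_px = -4), "canvas_px")
  expect_error(slide_spec(tumor_fraction = 1.5), "tumor_fraction")
  img <- array(0.5, c(8, 8, 3))
  expect_error(generate_superpixels(img, 100, "grid"), "exceeds")
  sp <- slide_spec(seed = 1, canvas_px = 128)
  expect_error(generate_dataset(sp, 0, tempdir()), "n_pairs")
})
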