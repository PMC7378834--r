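test_that("structural thresholding is conservative and monotone", {
  img <- matrix(0, 64, 64)
  img[20:29, 30:39] <- 100
  mask <- threshold_structural(img, seg_config(struct_threshold_quantile = 0.90))
  square <- matrix(FALSE, 64, 64); square[20:29, 30:39] <- TRUE
  expect_identical(mask, square)

  ## raising the quantile never grows the mask (noisy image)
  img <- img + matrix(rnorm(64 * 64, 0, 1e-3), 64, 64)
  qs <- c(0.5, 0.7, 0.9, 0.97)
  sizes <- vapply(qs, function(q) {
    sum(threshold_structural(img, seg_config(struct_threshold_quantile = q)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  expect_error(threshold_structural(matrix(3, 8, 8)), "constant")
})

test_that("thresholding covers the cores of synthetic cells", {
  cfg <- gen_config()
  f <- make_astrocyte_field(cfg, seed = 5)
  mask <- threshold_structural(f$image, seg_config())
  ## brute-force count against ground truth: pixels within 1 sigma of centers
  h <- nrow(f$image)
  covered <- total <- 0
  for (i in seq_len(nrow(f$truth$cells))) {
    cx <- f$truth$cells$x[i]; cy <- f$truth$cells$y[i]
    s <- f$truth$cells$soma_sigma_px[i]
    for (x in floor(cx - s):ceiling(cx + s)) for (y in floor(cy - s):ceiling(cy + s)) {
      if ((x - cx)^2 + (y - cy)^2 <= s^2) {
        total <- total + 1
        covered <- covered + mask[y, x]
      }
    }
  }
  expect_gte(covered / total, 0.95)
})

test_that("center detection finds cells, flags edges, honors seeds", {
  sg <- single_gauss_field(sigma_px = 5, noise = 1)
  ctr <- detect_cell_centers(sg$field$image, 1, seg_config(territory_radius = 25))
  expect_equal(nrow(ctr), 1)
  expect_lt(sqrt((ctr$x - 48)^2 + (ctr$y - 48)^2), 1.01)
  expect_false(ctr$edge_clipped[1])

  ## a cell 5 px from the border with edge_margin 20 is flagged edge_clipped
  img <- matrix(0, 96, 96)
  d2 <- outer((1:96 - 5)^2, (1:96 - 48)^2, "+")
  img <- 100 * exp(-t(d2) / 50) # center at x = 5, y = 48
  ctr2 <- detect_cell_centers(img + rnorm(96 * 96, 0, 0.5), 1,
                              seg_config(edge_margin = 20))
  expect_true(any(ctr2$edge_clipped))

  ## explicit seeds return verbatim after snapping to the local maximum
  seeds <- data.frame(x = c(46, 20), y = c(50, 20))
  ctr3 <- detect_cell_centers(sg$field$image, 1, seg_config(), seeds = seeds)
  expect_equal(nrow(ctr3), 2)
  expect_lte(max(abs(c(ctr3$x[1], ctr3$y[1]) - c(48, 48))), 1) # snapped
  expect_true(abs(ctr3$x[2] - 20) <= 3 && abs(ctr3$y[2] - 20) <= 3)
})

test_that("polar transform reproduces closed-form radial statistics", {
  sg <- single_gauss_field(sigma_px = 5)
  img <- sg$field$image
  prof <- polar_transform(img, sg$center, seg_config(), max_radius = 20)

  ## center bin equals the center pixel
  expect_equal(prof$mean[1], img[48, 48])
  ## radially symmetric cell: per-radius SD is discretization-level only
  ## (residual spread reflects the radial gradient within one-pixel annuli)
  expect_lt(max(prof$sd[prof$radius <= 10] / pmax(prof$mean[prof$radius <= 10], 1)),
            0.15)
  ## mean at r = sigma vs brute-force pixel average, and vs exp(-1/2)
  d <- sqrt(outer((1:96 - 48)^2, (1:96 - 48)^2, "+"))
  brute <- mean(img[round(d) == 5])
  expect_equal(prof$mean[prof$radius == 5], brute, tolerance = 1e-12)
  expect_equal(prof$mean[prof$radius == 5] / prof$mean[1], exp(-0.5),
               tolerance = 0.05)

  expect_error(polar_transform(img, c(200, 48), seg_config()), "outside")
})

test_that("soma delineation matches the Gaussian half-maximum law", {
  for (sigma in c(3, 5, 8)) {
    sg <- single_gauss_field(sigma_px = sigma)
    prof <- polar_transform(sg$field$image, sg$center, seg_config(),
                            max_radius = 24)
    soma <- delineate_soma(prof, seg_config(), background = 0)
    expect_equal(soma$radius, sigma * sqrt(2 * log(2)), tolerance = 1)
    ## mask is the disk of that radius
    expect_equal(length(soma$mask), sum(
      outer((1:96 - 48)^2, (1:96 - 48)^2, "+") <= soma$radius^2))
  }

  ## degenerate and invalid profiles
  expect_error(seg_config(soma_fraction = 1.0), "soma_fraction")
  flat <- polar_transform(matrix(10 + 1e-9 * runif(96 * 96), 96, 96),
                          c(48, 48), seg_config(), max_radius = 20)
  expect_error(delineate_soma(flat, seg_config(), background = 0), "not a cell")
})

test_that("arborization rule is strict and confined to contiguous structure", {
  ## radial arms of uniform intensity over dark background: the weak
  ## supra-median criterion admits the entire arm structure
  img <- matrix(0, 81, 81)
  ctr <- c(41, 41)
  d <- sqrt(outer((1:81 - 41)^2, (1:81 - 41)^2, "+"))
  th <- atan2(outer(rep(1, 81), 1:81 - 41), outer(1:81 - 41, rep(1, 81)))
  arm <- matrix(FALSE, 81, 81)
  for (a in seq(0, 2 * pi - 0.1, by = pi / 4)) {
    arm <- arm | (abs(atan2(sin(th - a), cos(th - a))) < 0.12 & d > 2 & d <= 30)
  }
  img[arm] <- 10
  img <- img + 50 * exp(-d^2 / (2 * 2^2)) # smooth soma core
  prof <- polar_transform(img, ctr, seg_config(), max_radius = 32)
  soma <- delineate_soma(prof, seg_config(), background = 0)
  mask <- delineate_arborization(img, prof, soma, seg_config())
  inside_arm <- arm & d > soma$radius & d <= 30
  expect_gte(sum(mask & inside_arm) / sum(inside_arm), 0.97)
  expect_lte(sum(mask & !inside_arm) / max(sum(mask), 1), 0.05)

  ## boundary convention: a pixel exactly at median + 0.25 SD is excluded
  thr_tab <- prof$median + 0.25 * prof$sd
  img2 <- img
  rb <- attr(prof, "rbin_img")
  target <- which(rb == 12 & !arm & d > soma$radius)[1]
  img2[target] <- thr_tab[13] # exactly at threshold for radius bin 12
  prof2 <- polar_transform(img2, ctr, seg_config(), max_radius = 32)
  thr2 <- prof2$median + 0.25 * prof2$sd
  mask2 <- delineate_arborization(img2, prof2, soma, seg_config())
  if (img2[target] == thr2[13]) expect_false(mask2[target])
})

test_that("arborization recall and precision against generator ground truth", {
  cfg <- gen_config()
  f <- make_astrocyte_field(cfg, seed = 11)
  terrs <- segment_territories(f$image, cfg$pixel_size, seg_config())
  expect_equal(length(terrs), cfg$n_cells)
  for (t in terrs) {
    d <- sqrt((f$truth$cells$x - t$center[1])^2 +
                (f$truth$cells$y - t$center[2])^2)
    gt <- f$truth$arb_masks[[which.min(d)]]
    det <- t$arborization_mask
    expect_gte(length(intersect(det, gt)) / length(gt), 0.9)   # recall
    expect_gte(length(intersect(det, gt)) / length(det), 0.8)  # precision
    ## soma and arborization are disjoint; both inside the territory disk
    expect_length(intersect(t$soma_mask, t$arborization_mask), 0)
  }
})

test_that("microdomain gridding counts match area and limiting cases", {
  ## annulus of ~450 um^2 at 1 um/px: expect about 50 microdomains
  h <- 64
  d <- sqrt(outer((1:h - 32)^2, (1:h - 32)^2, "+"))
  ann <- d >= 10 & d <= sqrt(100 + 450 / pi)
  md <- grid_microdomains(ann, c(32, 32), 1, seg_config())
  area <- sum(ann) # ~450 um^2
  expect_equal(length(md), area / 9, tolerance = 0.2)

  ## microdomains partition their pixels and stay inside the mask
  pix <- unlist(lapply(md, `[[`, "pixels"))
  expect_equal(length(pix), length(unique(pix)))
  expect_true(all(pix %in% which(ann)))

  ## empty mask, zero-overlap limit, coarse pixels
  expect_length(grid_microdomains(matrix(FALSE, 8, 8), c(4, 4), 1, seg_config()), 0)
  md0 <- grid_microdomains(ann, c(32, 32), 1,
                           seg_config(min_microdomain_overlap = 0))
  touching <- length(unique(paste(floor((which(ann, arr.ind = TRUE)[, 2] - 32) / 3),
                                  floor((which(ann, arr.ind = TRUE)[, 1] - 32) / 3))))
  expect_equal(length(md0), touching)
  expect_error(grid_microdomains(ann, c(32, 32), 4, seg_config()), "coarse")
})

test_that("microdomain count scales linearly with arborization area", {
  h <- 96
  d <- sqrt(outer((1:h - 48)^2, (1:h - 48)^2, "+"))
  areas <- counts <- c()
  for (r2 in seq(14, 34, by = 4)) {
    ann <- d >= 10 & d <= r2
    areas <- c(areas, sum(ann))
    counts <- c(counts, length(grid_microdomains(ann, c(48, 48), 1, seg_config())))
  }
  expect_gt(summary(lm(counts ~ areas))$r.squared, 0.98)
})

test_that("segmentation is translation-equivariant and scale-invariant", {
  cfg <- gen_config(field_size = 128, n_cells = 1, struct_noise_sd = 0)
  f <- make_astrocyte_field(cfg, seed = 9, centers = matrix(c(56, 60), 1))
  img <- f$image
  seedpt <- data.frame(x = 56, y = 60)
  t1 <- segment_territories(img, cfg$pixel_size, seg_config(), seeds = seedpt)[[1]]

  ## translation by (dx, dy): shift the image, masks shift identically
  dx <- 7; dy <- -5
  img2 <- matrix(cfg$background, 128, 128)
  src_x <- 1:(128 - dx); dst_x <- (1 + dx):128
  src_y <- (1 - dy):128; dst_y <- 1:(128 + dy)
  img2[dst_y, dst_x] <- img[src_y, src_x]
  t2 <- segment_territories(img2, cfg$pixel_size, seg_config(),
                            seeds = data.frame(x = 56 + dx, y = 60 + dy))[[1]]
  shift_idx <- function(idx, h, dx, dy) {
    rc <- arrayInd(idx, c(h, h))
    sort((rc[, 2] + dx - 1) * h + rc[, 1] + dy)
  }
  expect_equal(sort(t2$soma_mask), shift_idx(t1$soma_mask, 128, dx, dy))
  expect_equal(sort(t2$arborization_mask),
               shift_idx(t1$arborization_mask, 128, dx, dy))

  ## multiplying the structural channel by a positive constant changes nothing
  t3 <- segment_territories(img * 3.7, cfg$pixel_size, seg_config(),
                            seeds = seedpt)[[1]]
  expect_equal(sort(t3$soma_mask), sort(t1$soma_mask))
  expect_equal(sort(t3$arborization_mask), sort(t1$arborization_mask))
  expect_equal(length(t3$microdomains), length(t1$microdomains))
})

test_that("vasculature overlap and edge clipping exclude cells from statistics", {
  cfg <- gen_config(field_size = 128, n_cells = 1)
  f <- make_astrocyte_field(cfg, seed = 13, centers = matrix(c(64, 64), 1))
  vm <- matrix(FALSE, 128, 128); vm[60:68, 60:68] <- TRUE
  terr <- segment_territories(f$image, cfg$pixel_size, seg_config(),
                              seeds = data.frame(x = 64, y = 64),
                              vessel_mask = vm)[[1]]
  expect_true(terr$qc$vasculature_overlap)
  expect_false(qc_pass(terr))
})
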