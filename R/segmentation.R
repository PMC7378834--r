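#' Segmentation configuration
#'
#' Parameters of the territory segmentation: a strict structural threshold
#' (high quantile, mirroring the conservative SR101 thresholding), the soma
#' rule (50 % of central structural fluorescence), the arborization rule
#' (pixels brighter than median + `arb_k` x SD of their radius circle) and the
#' 3 x 3 um microdomain grid.
#'
#' @param struct_threshold_quantile intensity quantile defining SR101-positive
#'   pixels (default 0.90)
#' @param soma_fraction fraction of the background-subtracted central
#'   fluorescence delimiting the soma (default 0.50)
#' @param arb_k SD multiplier above the circle median for arborization pixels
#'   (default 0.25; strict `>`)
#' @param microdomain_size microdomain edge length, micrometres (default 3)
#' @param n_angular_bins angular resolution of the polar transform (default 36)
#' @param radial_step radial bin width, pixels (default 1)
#' @param min_microdomain_overlap minimum fraction of a grid square inside the
#'   arborization for it to count as a microdomain (default 0.5)
#' @param edge_margin cells closer than this to the image border are flagged
#'   `edge_clipped`, pixels (default 12)
#' @param territory_radius territory radius used to bound each cell's polar
#'   transform and to separate detected centers, micrometres (default 20)
#' @param smooth_sigma Gaussian smoothing applied before maxima detection,
#'   pixels (default 3)
#' @return a list of class `SegmentationConfig`
#' @export
seg_config <- function(struct_threshold_quantile = 0.90,
                       soma_fraction = 0.50,
                       arb_k = 0.25,
                       microdomain_size = 3.0,
                       n_angular_bins = 36L,
                       radial_step = 1,
                       min_microdomain_overlap = 0.5,
                       edge_margin = 12,
                       territory_radius = 20,
                       smooth_sigma = 3) {
  if (soma_fraction <= 0 || soma_fraction >= 1) stopf("soma_fraction must lie in (0, 1)")
  if (arb_k < 0) stopf("arb_k must be >= 0")
  if (microdomain_size <= 0) stopf("microdomain_size must be > 0")
  structure(as.list(environment()), class = "SegmentationConfig")
}

#' Threshold the structural channel
#'
#' SR101-positive pixels are those strictly above the
#' `struct_threshold_quantile` of the image intensity distribution; the high
#' default quantile keeps the estimate conservative.
#'
#' @param img structural image matrix
#' @param config a [seg_config()]
#' @return logical matrix
#' @export
threshold_structural <- function(img, config = seg_config()) {
  stopifnot(is.matrix(img))
  if (max(img) == min(img)) stopf("constant image cannot be thresholded")
  thr <- stats::quantile(img, config$struct_threshold_quantile, names = FALSE)
  img > thr
}

#' Estimate the structural background level
#'
#' The mode of the intensity histogram outside all thresholded regions; robust
#' to bright somata dominating the mean.
#'
#' @param img structural image matrix
#' @param config a [seg_config()]
#' @return scalar background intensity
#' @export
estimate_background <- function(img, config = seg_config()) {
  outside <- img[!threshold_structural(img, config)]
  if (!length(outside)) return(min(img))
  d <- stats::density(outside, n = 512)
  d$x[which.max(d$y)]
}

#' Detect astrocyte centers in the structural channel
#'
#' With `seeds` given, each seed snaps to the local intensity maximum within
#' 3 px and is returned verbatim otherwise (manual ROI seeding). Without
#' seeds, local maxima of the Gaussian-smoothed structural channel separated
#' by at least one territory diameter are returned. Centers within
#' `edge_margin` of the border are flagged `edge_clipped`.
#'
#' @param img structural image matrix
#' @param pixel_size micrometres per pixel
#' @param config a [seg_config()]
#' @param seeds optional data.frame or matrix with columns x, y (pixels)
#' @return data.frame with columns `x`, `y`, `edge_clipped`
#' @export
detect_cell_centers <- function(img, pixel_size, config = seg_config(),
                                seeds = NULL) {
  h <- nrow(img); w <- ncol(img)
  snap <- function(x, y) {
    xs <- max(1, round(x) - 3):min(w, round(x) + 3)
    ys <- max(1, round(y) - 3):min(h, round(y) + 3)
    sub <- img[ys, xs, drop = FALSE]
    ij <- arrayInd(which.max(sub), dim(sub))
    c(x = xs[ij[2]], y = ys[ij[1]])
  }
  if (!is.null(seeds)) {
    seeds <- as.data.frame(seeds)
    pts <- t(mapply(snap, seeds$x, seeds$y))
  } else {
    sm <- gauss_blur(img, config$smooth_sigma)
    mask <- threshold_structural(img, config)
    min_sep <- 2 * config$territory_radius / pixel_size * 0.75
    ## local maxima: strictly greater than the 8-neighbourhood
    cand <- which(mask, arr.ind = TRUE)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (r < 2 || r > h - 1 || c < 2 || c > w - 1) next
      nb <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
      keep[i] <- sm[r, c] == max(nb) && sum(nb == sm[r, c]) == 1L
    }
    cand <- cand[keep, , drop = FALSE]
    ## prominence gate: a soma peak must stand well above the background
    bg <- stats::median(sm)
    floor_val <- bg + 0.5 * (max(sm) - bg)
    cand <- cand[sm[cand] >= floor_val, , drop = FALSE]
    ord <- order(sm[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    acc <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (!nrow(acc) ||
          min(sqrt((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2)) >= min_sep) {
        acc <- rbind(acc, p)
      }
    }
    if (!nrow(acc)) {
      return(data.frame(x = numeric(0), y = numeric(0), edge_clipped = logical(0)))
    }
    pts <- cbind(x = acc[, 2], y = acc[, 1])
  }
  m <- config$edge_margin
  data.frame(x = pts[, 1], y = pts[, 2],
             edge_clipped = pts[, 1] <= m | pts[, 1] > w - m |
                            pts[, 2] <= m | pts[, 2] > h - m)
}

#' Polar transform of the structural channel around one cell
#'
#' Pixels are binned by rounded radius (step `radial_step`) and by angle
#' (`n_angular_bins`); per radius the mean, median and SD of the "circle of
#' fluorescence" are tabulated, plus a radius x angle mean-intensity matrix.
#'
#' @param img structural image matrix
#' @param center numeric c(x, y) in pixels
#' @param config a [seg_config()]
#' @param max_radius outer radius in pixels (default: territory radius, capped
#'   at the distance to the nearest border)
#' @return object of class `radial_profile`: data.frame columns `radius`,
#'   `mean`, `median`, `sd`, `n`, with the angular matrix and geometry as
#'   attributes
#' @export
polar_transform <- function(img, center, config = seg_config(),
                            max_radius = NULL) {
  h <- nrow(img); w <- ncol(img)
  cx <- center[[1]]; cy <- center[[2]]
  if (cx < 1 || cx > w || cy < 1 || cy > h) stopf("center lies outside the image")
  ## distance of every pixel to the center (x = column, y = row)
  dx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  dy <- matrix(rep(seq_len(h), w), h, w) - cy
  r <- sqrt(dx^2 + dy^2)
  max_radius <- max_radius %||% Inf
  rmax <- min(max_radius, cx - 1, w - cx, cy - 1, h - cy)
  if (rmax < 1) stopf("center too close to the border for a polar transform")
  step <- config$radial_step
  rbin <- as.integer(round(r / step))
  nb <- as.integer(floor(rmax / step))
  sel <- rbin <= nb
  idx <- rbin[sel] + 1L
  vals <- img[sel]
  mean_r <- tapply(vals, idx, mean)
  med_r <- tapply(vals, idx, stats::median)
  sd_r <- tapply(vals, idx, stats::sd)
  n_r <- tapply(vals, idx, length)
  radii <- (as.integer(names(mean_r)) - 1L) * step
  sd_r[is.na(sd_r)] <- 0
  prof <- data.frame(radius = radii, mean = as.numeric(mean_r),
                     median = as.numeric(med_r), sd = as.numeric(sd_r),
                     n = as.integer(n_r))
  theta <- atan2(dy, dx)[sel]
  abin <- pmin(config$n_angular_bins,
               1L + as.integer(floor((theta + pi) / (2 * pi) * config$n_angular_bins)))
  ang <- tapply(vals, list(idx, abin), mean)
  structure(prof, class = c("radial_profile", "data.frame"),
            angular = ang, center = c(x = cx, y = cy), dim_img = c(h, w),
            radial_step = step, rbin_img = rbin, in_range = sel)
}

disk_mask_idx <- function(dim_img, center, radius) {
  h <- dim_img[1]; w <- dim_img[2]
  dx <- matrix(rep(seq_len(w), each = h), h, w) - center[[1]]
  dy <- matrix(rep(seq_len(h), w), h, w) - center[[2]]
  which(dx^2 + dy^2 <= radius^2)
}

#' Delineate the soma from a radial profile
#'
#' The soma radius is the smallest radius at which the background-subtracted
#' azimuthally averaged structural fluorescence first falls below
#' `soma_fraction` of its central (r = 0) value, located by linear
#' interpolation between radial bins; the mask is the disk of that radius.
#'
#' @param profile a [polar_transform()] result
#' @param config a [seg_config()]
#' @param background structural background level subtracted before the ratio
#'   (default 0; see [estimate_background()])
#' @return list with `radius` (pixels) and `mask` (pixel indices)
#' @export
delineate_soma <- function(profile, config = seg_config(), background = 0) {
  v <- profile$mean - background
  if (v[1] <= 0) stopf("central fluorescence does not exceed background: not a cell")
  target <- config$soma_fraction * v[1]
  below <- which(v < target)
  if (!length(below)) {
    stopf("fluorescence never falls below %g%% of its central value: not a cell",
          100 * config$soma_fraction)
  }
  i <- below[1]
  if (i == 1L) stopf("degenerate soma: profile below threshold at r = 0")
  ## linear interpolation between the last supra- and first sub-threshold bin
  r0 <- profile$radius[i - 1]; r1 <- profile$radius[i]
  v0 <- v[i - 1]; v1 <- v[i]
  radius <- r0 + (v0 - target) / (v0 - v1) * (r1 - r0)
  mask <- disk_mask_idx(attr(profile, "dim_img"), attr(profile, "center"), radius)
  list(radius = radius, mask = mask)
}

#' Delineate the arborization
#'
#' A pixel at radius r beyond the soma belongs to the arborization iff its
#' intensity strictly exceeds median + `arb_k` x SD of its radius circle,
#' restricted to the connected region adjacent to the soma.
#'
#' @param img structural image matrix
#' @param profile the cell's [polar_transform()]
#' @param soma result of [delineate_soma()]
#' @param config a [seg_config()]
#' @return logical matrix mask (soma excluded); attribute `empty` flags an
#'   empty arborization
#' @export
delineate_arborization <- function(img, profile, soma, config = seg_config()) {
  h <- nrow(img); w <- ncol(img)
  rbin <- attr(profile, "rbin_img")
  in_range <- attr(profile, "in_range")
  thr_tab <- profile$median + config$arb_k * profile$sd
  thr_img <- matrix(Inf, h, w)
  thr_img[in_range] <- thr_tab[rbin[in_range] + 1L]
  soma_mask <- matrix(FALSE, h, w)
  soma_mask[soma$mask] <- TRUE
  ## radius map consistent with the profile binning
  supra <- img > thr_img & !soma_mask
  supra[!in_range] <- FALSE
  ## keep only the region contiguous with the soma
  seed_ring <- dilate1(soma_mask) & !soma_mask
  arb <- region_grow(seed_ring & supra, supra)
  ## also exclude pixels inside the soma radius that the disk missed
  attr(arb, "empty") <- !any(arb)
  arb
}

#' Discretize an arborization into 3 x 3 um microdomains
#'
#' An axis-aligned grid of `microdomain_size` squares anchored at the cell
#' center; a grid square is a microdomain iff at least
#' `min_microdomain_overlap` of its area lies inside the arborization mask.
#' Microdomain pixel sets are the intersections of grid squares with the mask,
#' hence pairwise disjoint.
#'
#' @param arb_mask logical matrix (arborization)
#' @param center numeric c(x, y), pixels
#' @param pixel_size micrometres per pixel
#' @param config a [seg_config()]
#' @return list of microdomains, each a list with `gi`, `gj` (grid indices)
#'   and `pixels` (matrix indices)
#' @export
grid_microdomains <- function(arb_mask, center, pixel_size,
                              config = seg_config()) {
  m <- config$microdomain_size / pixel_size
  if (m < 1) stopf("microdomain smaller than one pixel: pixel_size too coarse")
  idx <- which(arb_mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  gi <- floor((idx[, 2] - center[[1]]) / m)
  gj <- floor((idx[, 1] - center[[2]]) / m)
  key <- paste(gi, gj)
  counts <- table(key)
  keep <- names(counts)[counts / m^2 >= config$min_microdomain_overlap &
                          counts > 0]
  lin <- which(arb_mask)
  out <- lapply(keep, function(k) {
    sel <- key == k
    gij <- as.integer(strsplit(k, " ")[[1]])
    list(gi = gij[1], gj = gij[2], pixels = lin[sel])
  })
  out[order(vapply(out, function(d) d$gj * 1e6 + d$gi, numeric(1)))]
}

#' Segment astrocyte territories in a structural image
#'
#' Full chain: background estimation, center detection (or seeding), per-cell
#' polar transform, soma and arborization delineation, microdomain gridding
#' and QC flagging (edge-clipped cells, optional vasculature overlap, empty
#' arborizations). Flagged territories are retained but excluded from
#' population statistics downstream.
#'
#' @param img structural image matrix (or an [imaging_movie()], in which case
#'   the time-averaged structural channel is used)
#' @param pixel_size micrometres per pixel (taken from the movie if given)
#' @param config a [seg_config()]
#' @param seeds optional data.frame of centers (columns x, y)
#' @param vessel_mask optional logical matrix of vasculature pixels; cells
#'   whose territory overlaps it are flagged
#' @return list of `AstrocyteTerritory` objects (class `territory_set`)
#' @export
segment_territories <- function(img, pixel_size = NULL, config = seg_config(),
                                seeds = NULL, vessel_mask = NULL) {
  if (inherits(img, "ImagingMovie")) {
    pixel_size <- img$pixel_size
    img <- apply(img$structural, c(1, 2), mean)
  }
  stopifnot(is.matrix(img), is_scalar_num(pixel_size))
  bg <- estimate_background(img, config)
  centers <- detect_cell_centers(img, pixel_size, config, seeds = seeds)
  r_t <- config$territory_radius / pixel_size
  out <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    ctr <- c(centers$x[i], centers$y[i])
    terr <- tryCatch({
      prof <- polar_transform(img, ctr, config, max_radius = r_t)
      soma <- delineate_soma(prof, config, background = bg)
      arb <- delineate_arborization(img, prof, soma, config)
      md <- grid_microdomains(arb, ctr, pixel_size, config)
      vas <- !is.null(vessel_mask) &&
        any(vessel_mask[c(soma$mask, which(arb))])
      structure(list(cell_id = i, center = ctr,
                     soma_radius_px = soma$radius,
                     soma_mask = soma$mask,
                     arborization_mask = which(arb),
                     microdomains = md,
                     background = bg,
                     dim = dim(img),
                     qc = list(edge_clipped = centers$edge_clipped[i],
                               vasculature_overlap = isTRUE(vas),
                               empty_arborization = isTRUE(attr(arb, "empty")))),
                class = "AstrocyteTerritory")
    }, error = function(e) {
      structure(list(cell_id = i, center = ctr, soma_radius_px = NA_real_,
                     soma_mask = integer(0), arborization_mask = integer(0),
                     microdomains = list(), background = bg, dim = dim(img),
                     qc = list(edge_clipped = centers$edge_clipped[i],
                               vasculature_overlap = FALSE,
                               empty_arborization = TRUE),
                     error = conditionMessage(e)),
                class = "AstrocyteTerritory")
    })
    out[[i]] <- terr
  }
  structure(out, class = "territory_set")
}

#' @export
print.AstrocyteTerritory <- function(x, ...) {
  cat(sprintf(
    "AstrocyteTerritory %d: center (%.1f, %.1f), soma r = %.2f px, %d arb px, %d microdomains%s\n",
    x$cell_id, x$center[1], x$center[2], x$soma_radius_px,
    length(x$arborization_mask), length(x$microdomains),
    if (any(unlist(x$qc))) paste0(" [", paste(names(x$qc)[unlist(x$qc)], collapse = ","), "]")
    else ""))
  invisible(x)
}

#' @export
print.territory_set <- function(x, ...) {
  cat(sprintf("territory_set: %d cells (%d QC-passing)\n",
              length(x), sum(vapply(x, qc_pass, logical(1)))))
  for (t in x) print(t)
  invisible(x)
}

#' Does a territory pass QC?
#' @param territory an `AstrocyteTerritory`
#' @export
qc_pass <- function(territory) {
  !territory$qc$edge_clipped && !territory$qc$vasculature_overlap &&
    !territory$qc$empty_arborization
}

#' Territory summary table
#' @param x a `territory_set`
#' @param ... unused
#' @export
as.data.frame.territory_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(t) {
    data.frame(cell_id = t$cell_id, x = t$center[1], y = t$center[2],
               soma_radius_px = t$soma_radius_px,
               soma_px = length(t$soma_mask),
               arborization_px = length(t$arborization_mask),
               n_microdomains = length(t$microdomains),
               edge_clipped = t$qc$edge_clipped,
               vasculature_overlap = t$qc$vasculature_overlap,
               empty_arborization = t$qc$empty_arborization,
               qc_pass = qc_pass(t))
  }))
}
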