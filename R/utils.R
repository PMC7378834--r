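#' gliawave: astrocyte calcium imaging and astrocyte-gamma coupling analysis
#'
#' Territory segmentation of astrocyte structural images, 3-SD calcium event
#' detection, sigmoid stimulus-response fitting, ECoG spectral band analysis
#' and astrocyte-gamma coupling metrics, with a synthetic-data generator
#' providing ground truth for every stage. See `vignette` sources under
#' `vignettes/` and [run_pipeline()] for the end-to-end chain.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-stage seed derived from one global seed.
## Keeps derived seeds inside the 32-bit integer range.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## merge user overrides into a default config list, rejecting unknown names
merge_config <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  stopifnot(is.list(overrides))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  defaults
}

## 1-D FFT convolution with edge padding; returns same length as x.
## kern must have odd length and is applied centred (zero phase for
## symmetric kernels).
fft_filter <- function(x, kern) {
  nk <- length(kern)
  stopifnot(nk %% 2L == 1L)
  half <- (nk - 1L) / 2L
  n <- length(x)
  ## reflect-pad to suppress edge transients
  xp <- c(rev(x[seq_len(min(half, n))]), x, rev(x[seq.int(n - min(half, n) + 1L, n)]))
  nfft <- stats::nextn(length(xp) + nk - 1L, 2)
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  K <- stats::fft(c(kern, numeric(nfft - nk)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  pad <- min(half, n)
  y[seq.int(pad + half + 1L, pad + half + n)]
}

## separable Gaussian blur of a matrix (sigma in pixels)
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- apply(img, 2L, fft_filter, kern = k)
  t(apply(t(out), 2L, fft_filter, kern = k))
}

## binary dilation of a logical matrix by one pixel (8-connectivity)
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    sh <- matrix(FALSE, h, w)
    rs <- seq_len(h) - s[1]; cs <- seq_len(w) - s[2]
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    sh[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out <- out | sh
  }
  out
}

## grow a region inside `allowed` starting from `seed` (8-connectivity)
region_grow <- function(seed, allowed) {
  cur <- seed & allowed
  repeat {
    nxt <- dilate1(cur) & allowed
    if (sum(nxt) == sum(cur)) return(cur)
    cur <- nxt
  }
}

## write a named list of scalars / vectors as JSON (stable formatting)
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## ASCII PGM (P2) label image writer: plain-text, inspectable
write_pgm <- function(img, path) {
  img <- round(img)
  img[img < 0] <- 0
  mx <- max(img, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(mx)), con)
  apply(img, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
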