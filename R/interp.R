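# Image sampling primitives shared by registration, kymographs and the
# simulators. Images are plain numeric matrices indexed [row, col]; all
# user-visible coordinates are (x, y) = (column, row), 1-based, at pixel
# centres.

# Catmull-Rom cubic convolution weights for fractional offset t in [0, 1).
# Returns a length(t) x 4 matrix of weights for samples at -1, 0, +1, +2.
cubic_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind(
    -0.5 * t3 + t2 - 0.5 * t,
    1.5 * t3 - 2.5 * t2 + 1,
    -1.5 * t3 + 2 * t2 + 0.5 * t,
    0.5 * t3 - 0.5 * t2
  )
}

#' Sample an image at arbitrary positions with bicubic interpolation
#'
#' Cubic-convolution (Catmull-Rom) resampling, the interpolation used
#' throughout for channel correction and kymograph profile extraction.
#' Edge pixels are replicated for queries whose support overlaps the
#' border; queries outside the image return `fill`.
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param x,y Numeric vectors of query positions (1-based pixel centres).
#' @param fill Value returned for out-of-bounds queries (default `NA`).
#' @return Numeric vector of sampled intensities, same length as `x`.
#' @export
bicubic_sample <- function(img, x, y, fill = NA_real_) {
  stopifnot(is.matrix(img), length(x) == length(y))
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(as.numeric(fill), length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  ix <- floor(xs); iy <- floor(ys)
  wx <- cubic_weights(xs - ix)
  wy <- cubic_weights(ys - iy)
  acc <- numeric(length(xs))
  for (j in 1:4) {
    rr <- pmin(pmax(iy + (j - 2L), 1L), nr)
    rowacc <- numeric(length(xs))
    for (k in 1:4) {
      cc <- pmin(pmax(ix + (k - 2L), 1L), nc)
      rowacc <- rowacc + wx[, k] * img[cbind(rr, cc)]
    }
    acc <- acc + wy[, j] * rowacc
  }
  out[ok] <- acc
  out
}

# Separable Gaussian blur with edge replication. sigma in pixels; sigma = 0
# returns the input.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) { # along rows (i.e. down columns)
    nr <- nrow(m)
    acc <- matrix(0, nr, ncol(m))
    for (o in (-r):r) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      acc <- acc + k[o + r + 1L] * m[idx, , drop = FALSE]
    }
    acc
  }
  t(blur_1d(t(blur_1d(img))))
}

# Grey-scale dilation (running max) over a (2r+1)^2 square, separable.
dilate_max <- function(img, r) {
  run_1d <- function(m) {
    nr <- nrow(m)
    acc <- m
    for (o in setdiff((-r):r, 0L)) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      acc <- pmax(acc, m[idx, , drop = FALSE])
    }
    acc
  }
  t(run_1d(t(run_1d(img))))
}

# Local maxima of `img` above `threshold`, at least `min_sep` apart
# (brightest kept first). Returns tibble(x, y, value).
local_maxima <- function(img, threshold, radius = 2L, min_sep = NULL) {
  dil <- dilate_max(img, radius)
  hit <- which(img >= dil & img > threshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(tibble(x = numeric(), y = numeric(), value = numeric()))
  }
  val <- img[hit]
  ord <- order(val, decreasing = TRUE)
  hit <- hit[ord, , drop = FALSE]
  val <- val[ord]
  if (is.null(min_sep)) min_sep <- radius
  keep <- rep(TRUE, nrow(hit))
  if (min_sep > 0 && nrow(hit) > 1L) {
    for (i in 2:nrow(hit)) {
      if (!keep[i]) next
      d2 <- (hit[1:(i - 1), 1] - hit[i, 1])^2 + (hit[1:(i - 1), 2] - hit[i, 2])^2
      if (any(keep[1:(i - 1)] & d2 < min_sep^2)) keep[i] <- FALSE
    }
  }
  tibble(x = as.numeric(hit[keep, 2]), y = as.numeric(hit[keep, 1]),
         value = val[keep])
}

# FFT cross-correlation shift estimate of b relative to a (b approx a
# translated by the returned (dx, dy)). Subpixel via parabolic fit around
# the correlation peak; among equal-height periodic aliases the candidate
# closest to zero shift wins.
xcorr_shift <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  fa <- fft(a0)
  fb <- fft(b0)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  # candidate peaks within 2% of the max: pick smallest wrapped shift
  mx <- max(cc)
  idx <- which(cc >= mx * 0.98, arr.ind = TRUE)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dys <- wrap(idx[, 1], nr)
  dxs <- wrap(idx[, 2], nc)
  best <- which.min(dxs^2 + dys^2)
  pi_ <- idx[best, 1]; pj <- idx[best, 2]
  # parabolic subpixel refinement per axis (indices wrap)
  at <- function(i, j) cc[(i - 1) %% nr + 1, (j - 1) %% nc + 1]
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  dy <- wrap(pi_, nr) + sub(at(pi_ - 1, pj), at(pi_, pj), at(pi_ + 1, pj))
  dx <- wrap(pj, nc) + sub(at(pi_, pj - 1), at(pi_, pj), at(pi_, pj + 1))
  # correlation of b against a shifted by +d means b = a shifted by -d
  c(dx = -dx, dy = -dy)
}

# Add an axis-aligned 2D Gaussian spot (peak amplitude `amp`, sd `sigma`
# px) to `img` at (x, y); separable outer-product evaluation on a local
# patch. Returns the modified image.
add_gaussian_spot <- function(img, x, y, amp, sigma) {
  r <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  if (!is.finite(x) || !is.finite(y) ||
      y + r < 1 || y - r > nr || x + r < 1 || x - r > nc) {
    return(img) # spot entirely outside the frame: clipped, not an error
  }
  rows <- max(1L, floor(y - r)):min(nr, ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(nc, ceiling(x + r))
  gy <- exp(-(rows - y)^2 / (2 * sigma^2))
  gx <- exp(-(cols - x)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * (gy %o% gx)
  img
}
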