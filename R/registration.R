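# Dual-camera channel registration from a square-lattice calibration
# image: node detection, similarity-transform fitting, and bicubic
# application to movies. The transform family is similarity (scale +
# rotation + shift), the three corrections named by the imaging
# procedure; channel A (shorter wavelength) is the fixed reference and
# channel B is warped onto it.

#' Similarity transform between the two camera channels
#'
#' Maps reference-channel (A) coordinates to channel-B coordinates:
#' `p_B = scale * R(rotation) %*% (p_A - centre) + centre + shift`.
#' Registering channel B onto A resamples B at the forward-mapped
#' positions, so this one object both describes the camera misalignment
#' and corrects it.
#'
#' @param scale Unitless magnification ratio (> 0).
#' @param rotation_deg Rotation in degrees (anticlockwise).
#' @param shift Numeric `c(dx, dy)` in pixels.
#' @param centre Rotation/scaling origin, typically the image centre.
#' @param rms_residual_px Optional fit residual to carry along.
#' @param n_nodes Optional node count used in the fit.
#' @return A `channel_transform` object.
#' @export
channel_transform <- function(scale = 1, rotation_deg = 0, shift = c(0, 0),
                              centre = c(0, 0), rms_residual_px = NA_real_,
                              n_nodes = NA_integer_) {
  stop_if_not_scalar_pos(scale, "scale")
  structure(
    list(scale = scale, rotation_deg = rotation_deg,
         shift = as.numeric(shift), centre = as.numeric(centre),
         interpolation = "bicubic",
         rms_residual_px = rms_residual_px, n_nodes = n_nodes),
    class = "channel_transform")
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf(
    "<channel_transform> scale %.5f, rotation %.4f deg, shift (%.3f, %.3f) px\n",
    x$scale, x$rotation_deg, x$shift[1], x$shift[2]))
  if (is.finite(x$rms_residual_px)) {
    cat(sprintf("  fit residual %.4f px RMS over %d nodes\n",
                x$rms_residual_px, x$n_nodes))
  }
  invisible(x)
}

#' @method tidy channel_transform
#' @export
tidy.channel_transform <- function(x, ...) {
  tibble(term = c("scale", "rotation_deg", "shift_x_px", "shift_y_px"),
         estimate = c(x$scale, x$rotation_deg, x$shift))
}

#' @method glance channel_transform
#' @export
glance.channel_transform <- function(x, ...) {
  tibble(rms_residual_px = x$rms_residual_px, n_nodes = x$n_nodes,
         interpolation = x$interpolation)
}

#' Apply / invert the transform on point coordinates
#'
#' @param transform A [channel_transform()].
#' @param x,y Coordinate vectors in the reference (A) frame for
#'   `transform_points()`, in the B frame for `transform_points_inverse()`.
#' @return 2-column matrix of mapped coordinates.
#' @export
transform_points <- function(transform, x, y) {
  th <- transform$rotation_deg * pi / 180
  s <- transform$scale
  dx <- x - transform$centre[1]
  dy <- y - transform$centre[2]
  cbind(x = s * (cos(th) * dx - sin(th) * dy) + transform$centre[1] + transform$shift[1],
        y = s * (sin(th) * dx + cos(th) * dy) + transform$centre[2] + transform$shift[2])
}

#' @rdname transform_points
#' @export
transform_points_inverse <- function(transform, x, y) {
  th <- -transform$rotation_deg * pi / 180
  s <- 1 / transform$scale
  dx <- x - transform$centre[1] - transform$shift[1]
  dy <- y - transform$centre[2] - transform$shift[2]
  cbind(x = s * (cos(th) * dx - sin(th) * dy) + transform$centre[1],
        y = s * (sin(th) * dx + cos(th) * dy) + transform$centre[2])
}

#' Simulate a dual-colour calibration lattice pair
#'
#' Renders a 10-um-pitch square line lattice (Gaussian line profile) as
#' channel A; channel B is A warped through `transform` with bicubic
#' interpolation. Both are then independently noised per `spec`.
#'
#' @param spec An [acquisition_spec()] (single frame used).
#' @param transform The true [channel_transform()] (A -> B).
#' @param pitch_um Lattice pitch (default 10 um; 125 px at 80 nm/px).
#' @param line_sigma_px Gaussian line-profile sd (default 1.2).
#' @param amplitude Line peak amplitude in counts.
#' @param offset_px Position of the first lattice line (x and y).
#' @param seed Integer seed.
#' @return List with `image_a`, `image_b` (matrices), `nodes_a` (tibble
#'   of true node coordinates in A), `pitch_px`, and `transform`.
#' @export
sim_lattice_pair <- function(spec, transform = channel_transform(),
                             pitch_um = 10, line_sigma_px = 1.2,
                             amplitude = 400, offset_px = 30, seed = NULL) {
  with_seed_maybe(seed, {
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    pitch_px <- pitch_um * 1000 / spec$pixel_size_nm
    xs <- seq(offset_px, nc, by = pitch_px)
    ys <- seq(offset_px, nr, by = pitch_px)
    line_profile <- function(coord, centres) {
      v <- numeric(length(coord))
      for (c0 in centres) v <- pmax(v, exp(-(coord - c0)^2 / (2 * line_sigma_px^2)))
      v
    }
    vx <- line_profile(seq_len(nc), xs)
    vy <- line_profile(seq_len(nr), ys)
    # additive line crossings: value = A*(vx + vy), nodes brightest at 2A
    clean_a <- amplitude * (matrix(vy, nr, nc) + matrix(vx, nr, nc, byrow = TRUE)) +
      spec$background_level
    # warp A -> B: B(p) = A(t^-1(p))
    gx <- rep(seq_len(nc), each = nr)
    gy <- rep(seq_len(nr), times = nc)
    src <- transform_points_inverse(transform, gx, gy)
    clean_b <- matrix(bicubic_sample(clean_a, src[, 1], src[, 2],
                                     fill = spec$background_level), nr, nc)
    img_a <- matrix(apply_camera_noise(clean_a, spec), nr, nc)
    img_b <- matrix(apply_camera_noise(clean_b, spec), nr, nc)
    nodes <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
    list(image_a = img_a, image_b = img_b, nodes_a = as_tibble(nodes),
         pitch_px = pitch_px, transform = transform)
  })
}

#' Detect lattice intersections at subpixel precision
#'
#' Coarse detection by local maxima of the smoothed image (nodes are the
#' brightest points of an additive line lattice), followed by iterative
#' symmetric-window centroid refinement, which is exact for the locally
#' point-symmetric intensity around an intersection. Nodes whose
#' refinement window would leave the image are dropped, so the count
#' equals the number of fully visible intersections.
#'
#' @param image Numeric matrix containing a periodic square grid.
#' @param expected_pitch_px Approximate node spacing (> 4 px).
#' @return Tibble of node coordinates (`x`, `y`), ordered row-major
#'   (by y, then x).
#' @export
detect_lattice_nodes <- function(image, expected_pitch_px) {
  if (expected_pitch_px <= 4) {
    abort("`expected_pitch_px` must exceed 4 px.",
          class = "synaptrack_bad_argument")
  }
  sm <- gaussian_blur(image, 2)
  bg <- median(sm)
  mx <- max(sm)
  thr <- bg + 0.6 * (mx - bg)
  cand <- local_maxima(sm, thr, radius = max(3L, floor(expected_pitch_px / 4)),
                       min_sep = expected_pitch_px / 2)
  win <- floor(min(expected_pitch_px / 3, 25))
  nr <- nrow(image); nc <- ncol(image)
  keep <- cand$x - win >= 1 & cand$x + win <= nc &
    cand$y - win >= 1 & cand$y + win <= nr
  cand <- cand[keep, ]
  if (nrow(cand) < 4) {
    abort("Fewer than 4 lattice nodes found; calibration failed.",
          class = "synaptrack_calibration_failure")
  }
  base <- stats::quantile(image, 0.25)
  refine <- function(x0, y0) {
    for (it in 1:6) {
      rows <- round(y0) + (-win):win
      cols <- round(x0) + (-win):win
      if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) {
        return(c(NA, NA))
      }
      w <- pmax(image[rows, cols] - base, 0)
      # radially symmetric soft window: exact centroid for the locally
      # point-symmetric node intensity, negligible discretisation bias
      dy <- rows - y0; dx <- cols - x0
      sw2 <- (win / 2.5)^2
      mask <- outer(dy, dx, function(a, b) exp(-(a^2 + b^2) / (2 * sw2)))
      w <- w * mask
      sw <- sum(w)
      if (sw <= 0) return(c(NA, NA))
      nx <- sum(w %*% cols) / sw
      ny <- sum(rows %*% w) / sw
      if (abs(nx - x0) < 1e-4 && abs(ny - y0) < 1e-4) {
        x0 <- nx; y0 <- ny; break
      }
      x0 <- nx; y0 <- ny
    }
    c(x0, y0)
  }
  ref <- t(mapply(refine, cand$x, cand$y))
  ok <- complete.cases(ref)
  out <- tibble(x = ref[ok, 1], y = ref[ok, 2])
  if (nrow(out) < 4) {
    abort("Fewer than 4 lattice nodes found; calibration failed.",
          class = "synaptrack_calibration_failure")
  }
  arrange(out, round(.data$y / expected_pitch_px), .data$x)
}

#' Fit the similarity transform from matched lattice nodes
#'
#' Least-squares similarity (scale, rotation, shift) mapping node set A
#' onto node set B, the closed-form orthogonal-Procrustes solution.
#' When the two sets are unmatched detections, they are first paired by
#' nearest neighbour after a coarse cross-correlation pre-alignment of
#' the supplied images (or directly when lengths match and `match =
#' FALSE`).
#'
#' @param nodes_a,nodes_b Tibbles with `x`, `y` (channel A, channel B).
#' @param centre Rotation origin recorded in the transform (defaults to
#'   the centroid of `nodes_a`).
#' @param match Pair nodes by nearest neighbour first? (default `TRUE`;
#'   rows are assumed matched when `FALSE`).
#' @param max_pair_dist_px Gate for nearest-neighbour pairing.
#' @return A [channel_transform()] with `rms_residual_px` and `n_nodes`.
#' @export
fit_channel_transform <- function(nodes_a, nodes_b, centre = NULL,
                                  match = TRUE, max_pair_dist_px = 30) {
  a <- cbind(nodes_a$x, nodes_a$y)
  b <- cbind(nodes_b$x, nodes_b$y)
  if (match) {
    # inter-channel displacements are far below half a lattice pitch, so
    # plain nearest-neighbour pairing is unambiguous; duplicates resolve
    # to the closest pair
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    pairs <- apply(d2, 1, which.min)
    dist <- d2[cbind(seq_len(nrow(a)), pairs)]
    ok <- dist <= max_pair_dist_px^2
    for (j in unique(pairs[ok])) {
      hits <- which(ok & pairs == j)
      if (length(hits) > 1) ok[hits[-which.min(dist[hits])]] <- FALSE
    }
    a <- a[ok, , drop = FALSE]
    b <- b[pairs[ok], , drop = FALSE]
  }
  if (nrow(a) < 3) {
    abort("At least 3 matched node pairs are required.",
          class = "synaptrack_calibration_failure")
  }
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  if (min(svd(A)$d) < 1e-8 * max(svd(A)$d)) {
    abort("Node set is degenerate (collinear).",
          class = "synaptrack_calibration_failure")
  }
  # similarity B ~ s R A: rotation from the cross-covariance
  H <- crossprod(A, B) # 2x2
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  s <- sum(diag(t(B) %*% t(R %*% t(A)))) / sum(A^2)
  tvec <- cb - s * as.numeric(R %*% ca)
  th <- atan2(R[2, 1], R[1, 1])
  if (is.null(centre)) centre <- ca
  # p_B = s R (p_A - c) + c + shift  =>  shift = tvec + s R c - c
  shift <- tvec + s * as.numeric(R %*% centre) - centre
  pred <- t(s * R %*% t(a)) + matrix(tvec, nrow(a), 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((pred - b)^2)))
  channel_transform(scale = s, rotation_deg = th * 180 / pi, shift = shift,
                    centre = centre, rms_residual_px = rms,
                    n_nodes = nrow(a))
}

#' Register a movie (or single image) onto the reference channel
#'
#' Resamples each frame of channel B with bicubic interpolation at the
#' forward-mapped positions so that features align with channel A.
#' Frame shape is preserved; pixels mapping outside the source are set
#' to the frame's border-median background estimate.
#'
#' @param movie A [movie_stack()] or a single matrix (channel B).
#' @param transform A [channel_transform()] (A -> B).
#' @return Registered movie (or matrix) of the same shape.
#' @export
apply_channel_transform <- function(movie, transform) {
  single <- is.matrix(movie) && !inherits(movie, "movie_stack")
  frames <- if (single) list(movie) else
    lapply(seq_len(n_frames(movie)), function(t) get_frame(movie, t))
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  gx <- rep(seq_len(nc), each = nr)
  gy <- rep(seq_len(nr), times = nc)
  src <- transform_points(transform, gx, gy)
  out <- lapply(frames, function(fr) {
    bg <- median(c(fr[1, ], fr[nr, ], fr[, 1], fr[, nc]))
    matrix(bicubic_sample(fr, src[, 1], src[, 2], fill = bg), nr, nc)
  })
  if (single) {
    out[[1]]
  } else {
    m <- movie_stack(out, movie_spec(movie))
    attr(m, "registered") <- TRUE
    m
  }
}

#' Serialise / read a channel transform as JSON
#'
#' @param transform A [channel_transform()].
#' @param path File path.
#' @return `write_channel_transform()` the path invisibly;
#'   `read_channel_transform()` the transform.
#' @export
write_channel_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_channel_transform
#' @export
read_channel_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_transform(x$scale, x$rotation_deg, x$shift, x$centre,
                    x$rms_residual_px %||% NA_real_,
                    x$n_nodes %||% NA_integer_)
}
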