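# Synthetic +TIP comet movies with exact ground truth.
#
# A comet is a moving intensity feature at a growing microtubule tip: a
# sharp Gaussian leading edge (sd `edge_sigma_um`, default 120 nm) with
# an exponential intensity tail behind the tip (decay constant
# `tail_decay_um`), advected along a polyline path at constant speed.
# The transverse profile is Gaussian with the same edge sigma.

# Longitudinal comet profile; d = arc distance of tip ahead of sample
# point (d >= 0 behind the tip, d < 0 ahead of it). Tail truncated where
# it falls below 2% of peak.
comet_profile <- function(d, edge_sigma_px, tail_decay_px) {
  ifelse(d < 0,
         exp(-d^2 / (2 * edge_sigma_px^2)),
         ifelse(d <= tail_decay_px * log(50), exp(-d / tail_decay_px), 0))
}

# Cumulative arc length of a polyline given as a 2-col matrix (x, y).
polyline_arclength <- function(v) {
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  if (any(seg == 0)) {
    abort("Polyline has coincident consecutive vertices.",
          class = "synaptrack_bad_argument")
  }
  c(0, cumsum(seg))
}

# Point(s) on the polyline at arc positions s (clamped to the path).
polyline_point <- function(v, s) {
  cs <- polyline_arclength(v)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  seg <- pmax(findInterval(s, cs, rightmost.closed = TRUE), 1L)
  seg <- pmin(seg, nrow(v) - 1L)
  f <- (s - cs[seg]) / (cs[seg + 1L] - cs[seg])
  cbind(x = v[seg, 1] + f * (v[seg + 1L, 1] - v[seg, 1]),
        y = v[seg, 2] + f * (v[seg + 1L, 2] - v[seg, 2]))
}

# Distance along / perpendicular to a polyline for a block of pixel
# coordinates: nearest-point projection per segment, minimum over
# segments. Returns list(arc, perp2).
project_to_polyline <- function(v, px, py) {
  cs <- polyline_arclength(v)
  best_d2 <- rep(Inf, length(px))
  best_arc <- rep(NA_real_, length(px))
  for (i in seq_len(nrow(v) - 1L)) {
    ex <- v[i + 1L, 1] - v[i, 1]
    ey <- v[i + 1L, 2] - v[i, 2]
    len2 <- ex^2 + ey^2
    tt <- pmin(pmax(((px - v[i, 1]) * ex + (py - v[i, 2]) * ey) / len2, 0), 1)
    qx <- v[i, 1] + tt * ex
    qy <- v[i, 2] + tt * ey
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cs[i] + tt[upd] * sqrt(len2)
  }
  list(arc = best_arc, perp2 = best_d2)
}

# Render one comet into one frame (in place). tip_s = tip arc position.
render_comet <- function(frame, path, tip_s, amp, edge_sigma_px, tail_px) {
  cs <- polyline_arclength(path)
  total <- cs[length(cs)]
  s_lo <- tip_s - tail_px * log(50)
  s_hi <- tip_s + 3.5 * edge_sigma_px
  if (s_hi < 0 || s_lo > total) return(frame)
  pts <- polyline_point(path, seq(max(s_lo, 0), min(s_hi, total),
                                  length.out = 16))
  pad <- 4 * edge_sigma_px + 1
  nr <- nrow(frame); nc <- ncol(frame)
  c_lo <- max(1L, floor(min(pts[, 1]) - pad))
  c_hi <- min(nc, ceiling(max(pts[, 1]) + pad))
  r_lo <- max(1L, floor(min(pts[, 2]) - pad))
  r_hi <- min(nr, ceiling(max(pts[, 2]) + pad))
  if (c_lo > c_hi || r_lo > r_hi) return(frame) # support off-frame: clipped
  cols <- c_lo:c_hi
  rows <- r_lo:r_hi
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  pr <- project_to_polyline(path, gx, gy)
  d <- tip_s - pr$arc
  val <- amp * comet_profile(d, edge_sigma_px, tail_px) *
    exp(-pr$perp2 / (2 * edge_sigma_px^2))
  frame[rows, cols] <- frame[rows, cols] + matrix(val, length(rows))
  frame
}

#' Simulate a movie of moving +TIP comets with known ground truth
#'
#' Comets are advected at constant programmed speed along straight
#' random paths (or user-supplied polylines), rendered with a Gaussian
#' leading edge plus exponential tail, then camera noise per `spec` is
#' applied. The returned truth tibble exactly describes every rendered
#' comet; paths leaving the frame are clipped, not an error.
#'
#' @param spec An [acquisition_spec()].
#' @param n_comets Number of comets.
#' @param speed_um_per_s Programmed tip speed (single value for all
#'   comets unless `speed_sd` > 0).
#' @param speed_sd Optional lognormal dispersion of per-comet speeds
#'   (um/s); the mean stays exact.
#' @param snr Peak amplitude expressed as a multiple of the background
#'   noise sd (default 8).
#' @param edge_sigma_um Leading-edge / transverse Gaussian sd (default
#'   0.12 um).
#' @param tail_decay_um Exponential tail decay constant (default 0.4 um).
#' @param paths Optional list of 2-column matrices (x, y) of polyline
#'   vertices; generated at random spanning the frame when `NULL`.
#' @param seed Integer seed; identical seeds give bit-identical movies.
#' @return A list with `movie` (a [movie_stack()]) and `truth`, a tibble
#'   with one row per comet: `comet_id`, `birth_frame`, `speed_um_per_s`,
#'   `peak_amplitude`, `tail_decay_um`, `comet_length_um` (2%-of-peak
#'   support of the noise-free kernel) and a list-column `path` of
#'   vertex matrices.
#' @export
sim_comet_movie <- function(spec, n_comets = 10, speed_um_per_s = 0.30,
                            speed_sd = 0, snr = 8,
                            edge_sigma_um = 0.12, tail_decay_um = 0.4,
                            paths = NULL, seed = NULL) {
  stopifnot(inherits(spec, "acquisition_spec"))
  if (n_comets < 0 || speed_um_per_s < 0) {
    abort("Comet count and speed must be non-negative.",
          class = "synaptrack_bad_argument")
  }
  with_seed_maybe(seed, {
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    px_um <- spec$pixel_size_nm / 1000
    edge_px <- edge_sigma_um * 1000 / spec$pixel_size_nm
    tail_px <- tail_decay_um * 1000 / spec$pixel_size_nm
    amp <- amplitude_for_snr(spec, snr)
    if (is.null(paths) && n_comets > 0) {
      # straight paths with random orientation, kept fully inside the
      # frame margins (rejection sampling; feasible since len < frame)
      margin <- 8
      paths <- lapply(seq_len(n_comets), function(i) {
        repeat {
          x0 <- runif(1, margin, nc - margin)
          y0 <- runif(1, margin, nr - margin)
          th <- runif(1, 0, 2 * pi)
          len <- runif(1, 0.35, 0.6) * min(nr, nc)
          x1 <- x0 + cos(th) * len
          y1 <- y0 + sin(th) * len
          if (x1 >= margin && x1 <= nc - margin &&
              y1 >= margin && y1 <= nr - margin) {
            return(rbind(c(x0, y0), c(x1, y1)))
          }
        }
      })
    }
    n_comets <- if (is.null(paths)) 0L else length(paths)
    speeds <- rspeed(n_comets, speed_um_per_s, speed_sd)
    births <- if (n_comets > 0) sample.int(max(1L, spec$n_frames - 10L),
                                           n_comets, replace = TRUE) else integer()
    # comet length by the 2%-support convention on the clean kernel
    len_um <- (edge_sigma_um * sqrt(2 * log(50))) + tail_decay_um * log(50)
    clean <- array(spec$background_level, dim = c(nr, nc, spec$n_frames))
    for (t in seq_len(spec$n_frames)) {
      fr <- clean[, , t]
      for (i in seq_len(n_comets)) {
        if (t < births[i]) next
        tip_s <- (t - births[i]) * speeds[i] / px_um * spec$frame_interval_s
        fr <- render_comet(fr, paths[[i]], tip_s, amp, edge_px, tail_px)
      }
      clean[, , t] <- fr
    }
    noisy <- apply_camera_noise(clean, spec)
    truth <- tibble(
      comet_id = seq_len(n_comets),
      birth_frame = as.integer(births),
      speed_um_per_s = speeds,
      peak_amplitude = rep(amp, n_comets),
      tail_decay_um = rep(tail_decay_um, n_comets),
      comet_length_um = rep(len_um, n_comets),
      path = if (n_comets > 0) paths else list())
    list(movie = movie_stack(noisy, spec), truth = truth)
  })
}
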