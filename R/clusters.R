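# Punctate cluster detection, nearest-neighbour tracking, and
# plus/minus/immobile motion classification.
#
# Detection implements the two selection criteria for protein clusters:
# the diameter (FWHM of a 2D Gaussian fit) must exceed 240 nm (3 pixels
# at 80 nm/px), and the intensity difference between the cluster and its
# surrounding must exceed the standard deviation of the surrounding,
# measured in an annulus from 1.5x to 3x the fitted radius.

# Least-squares 2D Gaussian fit on a square patch. Returns list(x0, y0,
# sigma, amp, offset, converged).
fit_gaussian_spot <- function(img, x0, y0, window = 6L) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1L, round(y0) - window):min(nr, round(y0) + window)
  cols <- max(1L, round(x0) - window):min(nc, round(x0) + window)
  patch <- img[rows, cols]
  border <- c(patch[1, ], patch[nrow(patch), ], patch[, 1], patch[, ncol(patch)])
  off0 <- median(border)
  amp0 <- max(patch) - off0
  if (amp0 <= 0) return(NULL)
  w <- pmax(patch - off0, 0)
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  cx0 <- sum(w * matrix(gx, length(rows))) / sum(w)
  cy0 <- sum(w * matrix(gy, length(rows))) / sum(w)
  obj <- function(p) {
    mdl <- p[5] + p[3] * exp(-((gx - p[1])^2 + (gy - p[2])^2) / (2 * p[4]^2))
    sum((mdl - as.numeric(patch))^2)
  }
  fit <- tryCatch(
    optim(c(cx0, cy0, amp0, 1.8, off0), obj, method = "L-BFGS-B",
          lower = c(min(cols), min(rows), 0, 0.4, -Inf),
          upper = c(max(cols), max(rows), Inf, window, Inf),
          control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(x0 = fit$par[1], y0 = fit$par[2], amp = fit$par[3],
       sigma = fit$par[4], offset = fit$par[5],
       converged = fit$convergence == 0)
}

# Mean and sd of raw intensity in an annulus r_in..r_out around (x, y).
annulus_stats <- function(img, x, y, r_in, r_out) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1L, floor(y - r_out)):min(nr, ceiling(y + r_out))
  cols <- max(1L, floor(x - r_out)):min(nc, ceiling(x + r_out))
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  sel <- d2 >= r_in^2 & d2 <= r_out^2
  v <- img[rows, cols][sel]
  if (length(v) < 8) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(v), sd = sd(v))
}

#' Detect protein clusters in one frame
#'
#' Candidate bright spots (local maxima of the lightly smoothed frame
#' above a robust noise threshold) are fitted with a 2D Gaussian; a
#' candidate becomes a detection only if it satisfies both selection
#' criteria: FWHM diameter strictly greater than `min_diameter_nm`
#' (default 240 nm) and peak intensity exceeding the surrounding mean by
#' more than `contrast_sd` (default 1) standard deviations of the
#' surrounding, measured in an annulus 1.5x-3x the fitted radius.
#'
#' @param frame Numeric matrix (one movie frame).
#' @param pixel_size_nm Pixel pitch in nm.
#' @param min_diameter_nm Diameter criterion (default 240).
#' @param contrast_sd Contrast criterion in surrounding-sds (default 1).
#' @param candidate_sd Candidate threshold in robust noise sds above the
#'   frame median (default 4).
#' @param fit_window_px Half-width of the Gaussian fit patch.
#' @return Tibble of detections: `x`, `y` (subpixel), `diameter_nm`,
#'   `peak_intensity`, `local_background_mean`, `local_background_sd`,
#'   `criteria_diameter`, `criteria_contrast` (both `TRUE` for returned
#'   rows). Empty tibble for a flat or empty frame.
#' @export
detect_clusters <- function(frame, pixel_size_nm = 80,
                            min_diameter_nm = 240, contrast_sd = 1,
                            candidate_sd = 4, fit_window_px = 6L) {
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  empty <- tibble(x = numeric(), y = numeric(), diameter_nm = numeric(),
                  peak_intensity = numeric(),
                  local_background_mean = numeric(),
                  local_background_sd = numeric(),
                  criteria_diameter = logical(), criteria_contrast = logical())
  if (length(frame) == 0) return(empty)
  if (diff(range(frame)) == 0) return(empty) # flat frame
  sm <- gaussian_blur(frame, 1)
  thr <- median(sm) + candidate_sd * mad(sm)
  cand <- local_maxima(sm, thr, radius = 2L, min_sep = 3)
  if (!nrow(cand)) return(empty)
  out <- purrr::pmap(cand, function(x, y, value) {
    g <- fit_gaussian_spot(frame, x, y, window = fit_window_px)
    if (is.null(g)) return(NULL)
    radius_px <- 1.1774 * g$sigma # half of FWHM
    ann <- annulus_stats(frame, g$x0, g$y0, 1.5 * radius_px, 3 * radius_px)
    if (!is.finite(ann["mean"])) return(NULL)
    peak <- g$amp + g$offset
    tibble(
      x = g$x0, y = g$y0,
      diameter_nm = 2.3548 * g$sigma * pixel_size_nm,
      peak_intensity = peak,
      local_background_mean = unname(ann["mean"]),
      local_background_sd = unname(ann["sd"]),
      criteria_diameter = 2.3548 * g$sigma * pixel_size_nm > min_diameter_nm,
      criteria_contrast = (peak - ann["mean"]) > contrast_sd * ann["sd"])
  }) |> purrr::list_rbind()
  if (!nrow(out)) return(empty)
  filter(out, .data$criteria_diameter & .data$criteria_contrast)
}

#' Detect clusters across a movie
#'
#' @param movie A [movie_stack()].
#' @param ... Passed to [detect_clusters()].
#' @return Tibble of detections with a `frame` column.
#' @export
detect_clusters_movie <- function(movie, ...) {
  spec <- movie_spec(movie)
  purrr::map(seq_len(n_frames(movie)), function(t) {
    d <- detect_clusters(get_frame(movie, t),
                         pixel_size_nm = spec$pixel_size_nm, ...)
    if (nrow(d)) mutate(d, frame = t, .before = 1) else NULL
  }) |> purrr::list_rbind()
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking on consecutive frames with a
#' distance gate; no gap closing. The default gate of 5 px (0.4 um/s at
#' 80 nm and 1 fps) sits above the fastest expected cluster velocity.
#' Tracks shorter than `min_frames` (default 3, the colocalisation
#' rule's window) are discarded.
#'
#' @param detections Tibble with `frame`, `x`, `y` (from
#'   [detect_clusters_movie()]).
#' @param max_step_px Per-frame linking gate in pixels.
#' @param min_frames Minimum track length in frames.
#' @return The detections tibble filtered to kept tracks, with a
#'   `track_id` column.
#' @export
link_tracks <- function(detections, max_step_px = 5, min_frames = 3) {
  if (is.null(detections) || !nrow(detections)) {
    return(tibble(track_id = integer(), frame = integer(),
                  x = numeric(), y = numeric()))
  }
  detections <- arrange(as_tibble(detections), .data$frame)
  detections$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(detections$frame))
  prev_idx <- integer()
  for (f in frames) {
    cur_idx <- which(detections$frame == f)
    if (length(prev_idx)) {
      px <- detections$x[prev_idx]; py <- detections$y[prev_idx]
      cx <- detections$x[cur_idx]; cy <- detections$y[cur_idx]
      d <- sqrt(outer(px, cx, "-")^2 + outer(py, cy, "-")^2)
      d[d > max_step_px] <- Inf
      # greedy global-minimum assignment
      while (any(is.finite(d))) {
        k <- arrayInd(which.min(d), dim(d))
        detections$track_id[cur_idx[k[2]]] <-
          detections$track_id[prev_idx[k[1]]]
        d[k[1], ] <- Inf
        d[, k[2]] <- Inf
      }
    }
    new <- cur_idx[is.na(detections$track_id[cur_idx])]
    if (length(new)) {
      detections$track_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    # only detections in the immediately preceding frame may link (no gaps)
    prev_idx <- cur_idx
  }
  keep <- detections |>
    count(.data$track_id) |>
    filter(.data$n >= min_frames) |>
    pull(.data$track_id)
  out <- filter(detections, .data$track_id %in% keep)
  out$track_id <- match(out$track_id, sort(unique(out$track_id)))
  arrange(out, .data$track_id, .data$frame)
}

#' Per-track kinematics: mean velocity, speed, lifetime
#'
#' Speed is the magnitude of the mean per-frame displacement vector
#' (net displacement over elapsed time), the unbiased estimator for
#' directed motion; lifetime uses the inclusive convention
#' `n_detections * frame_interval`.
#'
#' @param tracks Tibble from [link_tracks()].
#' @param pixel_size_nm,frame_interval_s Acquisition calibration.
#' @return One row per track: `track_id`, `n_detections`, `frame_start`,
#'   `frame_end`, mean position, velocity components (um/s),
#'   `speed_um_per_s`, `lifetime_s`.
#' @export
summarize_tracks <- function(tracks, pixel_size_nm = 80, frame_interval_s = 1) {
  if (!nrow(tracks)) {
    abort("No tracks to summarise.", class = "synaptrack_empty_input")
  }
  if (any(count(tracks, .data$track_id)$n < 2)) {
    abort("Tracks with a single detection cannot be summarised.",
          class = "synaptrack_empty_input")
  }
  scale <- pixel_size_nm / 1000 / frame_interval_s
  tracks |>
    group_by(.data$track_id) |>
    summarise(
      n_detections = dplyr::n(),
      frame_start = min(.data$frame),
      frame_end = max(.data$frame),
      x_mean = mean(.data$x),
      y_mean = mean(.data$y),
      vx_um_per_s = (dplyr::last(.data$x) - dplyr::first(.data$x)) /
        (dplyr::n() - 1) * scale,
      vy_um_per_s = (dplyr::last(.data$y) - dplyr::first(.data$y)) /
        (dplyr::n() - 1) * scale,
      .groups = "drop") |>
    mutate(
      speed_um_per_s = sqrt(.data$vx_um_per_s^2 + .data$vy_um_per_s^2),
      lifetime_s = .data$n_detections * frame_interval_s)
}

#' Classify track motion as plus, minus or immobile
#'
#' A track is immobile when its mean speed is below
#' `immobile_threshold_um_s` (default 0.02 um/s, well below the slowest
#' directed population at 0.054 um/s); otherwise it is plus- or
#' minus-end-directed by the sign of the mean projection of its
#' per-frame displacements onto the local microtubule direction field.
#' The default field is radial, outward from the cell centre (plus ends
#' grow from the MTOC toward the periphery); pass `direction_fun` for a
#' comet-derived field.
#'
#' @param tracks Tibble from [link_tracks()].
#' @param geometry A [cell_geometry()] (for the radial field and the
#'   region of the first detection).
#' @param pixel_size_nm,frame_interval_s Acquisition calibration.
#' @param immobile_threshold_um_s Speed below which a track is immobile.
#' @param direction_fun Optional `function(x, y)` returning a 2-column
#'   matrix of unit plus-end direction vectors.
#' @return [summarize_tracks()] output with `motion_class`
#'   (`"plus"`/`"minus"`/`"immobile"`, `NA` where the field is
#'   undefined along the whole track) and `region` columns.
#' @export
classify_motion <- function(tracks, geometry, pixel_size_nm = 80,
                            frame_interval_s = 1,
                            immobile_threshold_um_s = 0.02,
                            direction_fun = NULL) {
  if (is.null(direction_fun)) {
    direction_fun <- function(x, y) radial_direction(geometry, x, y)
  }
  summ <- summarize_tracks(tracks, pixel_size_nm, frame_interval_s)
  proj <- tracks |>
    group_by(.data$track_id) |>
    summarise(
      mean_proj = {
        u <- direction_fun(head(.data$x, -1), head(.data$y, -1))
        p <- diff(.data$x) * u[, 1] + diff(.data$y) * u[, 2]
        mean(p, na.rm = TRUE)
      },
      field_defined = {
        u <- direction_fun(head(.data$x, -1), head(.data$y, -1))
        any(is.finite(u[, 1]))
      },
      .groups = "drop")
  first_pos <- tracks |>
    group_by(.data$track_id) |>
    summarise(x = dplyr::first(.data$x), y = dplyr::first(.data$y),
              .groups = "drop")
  region <- suppressWarnings(classify_region(first_pos, geometry))
  summ |>
    left_join(proj, by = "track_id") |>
    left_join(select(region, "track_id", "region"), by = "track_id") |>
    mutate(
      motion_class = dplyr::case_when(
        .data$speed_um_per_s < immobile_threshold_um_s ~ "immobile",
        !.data$field_defined ~ NA_character_,
        .data$mean_proj >= 0 ~ "plus",
        TRUE ~ "minus")) |>
    select(-"mean_proj", -"field_defined")
}
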