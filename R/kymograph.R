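# Kymograph construction and comet measurement along traced microtubule
# paths. A kymograph stacks the bicubic-sampled intensity profile along
# an arc-length-resampled path (1 px spacing), one row per frame, top =
# first frame; pitches are 80 nm/pixel horizontally and 1 s/row with the
# default acquisition.

#' Build a kymograph along a traced path
#'
#' The path is resampled at exactly 1 px arc spacing; row `t` is the
#' bicubic-sampled intensity along the path in frame `t`. With
#' `line_width_px > 1` intensities are averaged over evenly spaced
#' perpendicular offsets spanning the width.
#'
#' @param movie A [movie_stack()].
#' @param path A 2-column matrix or data frame of polyline vertices
#'   (x, y), ordered from the microtubule's minus-proximal end to its
#'   plus-directed end.
#' @param line_width_px Averaging width perpendicular to the path.
#' @return A `kymograph`: matrix (rows = time, cols = position) with
#'   `space_pitch_nm` and `time_pitch_s` attributes.
#' @export
build_kymograph <- function(movie, path, line_width_px = 1) {
  spec <- movie_spec(movie)
  path <- as.matrix(path)[, 1:2, drop = FALSE]
  if (nrow(path) < 2L) {
    abort("Path needs at least two vertices.", class = "synaptrack_bad_argument")
  }
  cs <- polyline_arclength(path)
  total <- cs[length(cs)]
  s <- seq(0, floor(total))
  if (total > floor(total)) s <- c(s, total)
  pts <- polyline_point(path, s)
  nr <- dim(movie)[1]; nc <- dim(movie)[2]
  if (any(pts[, 1] < 1 | pts[, 1] > nc | pts[, 2] < 1 | pts[, 2] > nr)) {
    abort("Path leaves the image bounds.", class = "synaptrack_path_outside")
  }
  # unit normals along the path (for width averaging)
  tx <- c(diff(pts[, 1]), NA); ty <- c(diff(pts[, 2]), NA)
  tx[length(tx)] <- tx[length(tx) - 1L]
  ty[length(ty)] <- ty[length(ty) - 1L]
  nrm <- sqrt(tx^2 + ty^2)
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- if (line_width_px > 1) {
    seq(-(line_width_px - 1) / 2, (line_width_px - 1) / 2, length.out = line_width_px)
  } else 0
  kym <- matrix(NA_real_, n_frames(movie), length(s))
  for (t in seq_len(n_frames(movie))) {
    fr <- get_frame(movie, t)
    acc <- 0
    for (o in offs) {
      acc <- acc + bicubic_sample(fr, pts[, 1] + o * nx, pts[, 2] + o * ny,
                                  fill = spec$background_level)
    }
    kym[t, ] <- acc / length(offs)
  }
  structure(kym,
            space_pitch_nm = spec$pixel_size_nm,
            time_pitch_s = spec$frame_interval_s,
            class = c("kymograph", "matrix", "array"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%.3g nm/px, %.3g s/row)\n",
              nrow(x), ncol(x), attr(x, "space_pitch_nm"),
              attr(x, "time_pitch_s")))
  invisible(x)
}

#' Velocity of a manually traced kymograph segment
#'
#' The comet velocity is the slope of a straight line in the kymograph:
#' `delta_position * space_pitch / delta_time`, signed positive toward
#' the path's plus end.
#'
#' @param kymo A `kymograph`.
#' @param position_px Numeric length-2: column positions (px) of the
#'   segment endpoints.
#' @param time_frame Numeric length-2: row (frame) indices of the
#'   endpoints; must differ.
#' @return Velocity in um/s (scalar).
#' @export
trace_velocity <- function(kymo, position_px, time_frame) {
  if (diff(time_frame) == 0) {
    abort("Segment endpoints must span distinct frames.",
          class = "synaptrack_bad_argument")
  }
  dpos <- diff(position_px) * attr(kymo, "space_pitch_nm") / 1000
  dt <- diff(time_frame) * attr(kymo, "time_pitch_s")
  dpos / dt
}

#' Detect straight comet traces in a kymograph
#'
#' Automates the manual reading of kymograph lines: per-row local maxima
#' above `baseline + sensitivity_sd * noise_sd` are linked across
#' consecutive rows by nearest neighbour within `gate_px`, and runs of at
#' least `min_frames` rows are fitted with a straight line whose slope
#' gives the velocity.
#'
#' @param kymo A `kymograph` (>= 5 rows).
#' @param sensitivity_sd Detection threshold in robust noise sds above
#'   the kymograph baseline (default 4).
#' @param gate_px Maximum per-row position jump when linking (default 6).
#' @param min_frames Minimum rows per accepted trace (default 5).
#' @param min_peak_sep_px Minimum separation of peaks within one row
#'   (default 12 px, about one comet length): secondary maxima on a
#'   comet's own tail are suppressed in favour of the brighter tip.
#' @return Tibble of trace segments: `trace_id`, endpoint columns
#'   (`position_start_px`, `position_end_px`, `frame_start`,
#'   `frame_end`), `n_points`, `velocity_um_per_s` (signed; positive
#'   toward the path's plus end). Empty tibble when nothing is found.
#' @export
detect_traces <- function(kymo, sensitivity_sd = 4, gate_px = 6,
                          min_frames = 5, min_peak_sep_px = 12) {
  if (nrow(kymo) < 5L) {
    abort("Kymograph must have at least 5 rows.",
          class = "synaptrack_bad_argument")
  }
  baseline <- median(kymo)
  noise <- mad(kymo)
  thr <- baseline + sensitivity_sd * noise
  # per-row 1D local maxima of the lightly smoothed profile
  sm <- kymo
  if (ncol(kymo) >= 7) {
    k <- exp(-(-2:2)^2 / 2); k <- k / sum(k)
    sm <- t(apply(kymo, 1, function(r) {
      as.numeric(stats::filter(c(rep(r[1], 2), r, rep(r[length(r)], 2)), k))[3:(length(r) + 2)]
    }))
  }
  peaks_by_row <- lapply(seq_len(nrow(sm)), function(t) {
    r <- sm[t, ]
    n <- length(r)
    if (n < 3) return(numeric())
    ismax <- r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n] &
      r[2:(n - 1)] > thr
    pos <- which(ismax) + 1L
    # suppress weaker maxima within one comet length of a stronger one
    if (length(pos) > 1L) {
      ord <- order(r[pos], decreasing = TRUE)
      keep_idx <- integer()
      for (j in ord) {
        if (!length(keep_idx) ||
            all(abs(pos[keep_idx] - pos[j]) >= min_peak_sep_px)) {
          keep_idx <- c(keep_idx, j)
        }
      }
      pos <- sort(pos[keep_idx])
    }
    # parabolic subpixel refinement
    if (length(pos)) {
      den <- r[pos - 1] - 2 * r[pos] + r[pos + 1]
      off <- ifelse(den == 0, 0, 0.5 * (r[pos - 1] - r[pos + 1]) / den)
      pos + pmax(pmin(off, 0.5), -0.5)
    } else numeric()
  })
  # greedy nearest-neighbour linking over consecutive rows
  active <- list() # each: list(pos = vector, rows = vector)
  done <- list()
  for (t in seq_along(peaks_by_row)) {
    pk <- peaks_by_row[[t]]
    taken <- rep(FALSE, length(pk))
    still <- logical(length(active))
    for (i in seq_along(active)) {
      tr <- active[[i]]
      if (length(pk)) {
        d <- abs(pk - tr$pos[length(tr$pos)])
        d[taken] <- Inf
        j <- which.min(d)
        if (length(j) && d[j] <= gate_px) {
          tr$pos <- c(tr$pos, pk[j]); tr$rows <- c(tr$rows, t)
          active[[i]] <- tr
          taken[j] <- TRUE
          still[i] <- TRUE
          next
        }
      }
      done[[length(done) + 1L]] <- tr
    }
    active <- active[still]
    for (j in which(!taken)) {
      active[[length(active) + 1L]] <- list(pos = pk[j], rows = t)
    }
  }
  done <- c(done, active)
  done <- done[vapply(done, function(tr) length(tr$rows) >= min_frames, logical(1))]
  if (!length(done)) {
    return(tibble(trace_id = integer(), position_start_px = numeric(),
                  position_end_px = numeric(), frame_start = integer(),
                  frame_end = integer(), n_points = integer(),
                  velocity_um_per_s = numeric()))
  }
  px_um <- attr(kymo, "space_pitch_nm") / 1000
  dt <- attr(kymo, "time_pitch_s")
  purrr::imap(done, function(tr, i) {
    fit <- lm(tr$pos ~ tr$rows)
    tibble(
      trace_id = i,
      position_start_px = tr$pos[1],
      position_end_px = tr$pos[length(tr$pos)],
      frame_start = tr$rows[1],
      frame_end = tr$rows[length(tr$rows)],
      n_points = length(tr$rows),
      velocity_um_per_s = unname(coef(fit)[2]) * px_um / dt)
  }) |> purrr::list_rbind()
}

#' Comet length from an intensity profile
#'
#' Implements the rise-to-baseline rule: the comet begins where the
#' intensity encounters a rapid rise (first position, scanning outward
#' from the peak toward the steep tip side, where the smoothed
#' derivative magnitude exceeds its threshold) and ends where the
#' intensity returns to baseline (first position outward of the peak on
#' the tail side below `baseline + baseline_k * baseline_sd`). The
#' baseline is the median of the lowest quartile of the profile.
#' Relative floors guard the zero-noise degenerate case.
#'
#' @param profile Numeric vector: intensity vs position along the path.
#' @param space_pitch_nm Spatial pitch of the profile (nm per sample).
#' @param smooth_sigma_px Gaussian smoothing sd before differentiation.
#' @param deriv_k Derivative threshold in baseline-derivative sds.
#' @param baseline_k Baseline-return threshold in baseline sds.
#' @param deriv_floor_frac,baseline_floor_frac Relative threshold floors
#'   (fractions of the peak derivative / peak height).
#' @return Length in um, or `NA` (with a `synaptrack_no_peak` warning)
#'   when no peak exceeds baseline + 3 sd.
#' @export
comet_length <- function(profile, space_pitch_nm,
                         smooth_sigma_px = 1, deriv_k = 3, baseline_k = 1,
                         deriv_floor_frac = 0.2, baseline_floor_frac = 0.02) {
  n <- length(profile)
  lowq <- sort(profile)[seq_len(max(2L, floor(n / 4)))]
  baseline <- median(lowq)
  base_sd <- sd(lowq)
  peak_i <- which.max(profile)
  peak <- profile[peak_i]
  if (!(peak > baseline + 3 * max(base_sd, 1e-12))) {
    warn("No peak above baseline + 3 sd; comet length undefined.",
         class = "synaptrack_no_peak")
    return(NA_real_)
  }
  sm <- profile
  if (smooth_sigma_px > 0) {
    r <- max(1L, ceiling(3 * smooth_sigma_px))
    k <- exp(-((-r):r)^2 / (2 * smooth_sigma_px^2)); k <- k / sum(k)
    padded <- c(rep(profile[1], r), profile, rep(profile[n], r))
    sm <- as.numeric(stats::filter(padded, k))[(r + 1):(r + n)]
  }
  # central differences keep the rule mirror-symmetric under path reversal
  dv <- c(0, (sm[3:n] - sm[1:(n - 2)]) / 2, 0)
  sm_peak_i <- which.max(sm)
  # the tip side is the steeper flank of the peak
  left <- seq_len(max(sm_peak_i - 1L, 1L))
  right <- if (sm_peak_i < n) (sm_peak_i + 1L):n else integer()
  steep_left <- if (length(left)) max(abs(dv[left])) else 0
  steep_right <- if (length(right)) max(abs(dv[right])) else 0
  tip_left <- steep_left >= steep_right
  # derivative noise threshold from the baseline region (lowest-quartile
  # positions), with a relative floor
  base_pos <- which(profile <= stats::quantile(profile, 0.25))
  dv_sd <- sd(dv[base_pos])
  dthr <- max(deriv_k * ifelse(is.finite(dv_sd), dv_sd, 0),
              deriv_floor_frac * max(abs(dv)))
  bthr <- baseline + max(baseline_k * ifelse(is.finite(base_sd), base_sd, 0),
                         baseline_floor_frac * (peak - baseline))
  scan_rise <- if (tip_left) (sm_peak_i - 1L):1L else (sm_peak_i + 1L):n
  scan_base <- if (tip_left) sm_peak_i:n else sm_peak_i:1L
  rise_i <- NA_integer_
  for (i in scan_rise) if (abs(dv[i]) > dthr) { rise_i <- i; break }
  if (is.na(rise_i)) rise_i <- if (tip_left) 1L else n
  end_i <- NA_integer_
  for (i in scan_base) if (profile[i] <= bthr) { end_i <- i; break }
  if (is.na(end_i)) end_i <- if (tip_left) n else 1L
  abs(end_i - rise_i) * space_pitch_nm / 1000
}

#' Per-group comet summaries
#'
#' @param comets Data frame with columns `velocity_um_per_s`,
#'   optionally `length_um`, and `group`.
#' @param min_n Warn (`synaptrack_min_n`) for groups below this size;
#'   the analysis convention is a minimum of 30 comets per data set.
#' @return Tibble: group, n, mean/sd of velocity and (when present)
#'   length.
#' @export
summarize_comets <- function(comets, min_n = 30) {
  comets <- as_tibble(comets)
  if (!nrow(comets)) {
    abort("No comets to summarise.", class = "synaptrack_empty_input")
  }
  if (!"group" %in% names(comets)) comets$group <- "all"
  out <- comets |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      mean_velocity_um_per_s = mean(.data$velocity_um_per_s),
      sd_velocity_um_per_s = ifelse(dplyr::n() > 1, sd(.data$velocity_um_per_s), 0),
      mean_length_um = if ("length_um" %in% names(comets))
        mean(.data$length_um, na.rm = TRUE) else NA_real_,
      sd_length_um = if ("length_um" %in% names(comets))
        ifelse(dplyr::n() > 1, sd(.data$length_um, na.rm = TRUE), 0) else NA_real_,
      .groups = "drop")
  low <- out$group[out$n < min_n]
  if (length(low)) {
    warn(sprintf("Group(s) below the minimum of %d comets: %s", min_n,
                 paste(low, collapse = ", ")),
         class = "synaptrack_min_n")
  }
  out
}
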