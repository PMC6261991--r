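# Synthetic dual-colour cluster movies: diffraction-limited spots in
# three motion states (plus-end-directed, minus-end-directed, immobile)
# with programmable inter-channel colocalisation, placed inside a cell
# geometry. Ground truth (per cluster per frame) is returned alongside.

#' Simulate ground-truth cluster trajectories (no rendering)
#'
#' Draws cluster sets inside the cell: each set is either a colocalised
#' pair (one trajectory shared by both channels) or a single-channel
#' cluster, with motion class drawn from `class_mix`, region drawn with
#' probability `centre_bias` of starting in the centre region, and
#' per-frame positions advanced along the radial direction field
#' (outward for plus, inward for minus, static for immobile).
#'
#' @param n_clusters Number of cluster sets.
#' @param spec An [acquisition_spec()].
#' @param geometry A [cell_geometry()] covering the frame.
#' @param class_mix Named fractions for classes `plus`, `minus`,
#'   `immobile`; must be non-negative and sum to 1.
#' @param coloc_fraction Proportion of cluster sets rendered identically
#'   in both channels.
#' @param centre_bias Probability a cluster starts in the centre region.
#' @param speeds_um_per_s Named per-class speeds; defaults are the
#'   plus-end growth rate 0.28 um/s and the weakly processive dynein
#'   rate 0.054 um/s.
#' @param speed_sd Optional lognormal per-cluster speed dispersion.
#' @param mean_lifetime_frames Mean of the (shifted-geometric) lifetime
#'   distribution; all lifetimes are >= `min_lifetime_frames`.
#' @param min_lifetime_frames Minimum lifetime (default 5 frames).
#' @param diameter_nm True spot FWHM (default 400 nm, above the 240 nm
#'   detection criterion).
#' @param seed Integer seed.
#' @return A tibble with one row per cluster per channel:
#'   `cluster_id`, `channel` ("A"/"B"), `colocalised`, `motion_class`,
#'   `region`, `speed_um_per_s`, `appearance_frame`,
#'   `disappearance_frame`, `diameter_nm`, and a list-column
#'   `positions` (matrix of x, y per live frame).
#' @export
sim_cluster_tracks <- function(n_clusters, spec, geometry,
                               class_mix = c(plus = 0.3, minus = 0.3, immobile = 0.4),
                               coloc_fraction = 0.5,
                               centre_bias = 0.5,
                               speeds_um_per_s = c(plus = 0.28, minus = 0.054,
                                                   immobile = 0),
                               speed_sd = 0,
                               mean_lifetime_frames = 15,
                               min_lifetime_frames = 5,
                               diameter_nm = 400,
                               seed = NULL) {
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    abort("`class_mix` fractions must be non-negative and sum to 1.",
          class = "synaptrack_bad_argument")
  }
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    abort("`coloc_fraction` must lie in [0, 1].",
          class = "synaptrack_bad_argument")
  }
  with_seed_maybe(seed, {
    px_um <- spec$pixel_size_nm / 1000
    classes <- sample(names(class_mix), n_clusters, replace = TRUE,
                      prob = class_mix)
    coloc <- runif(n_clusters) < coloc_fraction
    # non-colocalised sets alternate channels deterministically so both
    # channels are populated evenly
    solo_channel <- rep_len(c("A", "B"), n_clusters)
    region0 <- ifelse(runif(n_clusters) < centre_bias, "centre", "periphery")
    life <- pmax(min_lifetime_frames,
                 stats::rgeom(n_clusters,
                              1 / max(1, mean_lifetime_frames - min_lifetime_frames + 1)) +
                   min_lifetime_frames)
    life <- pmin(life, spec$n_frames)
    start <- vapply(life, function(L) {
      sample.int(spec$n_frames - L + 1L, 1L)
    }, integer(1))
    rows <- purrr::map(seq_len(n_clusters), function(i) {
      cls <- classes[i]
      sp_mean <- unname(speeds_um_per_s[cls])
      sp <- if (cls == "immobile") 0 else rspeed(1, sp_mean, speed_sd)
      p0 <- sample_in_cell(1, geometry, region = region0[i])
      nfr <- life[i]
      pos <- matrix(NA_real_, nfr, 2)
      pos[1, ] <- c(p0$x, p0$y)
      if (nfr > 1) {
        step_px <- um_per_s_to_px_per_frame(sp, spec$pixel_size_nm,
                                            spec$frame_interval_s)
        for (t in 2:nfr) {
          # minus-end cargo arriving at the MTOC/cell centre stops there:
          # truncate the trajectory instead of oscillating across it
          if (cls == "minus" &&
              sqrt(sum((pos[t - 1, ] - geometry$centre)^2)) <= step_px) {
            pos <- pos[seq_len(t - 1), , drop = FALSE]
            nfr <- t - 1L
            break
          }
          u <- radial_direction(geometry, pos[t - 1, 1], pos[t - 1, 2])
          dir <- switch(cls, plus = 1, minus = -1, immobile = 0)
          pos[t, ] <- pos[t - 1, ] + dir * step_px * c(u[1], u[2])
        }
      }
      channels <- if (coloc[i]) c("A", "B") else solo_channel[i]
      purrr::map(channels, function(ch) {
        tibble(cluster_id = i, channel = ch, colocalised = coloc[i],
               motion_class = cls, region = region0[i],
               speed_um_per_s = sp,
               appearance_frame = start[i],
               disappearance_frame = start[i] + nfr - 1L,
               diameter_nm = diameter_nm,
               positions = list(pos))
      }) |> purrr::list_rbind()
    })
    purrr::list_rbind(rows)
  })
}

#' Simulate a dual-colour cluster movie with ground truth
#'
#' Renders the trajectories from [sim_cluster_tracks()] as 2D Gaussian
#' spots (FWHM = `diameter_nm`) at SNR `snr` over the camera background,
#' with independent noise per channel. Colocalised pairs share the same
#' trajectory in both channels; channels are pixel-aligned unless a
#' `channel_transform` is supplied, in which case channel B is rendered
#' through it (emulating the second camera before registration).
#'
#' @inheritParams sim_cluster_tracks
#' @param snr Spot amplitude in background-noise sds (default 8).
#' @param transform Optional [channel_transform()] applied to channel B
#'   cluster positions.
#' @param ... Passed to [sim_cluster_tracks()].
#' @return List with `movie_a`, `movie_b` ([movie_stack()]s) and
#'   `truth` (the track tibble).
#' @export
sim_cluster_movie <- function(n_clusters, spec, geometry, snr = 8,
                              transform = NULL, seed = NULL, ...) {
  with_seed_maybe(seed, {
    truth <- sim_cluster_tracks(n_clusters, spec, geometry, ...)
    amp <- amplitude_for_snr(spec, snr)
    sigma_px <- truth$diameter_nm[1] / 2.3548 / spec$pixel_size_nm
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    render_channel <- function(ch) {
      clean <- array(spec$background_level, dim = c(nr, nc, spec$n_frames))
      sub <- truth[truth$channel == ch, ]
      for (k in seq_len(nrow(sub))) {
        pos <- sub$positions[[k]]
        frames <- sub$appearance_frame[k]:sub$disappearance_frame[k]
        for (j in seq_along(frames)) {
          xy <- pos[j, ]
          if (ch == "B" && !is.null(transform)) {
            xy <- transform_points(transform, xy[1], xy[2])
          }
          clean[, , frames[j]] <-
            add_gaussian_spot(clean[, , frames[j]], xy[1], xy[2], amp, sigma_px)
        }
      }
      movie_stack(apply_camera_noise(clean, spec), spec)
    }
    list(movie_a = render_channel("A"), movie_b = render_channel("B"),
         truth = truth)
  })
}
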