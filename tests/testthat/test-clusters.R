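# Cluster detection criteria (size and contrast individually
# necessary), nearest-neighbour tracking, and motion classification.

noisy_frame <- function(seed, shape = c(128L, 128L), bg = 100, sd = 4) {
  withr::with_seed(seed, {
    matrix(rpois(prod(shape), bg) + rnorm(prod(shape), sd = sd), shape[1])
  })
}

spot_frame <- function(seed, amp, fwhm_nm, x = 64.3, y = 61.7,
                       pixel_size_nm = 80) {
  fr <- noisy_frame(seed)
  sigma_px <- fwhm_nm / 2.3548 / pixel_size_nm
  add_gaussian_spot(fr, x, y, amp, sigma_px)
}

test_that("a flat frame yields no detections", {
  expect_equal(nrow(detect_clusters(matrix(7, 64, 64))), 0)
  expect_equal(nrow(detect_clusters(matrix(numeric(), 0, 0))), 0)
})

test_that("a bright 400 nm spot is detected exactly once", {
  # local noise sd ~ sqrt(100 + 16) ~ 10.8 counts; amplitude 5x that
  det <- detect_clusters(spot_frame(1, amp = 55, fwhm_nm = 400))
  expect_equal(nrow(det), 1)
  expect_equal(det$x, 64.3, tolerance = 0.3)
  expect_equal(det$y, 61.7, tolerance = 0.3)
  expect_equal(det$diameter_nm, 400, tolerance = 60)
  expect_true(det$criteria_diameter && det$criteria_contrast)
})

test_that("the 240 nm size criterion alone rejects small bright spots", {
  # 160 nm (2 px) spot, very bright: fails diameter regardless of contrast
  det <- detect_clusters(spot_frame(2, amp = 200, fwhm_nm = 160))
  expect_equal(nrow(det), 0)
  # same brightness at 400 nm is accepted: only the size flag flipped
  det2 <- detect_clusters(spot_frame(2, amp = 200, fwhm_nm = 400))
  expect_equal(nrow(det2), 1)
})

test_that("the 1-sd contrast criterion alone rejects dim spots", {
  # amplitude ~0.5 local sd: not detectable / fails contrast
  dim_spot <- spot_frame(3, amp = 5, fwhm_nm = 400)
  det <- detect_clusters(dim_spot)
  near <- det[abs(det$x - 64.3) < 3 & abs(det$y - 61.7) < 3, ]
  expect_equal(nrow(near), 0)
  # raising only the amplitude flips the outcome
  det2 <- detect_clusters(spot_frame(3, amp = 55, fwhm_nm = 400))
  expect_equal(nrow(det2), 1)
})

test_that("a stationary spot over 10 frames gives one 10-detection track", {
  spec <- spec_small(n_frames = 10)
  frames <- lapply(1:10, function(t) spot_frame(100 + t, amp = 60, fwhm_nm = 400))
  det <- detect_clusters_movie(movie_stack(frames, spec))
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("well-separated spots are never merged", {
  spec <- spec_small(n_frames = 8)
  frames <- lapply(1:8, function(t) {
    fr <- noisy_frame(200 + t)
    fr <- add_gaussian_spot(fr, 30, 30, 60, 2.1)
    add_gaussian_spot(fr, 95, 95, 60, 2.1)
  })
  tr <- link_tracks(detect_clusters_movie(movie_stack(frames, spec)))
  expect_equal(length(unique(tr$track_id)), 2)
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    expect_lt(max(dist(cbind(sub$x, sub$y))), 3)
  }
})

test_that("tracks shorter than three frames are discarded", {
  det <- tibble::tibble(frame = c(1, 2, 1:5), x = c(10, 10, 50, 50, 50, 50, 50),
                        y = c(10, 10, 80, 80, 80, 80, 80))
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(unique(tr$x), 50)
})

test_that("most truth tracks are recovered with correct identity at moderate density", {
  spec <- spec_small(n_frames = 30, shape = c(256L, 256L))
  geom <- cell_geometry(c(128.5, 128.5), c(112, 95), 10)
  sim <- sim_cluster_movie(25, spec, geom, snr = 8, seed = 55,
                           coloc_fraction = 0, mean_lifetime_frames = 20)
  truth_a <- sim$truth[sim$truth$channel == "A", ]
  tr <- link_tracks(detect_clusters_movie(sim$movie_a))
  summ <- summarize_tracks(tr)
  # a truth track counts as recovered if one linked track matches its
  # positions within 1.5 px over at least 80% of its life
  recovered <- vapply(seq_len(nrow(truth_a)), function(i) {
    pos <- truth_a$positions[[i]]
    frames <- truth_a$appearance_frame[i]:truth_a$disappearance_frame[i]
    inside <- pos[, 1] >= 5 & pos[, 1] <= 252 & pos[, 2] >= 5 & pos[, 2] <= 252
    if (sum(inside) < 3) return(NA) # left the frame; not expected recoverable
    any(vapply(split(tr, tr$track_id), function(s) {
      common <- intersect(s$frame, frames[inside])
      if (length(common) < 0.8 * sum(inside)) return(FALSE)
      j <- match(common, frames)
      all(sqrt((s$x[match(common, s$frame)] - pos[j, 1])^2 +
                 (s$y[match(common, s$frame)] - pos[j, 2])^2) < 1.5)
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(recovered, na.rm = TRUE), 0.9)
})

test_that("motion classes are assigned by speed threshold and field projection", {
  geom <- geom_default()
  mk_track <- function(id, x0, y0, vx, vy, n = 10) {
    tibble::tibble(track_id = id, frame = 1:n,
                   x = x0 + vx * (0:(n - 1)), y = y0 + vy * (0:(n - 1)))
  }
  ctr <- geom$centre
  tracks <- dplyr::bind_rows(
    mk_track(1, ctr[1] + 30, ctr[2], 0, 0),          # immobile
    mk_track(2, ctr[1] + 30, ctr[2], -0.675, 0),     # inward at 0.054 um/s
    mk_track(3, ctr[1] + 20, ctr[2], 3.5, 0))        # outward at 0.28 um/s
  cls <- classify_motion(tracks, geom)
  expect_equal(cls$motion_class, c("immobile", "minus", "plus"))
  expect_equal(cls$speed_um_per_s[2], 0.054, tolerance = 1e-9)
  expect_equal(cls$speed_um_per_s[3], 0.28, tolerance = 1e-9)
})

test_that("classification recovers a programmed 30/30/40 mix at >= 90% accuracy", {
  spec <- spec_small(n_frames = 40, shape = c(256L, 256L))
  geom <- cell_geometry(c(128.5, 128.5), c(112, 95), 0)
  sim <- sim_cluster_movie(30, spec, geom, snr = 8, seed = 66,
                           coloc_fraction = 0,
                           class_mix = c(plus = 0.3, minus = 0.3, immobile = 0.4))
  truth_a <- sim$truth[sim$truth$channel == "A", ]
  tr <- link_tracks(detect_clusters_movie(sim$movie_a))
  cls <- classify_motion(tr, geom)
  # match each classified track to the nearest truth cluster by mean position
  first_pos <- t(vapply(truth_a$positions, function(p) p[1, ], numeric(2)))
  got <- vapply(seq_len(nrow(cls)), function(i) {
    s <- tr[tr$track_id == cls$track_id[i], ]
    d <- sqrt((first_pos[, 1] - s$x[1])^2 + (first_pos[, 2] - s$y[1])^2)
    truth_a$motion_class[which.min(d)]
  }, character(1))
  acc <- mean(got == cls$motion_class, na.rm = TRUE)
  expect_gte(acc, 0.9)
})

test_that("speed and lifetime use the stated conventions", {
  trk <- tibble::tibble(track_id = 1, frame = 1:10,
                        x = 20 + 0.675 * (0:9), y = 50)
  s <- summarize_tracks(trk)
  expect_equal(s$lifetime_s, 10) # inclusive convention
  expect_equal(s$speed_um_per_s, 0.054, tolerance = 1e-12)
  still <- tibble::tibble(track_id = 1, frame = 1:5, x = 20, y = 20)
  expect_equal(summarize_tracks(still)$speed_um_per_s, 0)
  single <- tibble::tibble(track_id = 1, frame = 1, x = 1, y = 1)
  expect_error(summarize_tracks(single), class = "synaptrack_empty_input")
})

test_that("the speed estimator is unbiased on noise-free rendered tracks", {
  spec <- spec_noisefree(n_frames = 30, shape = c(256L, 256L))
  geom <- cell_geometry(c(128.5, 128.5), c(112, 95), 0)
  sim <- sim_cluster_movie(10, spec, geom, seed = 77, coloc_fraction = 0,
                           class_mix = c(plus = 1, minus = 0, immobile = 0),
                           speeds_um_per_s = c(plus = 0.2, minus = 0.054,
                                               immobile = 0))
  tr <- link_tracks(detect_clusters_movie(sim$movie_a))
  cls <- classify_motion(tr, geom)
  sp <- cls$speed_um_per_s[cls$motion_class == "plus"]
  expect_gte(length(sp), 5)
  expect_equal(mean(sp), 0.2, tolerance = 0.02 * 0.2)
})
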