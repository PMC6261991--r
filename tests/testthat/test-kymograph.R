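# Kymograph construction and comet measurement: shape/pitch contracts,
# slope-to-velocity arithmetic, automated trace detection against
# simulator ground truth, and the rise-to-baseline length rule.

make_static_line_movie <- function(spec, y = 64.5) {
  frames <- lapply(seq_len(spec$n_frames), function(t) {
    fr <- matrix(spec$background_level, spec$frame_shape[1], spec$frame_shape[2])
    fr[floor(y):ceiling(y), ] <- fr[floor(y):ceiling(y), ] + 200
    fr
  })
  movie_stack(frames, spec)
}

test_that("kymograph shape follows the path length contract", {
  spec <- spec_noisefree(n_frames = 60, shape = c(128L, 128L))
  mv <- make_static_line_movie(spec)
  ky <- build_kymograph(mv, rbind(c(10, 64.5), c(110, 64.5))) # length 100
  expect_equal(dim(unclass(ky)), c(60L, 101L))
  expect_equal(attr(ky, "space_pitch_nm"), 80)
  expect_equal(attr(ky, "time_pitch_s"), 1)
  # fractional path length rounds up and keeps the end point
  ky2 <- build_kymograph(mv, rbind(c(10, 64.5), c(110.4, 64.5)))
  expect_equal(ncol(ky2), 102L)
})

test_that("a static structure gives identical kymograph rows", {
  spec <- spec_noisefree(n_frames = 10)
  mv <- make_static_line_movie(spec)
  ky <- build_kymograph(mv, rbind(c(10, 64.5), c(110, 64.5)))
  for (t in 2:10) expect_equal(ky[t, ], ky[1, ])
})

test_that("a point moving 1 px/frame traces a 45-degree kymograph line", {
  spec <- spec_noisefree(n_frames = 40)
  frames <- lapply(seq_len(40), function(t) {
    fr <- matrix(spec$background_level, 128, 128)
    add_gaussian_spot(fr, 20 + (t - 1), 64.5, 300, 1.5)
  })
  mv <- movie_stack(frames, spec)
  ky <- build_kymograph(mv, rbind(c(10, 64.5), c(110, 64.5)))
  peaks <- apply(ky, 1, which.max)
  expect_equal(diff(peaks), rep(1L, 39))
})

test_that("a path outside the image is rejected", {
  spec <- spec_noisefree(n_frames = 5)
  mv <- make_static_line_movie(spec)
  expect_error(build_kymograph(mv, rbind(c(-5, 64), c(80, 64))),
               class = "synaptrack_path_outside")
})

test_that("segment slope converts to um/s by the kymograph pitches", {
  spec <- spec_noisefree(n_frames = 20)
  ky <- build_kymograph(make_static_line_movie(spec),
                        rbind(c(10, 64.5), c(110, 64.5)))
  # 1 px/frame at 80 nm/px, 1 s/frame
  expect_equal(trace_velocity(ky, c(10, 20), c(1, 11)), 0.08)
  # vertical trace: zero velocity
  expect_equal(trace_velocity(ky, c(30, 30), c(1, 11)), 0)
  expect_error(trace_velocity(ky, c(10, 20), c(5, 5)),
               class = "synaptrack_bad_argument")
})

test_that("a pure-noise kymograph yields no traces at default sensitivity", {
  spec <- spec_small(n_frames = 40)
  sim <- sim_comet_movie(spec, n_comets = 0, seed = 17)
  ky <- build_kymograph(sim$movie, rbind(c(10, 64.5), c(110, 64.5)))
  expect_equal(nrow(detect_traces(ky)), 0)
})

test_that("two comets of different speeds are both recovered within 10%", {
  spec <- spec_small(n_frames = 50)
  path <- rbind(c(10, 64.5), c(118, 64.5))
  sim1 <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.2,
                          paths = list(path), seed = 31)
  sim2 <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.4,
                          paths = list(rbind(c(10, 30.5), c(118, 30.5))),
                          seed = 32)
  both <- movie_stack(unclass(sim1$movie) + unclass(sim2$movie) -
                        spec$background_level, spec)
  ky1 <- build_kymograph(both, path)
  ky2 <- build_kymograph(both, rbind(c(10, 30.5), c(118, 30.5)))
  v1 <- detect_traces(ky1)$velocity_um_per_s
  v2 <- detect_traces(ky2)$velocity_um_per_s
  expect_gte(length(v1), 1)
  expect_gte(length(v2), 1)
  expect_equal(v1[which.max(abs(v1))], 0.2, tolerance = 0.1)
  expect_equal(v2[which.max(abs(v2))], 0.4, tolerance = 0.1)
})

test_that("a single comet at SNR >= 5 is always detected (recall 1/1)", {
  spec <- spec_small(n_frames = 40)
  path <- rbind(c(10, 64.5), c(118, 64.5))
  for (s in 1:3) {
    sim <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.3,
                           snr = 5, paths = list(path), seed = 40 + s)
    tr <- detect_traces(build_kymograph(sim$movie, path))
    expect_gte(nrow(tr), 1)
  }
})

test_that("kymograph velocities agree with raw tip positions (pitch consistency)", {
  spec <- spec_noisefree(n_frames = 40)
  path <- rbind(c(10, 64.5), c(118, 64.5))
  sim <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.3,
                         paths = list(path), seed = 51)
  ky <- build_kymograph(sim$movie, path)
  v_kymo <- detect_traces(ky)$velocity_um_per_s[1]
  # algorithm-free estimator: frame-to-frame argmax displacement of the
  # raw frames along the line
  birth <- sim$truth$birth_frame[1]
  tips <- vapply(birth + 3:15, function(t) {
    fr <- get_frame(sim$movie, t)
    which.max(colSums(fr[64:65, ])) # column of the tip
  }, numeric(1))
  v_raw <- mean(diff(tips)) * 0.08
  expect_equal(v_kymo, v_raw, tolerance = 0.05 * v_raw)
})

test_that("reversing the path negates velocities and preserves lengths", {
  spec <- spec_small(n_frames = 40)
  path <- rbind(c(10, 64.5), c(118, 64.5))
  sim <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.3,
                         paths = list(path), seed = 61)
  ky_f <- build_kymograph(sim$movie, path)
  ky_r <- build_kymograph(sim$movie, path[2:1, ])
  vf <- detect_traces(ky_f)$velocity_um_per_s
  vr <- detect_traces(ky_r)$velocity_um_per_s
  expect_equal(sort(vf), sort(-vr), tolerance = 1e-6)
  t_mid <- sim$truth$birth_frame[1] + 8
  lf <- comet_length(ky_f[t_mid, ], 80)
  lr <- comet_length(ky_r[t_mid, ], 80)
  expect_equal(lf, lr, tolerance = 1e-9)
})

test_that("velocities in um/s are invariant to the pixel-size / pixel-speed trade", {
  # same physical speed rendered at 80 nm/px and at 160 nm/px
  spec1 <- spec_noisefree(n_frames = 30)
  spec2 <- acquisition_spec(frame_shape = c(128L, 128L), n_frames = 30,
                            pixel_size_nm = 160, background_level = 100,
                            gaussian_noise_sd = 0, poisson_noise = FALSE)
  path <- rbind(c(10, 64.5), c(118, 64.5))
  v1 <- detect_traces(build_kymograph(
    sim_comet_movie(spec1, 1, 0.24, paths = list(path), seed = 71)$movie,
    path))$velocity_um_per_s
  v2 <- detect_traces(build_kymograph(
    sim_comet_movie(spec2, 1, 0.24, paths = list(path), seed = 71)$movie,
    path))$velocity_um_per_s
  expect_equal(v1[which.max(abs(v1))], 0.24, tolerance = 0.02)
  expect_equal(v2[which.max(abs(v2))], 0.24, tolerance = 0.02)
})

test_that("a rectangular pulse measures its own extent", {
  prof <- c(rep(0, 40), rep(100, 10), rep(0, 40))
  expect_equal(comet_length(prof, 80), 0.80, tolerance = 0.08)
})

test_that("a flat profile has undefined comet length", {
  expect_warning(out <- comet_length(rep(5, 80), 80),
                 class = "synaptrack_no_peak")
  expect_true(is.na(out))
})

test_that("measured comet length matches the rule applied to the clean kernel", {
  spec <- spec_small(n_frames = 30)
  path <- rbind(c(5, 64.5), c(123, 64.5))
  sim_clean <- sim_comet_movie(spec_noisefree(n_frames = 30), 1, 0.3,
                               tail_decay_um = 0.4, paths = list(path),
                               seed = 81)
  sim_noisy <- sim_comet_movie(spec, 1, 0.3, tail_decay_um = 0.4,
                               paths = list(path), seed = 81)
  t_mid <- sim_clean$truth$birth_frame[1] + 12
  ky_c <- build_kymograph(sim_clean$movie, path)
  ky_n <- build_kymograph(sim_noisy$movie, path)
  ref <- comet_length(ky_c[t_mid, ], 80)
  meas <- comet_length(ky_n[t_mid, ], 80)
  expect_false(is.na(ref))
  expect_equal(meas, ref, tolerance = 0.15)
})

test_that("comet summaries report mean, sd and the minimum-n warning", {
  one <- tibble::tibble(velocity_um_per_s = 0.31, group = "wt")
  expect_warning(s1 <- summarize_comets(one), class = "synaptrack_min_n")
  expect_equal(s1$mean_velocity_um_per_s, 0.31)
  expect_equal(s1$sd_velocity_um_per_s, 0)
  # warning only for the group under 30
  two <- tibble::tibble(
    velocity_um_per_s = rnorm(60, 0.3, 0.01),
    group = rep(c("small", "big"), c(29, 31)))
  w <- testthat::capture_warnings(summarize_comets(two))
  expect_length(w, 1)
  expect_match(w, "small")
  expect_no_match(w, "big")
  expect_error(summarize_comets(two[0, ]), class = "synaptrack_empty_input")
})

test_that("thirty noisy comets recover the programmed mean within 3 SE", {
  withr::with_seed(91, {
    v <- rspeed(30, 0.28, 0.05)
  })
  s <- summarize_comets(tibble::tibble(velocity_um_per_s = v, group = "g"))
  se <- 0.05 / sqrt(30)
  expect_lt(abs(s$mean_velocity_um_per_s - 0.28), 3 * se)
})
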