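# The simulators must honour their ground-truth contracts: rendered
# features match the returned truth exactly, randomness is fully
# seed-determined, and programmed rates are recovered at large n.

test_that("an empty comet scene is pure camera noise at the background level", {
  spec <- spec_small(n_frames = 1)
  sim <- sim_comet_movie(spec, n_comets = 0, seed = 1)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(mean(sim$movie), spec$background_level,
               tolerance = 3 / sqrt(length(sim$movie) / 110))
})

test_that("comet tips advance at the programmed speed in pixel units", {
  # 0.30 um/s at 80 nm/px, 1 s/frame -> 3.75 px/frame along the path
  expect_equal(0.30 * 1000 / 80, 3.75)
  spec <- spec_noisefree(n_frames = 12)
  path <- straight_path()
  sim <- sim_comet_movie(spec, n_comets = 1, speed_um_per_s = 0.30,
                         paths = list(path), seed = 5)
  birth <- sim$truth$birth_frame[1]
  # locate the tip (intensity argmax along the path) in two frames
  tip_col <- function(t) {
    prof <- get_frame(sim$movie, t)[64:65, 10:118]
    which.max(colSums(prof))
  }
  t1 <- birth + 4; t2 <- birth + 6
  expect_equal((tip_col(t2) - tip_col(t1)) / (t2 - t1), 3.75, tolerance = 0.2)
})

test_that("identical seeds give bit-identical comet movies", {
  spec <- spec_small(n_frames = 5)
  a <- sim_comet_movie(spec, n_comets = 3, seed = 42)
  b <- sim_comet_movie(spec, n_comets = 3, seed = 42)
  expect_identical(unclass(a$movie), unclass(b$movie))
  expect_identical(a$truth$speed_um_per_s, b$truth$speed_um_per_s)
  c <- sim_comet_movie(spec, n_comets = 3, seed = 43)
  expect_false(identical(unclass(a$movie), unclass(c$movie)))
})

test_that("every rendered comet appears in the truth list and vice versa", {
  spec <- spec_noisefree(n_frames = 10)
  sim <- sim_comet_movie(spec, n_comets = 4, seed = 9)
  expect_equal(nrow(sim$truth), 4)
  # each truth comet leaves signal above background near its path at a
  # frame where it is alive
  for (i in 1:4) {
    t <- min(sim$truth$birth_frame[i] + 2, 10)
    tip_s <- (t - sim$truth$birth_frame[i]) * 3.75 # not used; sample path box
    p <- sim$truth$path[[i]]
    fr <- get_frame(sim$movie, t)
    box <- fr[max(1, floor(min(p[, 2])) - 3):min(128, ceiling(max(p[, 2])) + 3),
              max(1, floor(min(p[, 1])) - 3):min(128, ceiling(max(p[, 1])) + 3)]
    expect_gt(max(box), spec$background_level + 1)
  }
})

test_that("cluster truth honours the programmed class displacement", {
  # minus class at 0.054 um/s -> 0.675 px/frame toward the cell centre
  expect_equal(0.054 * 1000 / 80, 0.675)
  spec <- spec_small(n_frames = 30)
  geom <- geom_default()
  tr <- sim_cluster_tracks(40, spec, geom, seed = 3,
                           class_mix = c(plus = 0, minus = 1, immobile = 0),
                           coloc_fraction = 0)
  for (k in sample(nrow(tr), 5)) {
    pos <- tr$positions[[k]]
    steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
    expect_equal(unname(steps), rep(0.675, nrow(pos) - 1), tolerance = 1e-10)
    # displacement is toward the centre (negative radial projection)
    u <- pos[2, ] - pos[1, ]
    ctr <- geom$centre - pos[1, ]
    expect_gt(sum(u * ctr), 0)
  }
})

test_that("coloc_fraction = 0 yields no shared trajectories across channels", {
  tr <- sim_cluster_tracks(60, spec_small(), geom_default(), seed = 11,
                           coloc_fraction = 0)
  expect_false(any(tr$colocalised))
  # every cluster id appears in exactly one channel
  expect_true(all(table(tr$cluster_id) == 1))
})

test_that("truth colocalisation proportion matches the programmed fraction", {
  n <- 1000
  tr <- sim_cluster_tracks(n, spec_small(), geom_default(), seed = 21,
                           coloc_fraction = 0.5)
  n_coloc <- length(unique(tr$cluster_id[tr$colocalised]))
  ci <- binom_count_ci(n, 0.5, conf = 0.99)
  expect_gte(n_coloc, ci[1])
  expect_lte(n_coloc, ci[2])
})

test_that("empirical class mix converges to the requested mix", {
  mix <- c(plus = 0.3, minus = 0.3, immobile = 0.4)
  tr <- sim_cluster_tracks(600, spec_small(), geom_default(), seed = 8,
                           class_mix = mix, coloc_fraction = 0)
  emp <- table(tr$motion_class)[names(mix)] / nrow(tr)
  for (cls in names(mix)) {
    ci <- binom_count_ci(nrow(tr), mix[[cls]], conf = 0.999) / nrow(tr)
    expect_gte(emp[[cls]], ci[1])
    expect_lte(emp[[cls]], ci[2])
  }
})

test_that("colocalised pairs share position and class over their lifetime", {
  tr <- sim_cluster_tracks(50, spec_small(), geom_default(), seed = 13,
                           coloc_fraction = 1)
  for (id in unique(tr$cluster_id)) {
    sub <- tr[tr$cluster_id == id, ]
    expect_equal(nrow(sub), 2)
    expect_identical(sub$positions[[1]], sub$positions[[2]])
    expect_identical(sub$motion_class[1], sub$motion_class[2])
  }
})

test_that("the MTOC spot is sharpest at the refraction-scaled stage shift", {
  spec <- spec_small(n_frames = 1, shape = c(64L, 64L))
  # depth 0: sharpest at stage 0
  st0 <- sim_mtoc_stack(spec, c(32, 32), true_depth_um = 0,
                        z_range_um = c(0, 1.5), z_step_um = 0.05, seed = 2)
  expect_equal(st0$truth$best_focus_stage_um, 0)
  peaks0 <- apply(st0$stack, 3, max)
  expect_equal(which.max(peaks0), 1)
  # depth 0.9013 um with n 1.37/1.52: best mechanical shift 1.0 um
  depth <- 1.0 * 1.37 / 1.52
  st1 <- sim_mtoc_stack(spec, c(32, 32), true_depth_um = depth,
                        z_range_um = c(0, 2), z_step_um = 0.05, seed = 2)
  expect_equal(st1$truth$best_focus_stage_um, 1.0, tolerance = 1e-12)
  bf <- find_best_focus(st1)
  expect_equal(bf$best_focus_stage_um, 1.0, tolerance = 0.05)
  # and the corrected distance recovers the true depth
  expect_equal(correct_axial_distance(bf$best_focus_stage_um), depth,
               tolerance = 0.05)
})

test_that("defocus blur grows monotonically away from best focus", {
  spec <- spec_noisefree(n_frames = 1, shape = c(64L, 64L))
  st <- sim_mtoc_stack(spec, c(32, 32), true_depth_um = 1.37 / 1.52,
                       z_range_um = c(0, 2), z_step_um = 0.1, seed = 1)
  peaks <- apply(st$stack, 3, max)
  i_best <- which.min(abs(st$stage_z_um - 1.0))
  expect_true(all(diff(peaks[1:i_best]) > 0))
  expect_true(all(diff(peaks[i_best:length(peaks)]) < 0))
})

test_that("lattice node spacing is pitch / pixel size and identity warp is noise-only", {
  # 10 um at 80 nm/px -> 125 px
  expect_equal(10 * 1000 / 80, 125)
  spec <- acquisition_spec(frame_shape = c(512L, 512L), n_frames = 1,
                           background_level = 100, gaussian_noise_sd = 4)
  lat <- sim_lattice_pair(spec, channel_transform(), seed = 4)
  expect_equal(diff(sort(unique(lat$nodes_a$x))),
               rep(125, length(unique(lat$nodes_a$x)) - 1))
  # identity transform: A and B differ only by independent noise
  dif <- lat$image_a - lat$image_b
  expect_lt(abs(mean(dif)), 1)
  expect_lt(sd(dif), 4 * sqrt(2 * (100 + 16) / 16) * 3) # loose noise bound
  expect_gt(sd(dif), 1)
})

test_that("a pure shift is recovered by cross-correlation of the pair", {
  spec <- acquisition_spec(frame_shape = c(512L, 512L), n_frames = 1)
  tr <- channel_transform(shift = c(3.2, -1.7))
  lat <- sim_lattice_pair(spec, tr, seed = 6)
  sh <- xcorr_shift(lat$image_a, lat$image_b)
  expect_equal(unname(sh["dx.col"]), 3.2, tolerance = 0.1)
  expect_equal(unname(sh["dy.row"]), -1.7, tolerance = 0.1)
})

test_that("qPCR tables encode fold changes as -log2 in ddCT", {
  # zero noise: fold 1 -> ddCT 0; fold 0.5 -> ddCT 1
  tab <- sim_qpcr_table(3, c(cond_a = 1, cond_b = 0.5), ct_noise_sd = 0,
                        seed = 1)
  fc <- relative_expression(tab, "calibrator")
  expect_equal(fc$ddct[fc$condition == "cond_a"], rep(0, 3))
  expect_equal(fc$ddct[fc$condition == "cond_b"], rep(1, 3))
  expect_equal(fc$fold_change[fc$condition == "cond_b"], rep(0.5, 3))
  expect_error(sim_qpcr_table(3, c(bad = -1)), class = "synaptrack_bad_argument")
})
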