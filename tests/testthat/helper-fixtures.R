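# Shared fixtures: small acquisition specs and a default cell geometry.
# Everything is generated in code at test time; no stored data.

spec_small <- function(n_frames = 30, shape = c(128L, 128L), ...) {
  acquisition_spec(frame_shape = shape, n_frames = n_frames, ...)
}

spec_noisefree <- function(n_frames = 30, shape = c(128L, 128L), ...) {
  acquisition_spec(frame_shape = shape, n_frames = n_frames,
                   background_level = 100, gaussian_noise_sd = 0,
                   poisson_noise = FALSE, ...)
}

geom_default <- function(shape = c(128L, 128L)) {
  cell_geometry(centre = (shape[c(2, 1)] + 1) / 2,
                semi_axes = c(0.44, 0.36) * min(shape), rotation_deg = 15)
}

# exact binomial two-sided CI bounds on a count at confidence `conf`
binom_count_ci <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}

# single straight horizontal path across a frame, y fixed
straight_path <- function(y = 64.5, x0 = 10, x1 = 118) {
  rbind(c(x0, y), c(x1, y))
}
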