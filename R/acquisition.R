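# Acquisition metadata and the movie container.
#
# A movie is a numeric array [row, col, frame] carrying its acquisition
# spec; intensities are camera counts. Defaults follow the imaging setup
# being emulated: EMCCD at approximately 80 nm/pixel, 1 frame/s.

#' Describe how a (synthetic) movie is acquired
#'
#' Bundles pixel pitch, frame interval, frame geometry and the camera
#' noise model used by all simulators. The noise model is Poisson shot
#' noise on signal + background plus additive Gaussian read noise,
#' an EMCCD-like default; the original data's camera statistics are not
#' published, so these are free parameters, not claims about real data.
#'
#' @param frame_shape Integer vector `c(rows, cols)` in pixels.
#' @param n_frames Number of frames (>= 1).
#' @param pixel_size_nm Physical pixel pitch in nanometres (default 80).
#' @param frame_interval_s Time between frames in seconds (default 1).
#' @param background_level Mean background counts per pixel.
#' @param gaussian_noise_sd Additive read-noise standard deviation (counts).
#' @param poisson_noise Apply Poisson shot noise? (default `TRUE`).
#' @return An `acquisition_spec` object (a validated list).
#' @export
acquisition_spec <- function(frame_shape = c(256L, 256L),
                             n_frames = 60L,
                             pixel_size_nm = 80,
                             frame_interval_s = 1,
                             background_level = 100,
                             gaussian_noise_sd = 4,
                             poisson_noise = TRUE) {
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  if (length(frame_shape) != 2L || any(frame_shape < 1)) {
    abort("`frame_shape` must be c(rows, cols) with positive entries.",
          class = "synaptrack_bad_argument")
  }
  if (n_frames < 1) {
    abort("`n_frames` must be >= 1.", class = "synaptrack_bad_argument")
  }
  if (background_level < 0 || gaussian_noise_sd < 0) {
    abort("Background and noise levels must be non-negative.",
          class = "synaptrack_bad_argument")
  }
  structure(
    list(
      frame_shape = as.integer(frame_shape),
      n_frames = as.integer(n_frames),
      pixel_size_nm = pixel_size_nm,
      frame_interval_s = frame_interval_s,
      background_level = background_level,
      gaussian_noise_sd = gaussian_noise_sd,
      poisson_noise = isTRUE(poisson_noise)
    ),
    class = "acquisition_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf(
    "<acquisition_spec> %d x %d px, %d frames, %.3g nm/px, %.3g s/frame\n",
    x$frame_shape[1], x$frame_shape[2], x$n_frames,
    x$pixel_size_nm, x$frame_interval_s))
  cat(sprintf("  background %.3g counts, read noise sd %.3g, shot noise %s\n",
              x$background_level, x$gaussian_noise_sd,
              if (x$poisson_noise) "on" else "off"))
  invisible(x)
}

# Peak amplitude (counts) giving a requested signal-to-noise ratio against
# the per-pixel background noise sd sqrt(background + read^2).
amplitude_for_snr <- function(spec, snr) {
  shot <- if (spec$poisson_noise) spec$background_level else 0
  noise_sd <- sqrt(shot + spec$gaussian_noise_sd^2)
  # noise-free rendering still needs signal: scale as if shot noise applied
  if (noise_sd == 0) noise_sd <- max(sqrt(spec$background_level), 1)
  snr * noise_sd
}

#' Construct a movie stack
#'
#' @param frames Numeric array `[row, col, frame]` or a list of matrices.
#' @param spec The [acquisition_spec()] the movie was acquired under.
#' @return A `movie_stack` (numeric array with spec attached).
#' @export
movie_stack <- function(frames, spec) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L)
  structure(frames, spec = spec, class = c("movie_stack", "array"))
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<movie_stack> %d x %d px, %d frames\n", d[1], d[2], d[3]))
  invisible(x)
}

n_frames <- function(movie) dim(movie)[3]

get_frame <- function(movie, t) {
  movie[, , t, drop = TRUE]
}

movie_spec <- function(movie) attr(movie, "spec")

# Apply the camera noise model of `spec` to a clean (expected-counts)
# array. Vectorised over the whole stack.
apply_camera_noise <- function(clean, spec) {
  x <- clean
  if (spec$poisson_noise) {
    x[] <- rpois(length(x), lambda = pmax(x, 0))
  }
  if (spec$gaussian_noise_sd > 0) {
    x <- x + rnorm(length(x), sd = spec$gaussian_noise_sd)
  }
  x
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' Counts are stored as 16-bit TIFF scaled by the recorded `scale_max`;
#' the sidecar carries the acquisition spec so a round trip preserves
#' physical units and pitches.
#'
#' @param movie A `movie_stack`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_movie()` the path, invisibly; `read_movie()` a
#'   `movie_stack`.
#' @export
write_movie <- function(movie, path) {
  spec <- movie_spec(movie)
  mx <- max(movie, 1e-9)
  pages <- lapply(seq_len(n_frames(movie)),
                  function(t) pmin(pmax(get_frame(movie, t) / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(scale_max = mx, spec = unclass(spec)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) p * side$scale_max)
  spec <- do.call(acquisition_spec, side$spec[c(
    "frame_shape", "n_frames", "pixel_size_nm", "frame_interval_s",
    "background_level", "gaussian_noise_sd", "poisson_noise")])
  movie_stack(frames, spec)
}
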