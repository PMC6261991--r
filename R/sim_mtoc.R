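# Synthetic MTOC focal series: a bright spot at a known depth above the
# coverslip imaged at a range of z-stage positions. The defocus model is
# a Gaussian whose width grows linearly with distance from best focus
# and whose integrated intensity is conserved (peak falls as 1/width^2)
# — sufficient for best-focus localisation, not a physical PSF.

#' Simulate an MTOC through-focus image series
#'
#' The spot is sharpest (maximum peak, minimum width) at the stage
#' position equal to the true depth scaled by the inverse refraction
#' correction, i.e. at the mechanical shift
#' `z0 = depth * n_glass / n_specimen`.
#'
#' @param spec An [acquisition_spec()] (frame geometry and noise; one
#'   frame per stage position).
#' @param lateral_position `c(x, y)` of the MTOC in pixels.
#' @param true_depth_um True distance from the contact surface (>= 0).
#' @param z_range_um Stage positions scanned, `c(min, max)` relative to
#'   the contact-surface focus.
#' @param z_step_um Stage step (> 0).
#' @param model A [refraction_model()].
#' @param focus_sigma_um In-focus spot sd (default 0.15 um).
#' @param defocus_slope Width growth per um of defocus (default 0.35).
#' @param amplitude In-focus peak amplitude in counts.
#' @param seed Integer seed.
#' @return List: `stack` ([movie_stack()], one frame per stage
#'   position), `stage_z_um` (positions), `truth` (list with
#'   `lateral_position`, `true_depth_um`, `best_focus_stage_um`).
#' @export
sim_mtoc_stack <- function(spec, lateral_position, true_depth_um,
                           z_range_um = c(0, 3), z_step_um = 0.1,
                           model = refraction_model(),
                           focus_sigma_um = 0.15, defocus_slope = 0.35,
                           amplitude = 2000, seed = NULL) {
  stop_if_not_scalar_pos(z_step_um, "z_step_um")
  if (true_depth_um < 0) {
    abort("`true_depth_um` must be non-negative.",
          class = "synaptrack_bad_argument")
  }
  zs <- seq(z_range_um[1], z_range_um[2], by = z_step_um)
  if (!length(zs)) {
    abort("Empty z range.", class = "synaptrack_bad_argument")
  }
  best_z0 <- true_depth_um * model$n_glass / model$n_specimen
  px_um <- spec$pixel_size_nm / 1000
  with_seed_maybe(seed, {
    frames <- lapply(zs, function(z) {
      defocus <- abs(z - best_z0)
      sigma_um <- focus_sigma_um + defocus_slope * defocus
      sigma_px <- sigma_um / px_um
      peak <- amplitude * (focus_sigma_um / sigma_um)^2
      fr <- matrix(spec$background_level, spec$frame_shape[1],
                   spec$frame_shape[2])
      fr <- add_gaussian_spot(fr, lateral_position[1], lateral_position[2],
                              peak, sigma_px)
      matrix(apply_camera_noise(fr, spec), nrow(fr))
    })
    list(stack = movie_stack(frames, spec), stage_z_um = zs,
         truth = list(lateral_position = lateral_position,
                      true_depth_um = true_depth_um,
                      best_focus_stage_um = best_z0))
  })
}

#' Find the best-focus stage position of a through-focus series
#'
#' Fits a Gaussian to the spot in every frame and maximises the
#' sharpness metric peak / fitted width, with parabolic refinement of
#' the metric around its maximum. Feed the result to
#' [correct_axial_distance()] to obtain the true depth.
#'
#' @param stack_result Output of [sim_mtoc_stack()], or a list with
#'   `stack` and `stage_z_um`.
#' @param lateral_hint Optional `c(x, y)` seed for the spot fit
#'   (defaults to the brightest pixel of the sharpest-looking frame).
#' @return List: `best_focus_stage_um`, `metric` tibble
#'   (`stage_z_um`, `peak`, `sigma_px`, `sharpness`).
#' @export
find_best_focus <- function(stack_result, lateral_hint = NULL) {
  stack <- stack_result$stack
  zs <- stack_result$stage_z_um
  if (is.null(lateral_hint)) {
    mx <- which.max(apply(stack, 3, max))
    fr <- get_frame(stack, mx)
    idx <- arrayInd(which.max(fr), dim(fr))
    lateral_hint <- c(idx[2], idx[1])
  }
  rows <- purrr::map(seq_len(n_frames(stack)), function(t) {
    g <- fit_gaussian_spot(get_frame(stack, t), lateral_hint[1],
                           lateral_hint[2], window = 10L)
    if (is.null(g)) return(NULL)
    tibble(stage_z_um = zs[t], peak = g$amp, sigma_px = g$sigma,
           sharpness = g$amp / g$sigma)
  })
  metric <- purrr::list_rbind(rows)
  i <- which.max(metric$sharpness)
  best <- metric$stage_z_um[i]
  if (i > 1 && i < nrow(metric)) {
    y0 <- metric$sharpness[i - 1]; y1 <- metric$sharpness[i]
    y2 <- metric$sharpness[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      best <- best + 0.5 * (y0 - y2) / den * diff(metric$stage_z_um[i + 0:1])
    }
  }
  list(best_focus_stage_um = best, metric = metric)
}
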