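# Shared small helpers: unit conversions, seeds, validation.

#' Convert speeds between micrometres per minute and per second
#'
#' Microtubule growth rates are conventionally reported in um/min while
#' single-particle velocities are reported in um/s; the exact conversion
#' factor is 1/60.
#'
#' @param x Numeric vector of speeds.
#' @return Numeric vector in the other unit.
#' @examples
#' um_per_min_to_um_per_s(17.9) # 0.298...
#' um_per_min_to_um_per_s(3.26) # 0.0543...
#' @export
um_per_min_to_um_per_s <- function(x) x / 60

#' @rdname um_per_min_to_um_per_s
#' @export
um_per_s_to_um_per_min <- function(x) x * 60

# px/frame <-> um/s for a given acquisition
px_per_frame_to_um_per_s <- function(x, pixel_size_nm, frame_interval_s) {
  x * pixel_size_nm / 1000 / frame_interval_s
}

um_per_s_to_px_per_frame <- function(x, pixel_size_nm, frame_interval_s) {
  x * 1000 / pixel_size_nm * frame_interval_s
}

# Evaluate `expr` under a fixed RNG state when `seed` is given, otherwise
# consume the current stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "synaptrack_bad_argument")
  }
  invisible(x)
}

# Wilson score 95% interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# Draw n positive speeds with exact mean `mean` and sd `sd` (lognormal);
# sd = 0 gives the constant value.
rspeed <- function(n, mean, sd = 0) {
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
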