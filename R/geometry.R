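# Cell geometry: the fitted boundary ellipse and the concentric
# half-diameter "centre" ellipse dividing centre from periphery.

#' Cell geometry: boundary ellipse and half-diameter centre ellipse
#'
#' The centre/periphery dichotomy used for both MTOC positions and
#' cluster tracks: a point is "centre" when its normalised elliptical
#' radius (in the ellipse frame, `sqrt((x'/a)^2 + (y'/b)^2)`) is at most
#' `centre_fraction` (default one half, i.e. the ellipse with half the
#' cell's diameters, covering a quarter of the cell area).
#'
#' @param centre Numeric `c(x, y)` in pixels.
#' @param semi_axes Numeric `c(a, b)` semi-axis lengths in pixels, `a >= b`.
#' @param rotation_deg Major-axis angle, degrees anticlockwise from +x.
#' @param centre_fraction Normalised radius dividing centre from periphery.
#' @return A `cell_geometry` object.
#' @export
cell_geometry <- function(centre, semi_axes, rotation_deg = 0,
                          centre_fraction = 0.5) {
  if (semi_axes[1] < semi_axes[2]) {
    semi_axes <- rev(semi_axes)
    rotation_deg <- rotation_deg + 90
  }
  if (any(semi_axes <= 0)) {
    abort("Semi-axes must be positive.", class = "synaptrack_bad_argument")
  }
  if (centre_fraction <= 0 || centre_fraction >= 1) {
    abort("`centre_fraction` must lie in (0, 1).",
          class = "synaptrack_bad_argument")
  }
  structure(
    list(centre = as.numeric(centre), semi_axes = as.numeric(semi_axes),
         rotation_deg = (rotation_deg %% 180),
         centre_fraction = centre_fraction),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> centre (%.1f, %.1f), a = %.1f px, b = %.1f px, %.1f deg\n",
    x$centre[1], x$centre[2], x$semi_axes[1], x$semi_axes[2], x$rotation_deg))
  cat(sprintf("  centre region: normalised radius <= %.2f\n",
              x$centre_fraction))
  invisible(x)
}

#' @method tidy cell_geometry
#' @export
tidy.cell_geometry <- function(x, ...) {
  tibble(
    term = c("centre_x", "centre_y", "semi_axis_a", "semi_axis_b",
             "rotation_deg", "centre_fraction"),
    estimate = c(x$centre, x$semi_axes, x$rotation_deg, x$centre_fraction))
}

# Normalised elliptical radius of points (x, y): 0 at centre, 1 on the
# boundary ellipse.
elliptical_radius <- function(geometry, x, y) {
  th <- geometry$rotation_deg * pi / 180
  dx <- x - geometry$centre[1]
  dy <- y - geometry$centre[2]
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  sqrt((xr / geometry$semi_axes[1])^2 + (yr / geometry$semi_axes[2])^2)
}

#' Classify points as centre or periphery
#'
#' Points on the centre-ellipse boundary count as centre; points outside
#' the cell boundary are flagged `NA` with a warning and are excluded
#' from downstream fractions.
#'
#' @param data Data frame with columns `x`, `y` (pixels).
#' @param geometry A [cell_geometry()].
#' @return The input tibble with `elliptical_radius` and
#'   `region` (`"centre"`/`"periphery"`, `NA` outside the cell) added.
#' @export
classify_region <- function(data, geometry) {
  data <- as_tibble(data)
  r <- elliptical_radius(geometry, data$x, data$y)
  region <- ifelse(r <= geometry$centre_fraction, "centre", "periphery")
  outside <- r > 1
  if (any(outside)) {
    warn(sprintf("%d point(s) outside the cell boundary; region set to NA.",
                 sum(outside)),
         class = "synaptrack_outside_cell")
    region[outside] <- NA_character_
  }
  data$elliptical_radius <- r
  data$region <- region
  data
}

# --- ellipse fitting -------------------------------------------------------

# Direct least-squares conic fit (ellipse-specific), then conversion to
# geometric parameters.
fit_ellipse_conic <- function(x, y) {
  if (length(x) < 5L) {
    abort("At least 5 boundary points are required.",
          class = "synaptrack_degenerate_fit")
  }
  mx <- mean(x); my <- mean(y)
  sc <- max(sd(x), sd(y))
  if (!is.finite(sc) || sc == 0) {
    abort("Degenerate boundary points.", class = "synaptrack_degenerate_fit")
  }
  xs <- (x - mx) / sc
  ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    abort("Degenerate boundary points (collinear or coincident).",
          class = "synaptrack_degenerate_fit")
  })
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  pick <- which(cond > 0)
  if (length(pick) == 0L) {
    abort("No ellipse solution (degenerate point set).",
          class = "synaptrack_degenerate_fit")
  }
  a1 <- evec[, pick[1]]
  par <- c(a1, Tm %*% a1) # A B C D E F in scaled frame
  # unscale: x = (X - mx)/sc
  A <- par[1]; B <- par[2]; C <- par[3]
  D <- par[4] * sc; E <- par[5] * sc; F <- par[6] * sc^2
  D <- D - 2 * A * mx - B * my
  E <- E - 2 * C * my - B * mx
  F <- F + A * mx^2 + B * mx * my + C * my^2 -
    (par[4] * sc) * mx - (par[5] * sc) * my
  conic_to_geometry(c(A, B, C, D, E, F))
}

conic_to_geometry <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) {
    abort("Fitted conic is not an ellipse.", class = "synaptrack_degenerate_fit")
  }
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  # centred quadratic form: (x - c)' M2 (x - c) = -F0
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  ev <- eigen(M2, symmetric = TRUE)
  lam <- ev$values # decreasing; must share the sign of -F0
  if (any(lam * -F0 <= 0)) {
    abort("Fitted conic is not an ellipse.", class = "synaptrack_degenerate_fit")
  }
  axes <- sqrt(-F0 / lam) # increasing axis with decreasing eigenvalue
  major <- which.max(axes)
  theta <- atan2(ev$vectors[2, major], ev$vectors[1, major])
  list(centre = c(x0, y0), semi_axes = sort(axes, decreasing = TRUE),
       rotation_deg = (theta * 180 / pi) %% 180)
}

#' Fit the cell boundary ellipse
#'
#' From boundary points: direct least-squares conic fit constrained to an
#' ellipse. From a filled binary mask: the exact equivalent ellipse from
#' the region's second moments (for a uniformly filled ellipse the
#' semi-axes are twice the principal standard deviations).
#'
#' @param boundary Either a data frame with columns `x`, `y` of boundary
#'   points, or a logical/0-1 matrix mask of the cell footprint.
#' @param centre_fraction Passed to [cell_geometry()].
#' @return A [cell_geometry()].
#' @export
fit_cell_geometry <- function(boundary, centre_fraction = 0.5) {
  if (is.matrix(boundary)) {
    idx <- which(boundary > 0, arr.ind = TRUE)
    if (nrow(idx) < 5L) {
      abort("Mask too small to fit an ellipse.",
            class = "synaptrack_degenerate_fit")
    }
    x <- idx[, 2]; y <- idx[, 1]
    ctr <- c(mean(x), mean(y))
    cv <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
    cv <- cv + diag(2) / 12 # pixel-area correction (uniform within pixel)
    ev <- eigen(cv, symmetric = TRUE)
    axes <- 2 * sqrt(ev$values)
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    g <- list(centre = ctr, semi_axes = axes,
              rotation_deg = (theta * 180 / pi) %% 180)
  } else {
    g <- fit_ellipse_conic(boundary$x, boundary$y)
  }
  cell_geometry(g$centre, g$semi_axes, g$rotation_deg, centre_fraction)
}

# Uniform random points inside the boundary ellipse; optionally
# restricted to one region.
sample_in_cell <- function(n, geometry, region = c("any", "centre", "periphery")) {
  region <- match.arg(region)
  lo <- switch(region, any = 0, centre = 0, periphery = geometry$centre_fraction)
  hi <- switch(region, any = 1, centre = geometry$centre_fraction, periphery = 1)
  # area-uniform radius within the annulus [lo, hi], uniform angle in the
  # unit-disc frame, then map through the ellipse
  r <- sqrt(runif(n, lo^2, hi^2))
  phi <- runif(n, 0, 2 * pi)
  ux <- r * cos(phi) * geometry$semi_axes[1]
  uy <- r * sin(phi) * geometry$semi_axes[2]
  th <- geometry$rotation_deg * pi / 180
  tibble(
    x = geometry$centre[1] + cos(th) * ux - sin(th) * uy,
    y = geometry$centre[2] + sin(th) * ux + cos(th) * uy)
}

# Outward radial unit vector(s) from the cell centre at points (x, y);
# the default microtubule plus-end direction field.
radial_direction <- function(geometry, x, y) {
  dx <- x - geometry$centre[1]
  dy <- y - geometry$centre[2]
  nrm <- sqrt(dx^2 + dy^2)
  bad <- nrm < 1e-12
  cbind(ux = ifelse(bad, NA_real_, dx / nrm),
        uy = ifelse(bad, NA_real_, dy / nrm))
}
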