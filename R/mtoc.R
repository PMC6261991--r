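# MTOC repositioning quantification: refraction-corrected axial
# distance (perpendicular direction) and centre/periphery centring
# fraction (parallel direction), plus plain two-sample comparison
# utilities.

#' Refractive-index model for axial distance correction
#'
#' The apparent focal shift read off the mechanical z-stage
#' overestimates the true axial distance in an aqueous specimen imaged
#' through glass/oil; the corrected distance is
#' `z = z0 * n_specimen / n_glass`. Defaults: cytoplasm 1.37, BK7
#' glass/immersion oil 1.52.
#'
#' @param n_specimen Specimen refractive index (> 1).
#' @param n_glass Coverslip/immersion refractive index (> 1).
#' @return A `refraction_model` list.
#' @export
refraction_model <- function(n_specimen = 1.37, n_glass = 1.52) {
  if (n_specimen <= 1 || n_glass <= 1) {
    abort("Refractive indices must exceed 1.",
          class = "synaptrack_bad_argument")
  }
  structure(list(n_specimen = n_specimen, n_glass = n_glass),
            class = "refraction_model")
}

#' Refraction-corrected axial distance
#'
#' @param z0_um Mechanical z-stage shift(s) in um (>= 0) between the
#'   contact-surface focus and the MTOC focus.
#' @param model A [refraction_model()].
#' @return Corrected distance(s) `z = z0 * n_specimen / n_glass` in um.
#' @export
correct_axial_distance <- function(z0_um, model = refraction_model()) {
  if (any(z0_um < 0)) {
    abort("Mechanical shifts must be non-negative.",
          class = "synaptrack_bad_argument")
  }
  z0_um * model$n_specimen / model$n_glass
}

#' MTOC centring fraction with Wilson confidence interval
#'
#' The fraction of cells whose MTOC lies in the centre region (inside
#' the half-diameter ellipse); under uniform placement this converges
#' to 0.25, the area ratio of the centre ellipse.
#'
#' @param measurements Data frame with a `region` column
#'   (`"centre"`/`"periphery"`; `NA` rows are excluded) and optionally a
#'   `condition` column to stratify by.
#' @return Tibble per condition: `n`, `n_centre`, `fraction`,
#'   `ci_lower`, `ci_upper` (Wilson 95%).
#' @export
centring_fraction <- function(measurements) {
  m <- filter(as_tibble(measurements), !is.na(.data$region))
  if (!nrow(m)) {
    abort("No cells with a region classification.",
          class = "synaptrack_empty_input")
  }
  if (!"condition" %in% names(m)) m$condition <- "all"
  m |>
    group_by(.data$condition) |>
    summarise(
      n = dplyr::n(),
      n_centre = sum(.data$region == "centre"),
      .groups = "drop") |>
    mutate(
      fraction = .data$n_centre / .data$n,
      ci_lower = purrr::map2_dbl(.data$n_centre, .data$n,
                                 ~ wilson_ci(.x, .y)["lower"]),
      ci_upper = purrr::map2_dbl(.data$n_centre, .data$n,
                                 ~ wilson_ci(.x, .y)["upper"]))
}

#' Compare two conditions (descriptive utility)
#'
#' Two-proportion test for centring fractions (`prop.test`), Welch two-
#' sample t-test for distance lists. The original analyses report
#' p-values without naming tests, so these are plain utilities, not a
#' reproduction of those values.
#'
#' @param x,y For `type = "fraction"`: integer vectors `c(successes,
#'   n)`. For `type = "distance"`: numeric samples.
#' @param type `"fraction"` or `"distance"`.
#' @return Tibble: `difference`, `statistic`, `p_value`, `method`.
#' @export
compare_conditions <- function(x, y, type = c("fraction", "distance")) {
  type <- match.arg(type)
  if (type == "fraction") {
    if (x[2] < 1 || y[2] < 1) {
      abort("Empty sample.", class = "synaptrack_empty_input")
    }
    tst <- suppressWarnings(prop.test(c(x[1], y[1]), c(x[2], y[2])))
    tibble(difference = x[1] / x[2] - y[1] / y[2],
           statistic = unname(tst$statistic),
           p_value = tst$p.value,
           method = "two-proportion chi-squared (continuity corrected)")
  } else {
    if (!length(x) || !length(y)) {
      abort("Empty sample.", class = "synaptrack_empty_input")
    }
    if (sd(c(x, y)) == 0) {
      # identical constant samples: no evidence of difference
      return(tibble(difference = mean(x) - mean(y), statistic = 0,
                    p_value = 1, method = "Welch two-sample t-test"))
    }
    tst <- t.test(x, y)
    tibble(difference = mean(x) - mean(y),
           statistic = unname(tst$statistic),
           p_value = tst$p.value,
           method = "Welch two-sample t-test")
  }
}

#' Assemble an MTOC measurement table
#'
#' Applies the refraction correction and the centre/periphery rule to
#' per-cell mechanical shifts and lateral positions.
#'
#' @param cells Data frame with `cell_id`, `z0_um`, `x`, `y` and
#'   optionally `condition`.
#' @param geometry A [cell_geometry()] (shared) — or supply a
#'   `geometry` list-column of per-cell geometries.
#' @param model A [refraction_model()].
#' @return The input with `z_um` and `region` columns added.
#' @export
mtoc_measurements <- function(cells, geometry, model = refraction_model()) {
  cells <- as_tibble(cells)
  cells$z_um <- correct_axial_distance(cells$z0_um, model)
  if ("geometry" %in% names(cells)) {
    cells$region <- purrr::map2_chr(
      seq_len(nrow(cells)), cells$geometry,
      function(i, g) {
        suppressWarnings(
          classify_region(cells[i, c("x", "y")], g)$region)
      })
  } else {
    cells <- suppressWarnings(classify_region(cells, geometry))
  }
  cells
}
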