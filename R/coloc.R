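# Dual-colour track colocalisation: two clusters from different
# channels count as colocalised when they stay within a distance gate
# and share the same movement category for not less than three
# consecutive frames. Fractions are normalised so the grand total over
# both regions is 100%.

# Longest run of TRUE in a logical vector.
longest_run <- function(ok) {
  if (!length(ok) || !any(ok)) return(0L)
  r <- rle(ok)
  max(r$lengths[r$values])
}

#' Match classified tracks across the two registered channels
#'
#' A pair of tracks (one per channel) is colocalised iff there exist at
#' least `min_frames` consecutive frames on which both exist, their
#' centroid distance is at most `distance_gate_px`, and their motion
#' classes are identical. Pairing is one-to-one, closest mean distance
#' first; unpaired tracks become non-colocalised records.
#'
#' @param tracks_a,tracks_b Detection tibbles with `track_id`, `frame`,
#'   `x`, `y` ([link_tracks()] output) for channels A and B. Channel B
#'   must already be registered onto A (apply the channel transform to
#'   the movie before detection); if the B movie carried no registration
#'   provenance a warning is emitted by [run_pipeline()], not here.
#' @param classes_a,classes_b Track summaries with `track_id`,
#'   `motion_class`, `region` ([classify_motion()] output).
#' @param distance_gate_px Colocalisation distance gate (default 2 px,
#'   about 160 nm).
#' @param min_frames Minimum consecutive overlap (default 3 frames).
#' @return Tibble of colocalisation records: `track_id_a`, `track_id_b`
#'   (`NA` when unpaired), `colocalised`, `overlap_frames` (longest
#'   qualifying run), `motion_class`, `region`, `channel` (for
#'   non-colocalised records, which channel the track came from).
#' @export
match_tracks <- function(tracks_a, tracks_b, classes_a, classes_b,
                         distance_gate_px = 2, min_frames = 3) {
  cand <- list()
  ids_a <- unique(tracks_a$track_id)
  ids_b <- unique(tracks_b$track_id)
  ta <- split(tracks_a, tracks_a$track_id)
  tb <- split(tracks_b, tracks_b$track_id)
  cls_a <- setNames(classes_a$motion_class, classes_a$track_id)
  cls_b <- setNames(classes_b$motion_class, classes_b$track_id)
  for (ia in ids_a) {
    a <- ta[[as.character(ia)]]
    for (ib in ids_b) {
      if (is.na(cls_a[as.character(ia)]) || is.na(cls_b[as.character(ib)]) ||
          cls_a[as.character(ia)] != cls_b[as.character(ib)]) next
      b <- tb[[as.character(ib)]]
      common <- intersect(a$frame, b$frame)
      if (length(common) < min_frames) next
      common <- sort(common)
      pa <- a[match(common, a$frame), ]
      pb <- b[match(common, b$frame), ]
      d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
      # qualifying runs must be over consecutive frames within the gate
      consec <- c(TRUE, diff(common) == 1)
      ok <- d <= distance_gate_px
      grp <- cumsum(!consec)
      run <- max(vapply(split(ok, grp), longest_run, integer(1)))
      if (run >= min_frames) {
        cand[[length(cand) + 1L]] <- tibble(
          track_id_a = ia, track_id_b = ib,
          overlap_frames = run, mean_dist = mean(d[ok]))
      }
    }
  }
  cand <- purrr::list_rbind(cand)
  pairs <- NULL
  if (!is.null(cand) && nrow(cand)) {
    cand <- arrange(cand, .data$mean_dist)
    used_a <- used_b <- character()
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!(cand$track_id_a[i] %in% used_a) &&
          !(cand$track_id_b[i] %in% used_b)) {
        keep[i] <- TRUE
        used_a <- c(used_a, cand$track_id_a[i])
        used_b <- c(used_b, cand$track_id_b[i])
      }
    }
    pairs <- cand[keep, ]
  }
  reg_a <- setNames(classes_a$region, classes_a$track_id)
  reg_b <- setNames(classes_b$region, classes_b$track_id)
  rec <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    rec[[1]] <- tibble(
      track_id_a = pairs$track_id_a, track_id_b = pairs$track_id_b,
      colocalised = TRUE, overlap_frames = pairs$overlap_frames,
      motion_class = unname(cls_a[as.character(pairs$track_id_a)]),
      region = unname(reg_a[as.character(pairs$track_id_a)]),
      channel = NA_character_)
  }
  solo_a <- setdiff(ids_a, if (is.null(pairs)) integer() else pairs$track_id_a)
  solo_b <- setdiff(ids_b, if (is.null(pairs)) integer() else pairs$track_id_b)
  if (length(solo_a)) {
    rec[[length(rec) + 1L]] <- tibble(
      track_id_a = solo_a, track_id_b = NA_integer_, colocalised = FALSE,
      overlap_frames = 0L,
      motion_class = unname(cls_a[as.character(solo_a)]),
      region = unname(reg_a[as.character(solo_a)]), channel = "A")
  }
  if (length(solo_b)) {
    rec[[length(rec) + 1L]] <- tibble(
      track_id_a = NA_integer_, track_id_b = solo_b, colocalised = FALSE,
      overlap_frames = 0L,
      motion_class = unname(cls_b[as.character(solo_b)]),
      region = unname(reg_b[as.character(solo_b)]), channel = "B")
  }
  out <- purrr::list_rbind(rec)
  if (is.null(out) || !nrow(out)) {
    out <- tibble(track_id_a = integer(), track_id_b = integer(),
                  colocalised = logical(), overlap_frames = integer(),
                  motion_class = character(), region = character(),
                  channel = character())
  }
  out
}

#' Region x motion x colocalisation fraction table
#'
#' Each cell is the percentage of all records in one (region, status,
#' motion class) combination, where status is colocalised,
#' non-colocalised channel A, or non-colocalised channel B; the grand
#' total over both regions is 100% by construction.
#'
#' @param records [match_tracks()] output.
#' @param min_records Warn (`synaptrack_min_n`) below this count; the
#'   analysis convention is a minimum of 100 cluster sets from five
#'   cells.
#' @return A `fraction_table` tibble: `region`, `status`,
#'   `motion_class`, `n`, `fraction_pct`, with the record total as an
#'   attribute.
#' @export
build_fraction_table <- function(records, min_records = 100) {
  records <- filter(as_tibble(records), !is.na(.data$region),
                    !is.na(.data$motion_class))
  if (!nrow(records)) {
    abort("No records to tabulate.", class = "synaptrack_empty_input")
  }
  if (nrow(records) < min_records) {
    warn(sprintf("Only %d cluster records (< %d minimum).",
                 nrow(records), min_records),
         class = "synaptrack_min_n")
  }
  records <- mutate(records, status = dplyr::case_when(
    .data$colocalised ~ "colocalised",
    .data$channel == "A" ~ "non_colocalised_A",
    TRUE ~ "non_colocalised_B"))
  grid <- tidyr::expand_grid(
    region = c("centre", "periphery"),
    status = c("colocalised", "non_colocalised_A", "non_colocalised_B"),
    motion_class = c("plus", "minus", "immobile"))
  tab <- records |>
    count(.data$region, .data$status, .data$motion_class) |>
    dplyr::right_join(grid, by = c("region", "status", "motion_class")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           fraction_pct = 100 * .data$n / nrow(records)) |>
    arrange(.data$region, .data$status, .data$motion_class)
  structure(tab, n_records = nrow(records),
            class = c("fraction_table", class(tab)))
}

#' Per-group velocity summary of colocalisation records
#'
#' @param records [match_tracks()] output.
#' @param summaries_a,summaries_b [classify_motion()] outputs carrying
#'   `speed_um_per_s` per track.
#' @param by Grouping columns among `colocalised`, `motion_class`,
#'   `region` (default all three).
#' @return Tibble with group columns, `n`, `mean_um_per_s`,
#'   `sd_um_per_s`, `mean_um_per_min`, `sd_um_per_min`. Velocities of a
#'   colocalised pair use the mean of the two channel estimates.
#' @export
velocity_summary <- function(records, summaries_a, summaries_b,
                             by = c("colocalised", "motion_class", "region")) {
  sp_a <- setNames(summaries_a$speed_um_per_s, summaries_a$track_id)
  sp_b <- setNames(summaries_b$speed_um_per_s, summaries_b$track_id)
  recs <- records |>
    mutate(speed_um_per_s = rowMeans(cbind(
      sp_a[as.character(.data$track_id_a)],
      sp_b[as.character(.data$track_id_b)]), na.rm = TRUE)) |>
    filter(is.finite(.data$speed_um_per_s))
  out <- recs |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(n = dplyr::n(),
              mean_um_per_s = mean(.data$speed_um_per_s),
              sd_um_per_s = ifelse(dplyr::n() > 1, sd(.data$speed_um_per_s), 0),
              .groups = "drop") |>
    mutate(mean_um_per_min = um_per_s_to_um_per_min(.data$mean_um_per_s),
           sd_um_per_min = um_per_s_to_um_per_min(.data$sd_um_per_s))
  out
}

#' Per-group lifetime summary
#'
#' @inheritParams velocity_summary
#' @return Tibble with group columns, `n`, `mean_lifetime_s` (inclusive
#'   convention: `n_detections * frame_interval`).
#' @export
lifetime_summary <- function(records, summaries_a, summaries_b,
                             by = c("colocalised", "motion_class", "region")) {
  lt_a <- setNames(summaries_a$lifetime_s, summaries_a$track_id)
  lt_b <- setNames(summaries_b$lifetime_s, summaries_b$track_id)
  records |>
    mutate(lifetime_s = rowMeans(cbind(
      lt_a[as.character(.data$track_id_a)],
      lt_b[as.character(.data$track_id_b)]), na.rm = TRUE)) |>
    filter(is.finite(.data$lifetime_s)) |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(n = dplyr::n(),
              mean_lifetime_s = mean(.data$lifetime_s), .groups = "drop")
}
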