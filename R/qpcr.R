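# Comparative-CT relative expression with triplicate handling and
# reference-gene normalisation, plus a matching synthetic CT-table
# generator. Amplification efficiency is fixed at 2 (the comparative-CT
# assumption); replicates are averaged at the CT level.

#' Simulate a qPCR CT table with known fold changes
#'
#' One calibrator condition (fold 1) plus one condition per entry of
#' `true_fold_changes`; `n_samples` biological samples per condition,
#' each with `n_replicates` technical replicates of the target and the
#' reference gene. Expected delta-delta-CT of a condition with fold `f`
#' is `-log2(f)`.
#'
#' @param n_samples Samples per condition.
#' @param true_fold_changes Named (or unnamed) positive fold changes
#'   relative to the calibrator.
#' @param ct_noise_sd Per-well CT noise sd (cycles).
#' @param n_replicates Technical replicates per (sample, gene); default
#'   3 (triplicate).
#' @param calibrator Name of the calibrator condition.
#' @param base_ct_reference,base_ct_target Mean CT of the reference gene
#'   and of the target in the calibrator.
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `condition`, `gene`
#'   (`"target"`/`"reference"`), `replicate`, `ct`.
#' @export
sim_qpcr_table <- function(n_samples, true_fold_changes, ct_noise_sd = 0.1,
                           n_replicates = 3, calibrator = "calibrator",
                           base_ct_reference = 17, base_ct_target = 24,
                           seed = NULL) {
  if (any(true_fold_changes <= 0)) {
    abort("Fold changes must be positive.", class = "synaptrack_bad_argument")
  }
  if (is.null(names(true_fold_changes))) {
    names(true_fold_changes) <- paste0("condition_",
                                       seq_along(true_fold_changes))
  }
  folds <- c(setNames(1, calibrator), true_fold_changes)
  with_seed_maybe(seed, {
    purrr::imap(folds, function(f, cond) {
      purrr::map(seq_len(n_samples), function(i) {
        tibble(
          sample_id = sprintf("%s_s%02d", cond, i),
          condition = cond,
          gene = rep(c("target", "reference"), each = n_replicates),
          replicate = rep(seq_len(n_replicates), 2),
          ct = c(base_ct_target - log2(f) +
                   rnorm(n_replicates, sd = ct_noise_sd),
                 base_ct_reference + rnorm(n_replicates, sd = ct_noise_sd)))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
}

#' Comparative-CT relative expression
#'
#' Per sample: `dCT = mean CT(target) - mean CT(reference)`;
#' `ddCT = dCT - mean dCT(calibrator samples)`; fold change
#' `2^(-ddCT)`. The calibrator's mean fold is 1 by construction when
#' noise is absent.
#'
#' @param table CT tibble with columns `sample_id`, `condition`, `gene`,
#'   `ct` (see [sim_qpcr_table()]).
#' @param calibrator Calibrator condition name (must be present).
#' @param target_gene,reference_gene Gene labels in `gene`.
#' @return Per-sample tibble: `sample_id`, `condition`, `dct`, `ddct`,
#'   `fold_change`.
#' @export
relative_expression <- function(table, calibrator,
                                target_gene = "target",
                                reference_gene = "reference") {
  table <- as_tibble(table)
  if (!calibrator %in% table$condition) {
    abort("Calibrator condition not present in the table.",
          class = "synaptrack_missing_calibrator")
  }
  if (!all(c(target_gene, reference_gene) %in% table$gene)) {
    abort("Target or reference gene missing from the table.",
          class = "synaptrack_missing_gene")
  }
  per_sample <- table |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    group_by(.data$sample_id, .data$condition, .data$gene) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct")
  if (anyNA(per_sample[[target_gene]]) || anyNA(per_sample[[reference_gene]])) {
    abort("Every sample needs both target and reference CT values.",
          class = "synaptrack_missing_gene")
  }
  per_sample <- mutate(per_sample,
                       dct = .data[[target_gene]] - .data[[reference_gene]])
  cal_dct <- mean(per_sample$dct[per_sample$condition == calibrator])
  per_sample |>
    mutate(ddct = .data$dct - cal_dct,
           fold_change = 2^(-.data$ddct)) |>
    select("sample_id", "condition", "dct", "ddct", "fold_change")
}
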