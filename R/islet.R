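# Normal-islet matrisome definition and relative-abundance ranking.

#' Derive per-protein detection records from protein-level quants
#'
#' Collapses a (protein, replicate) quant table into one row per protein with
#' the set of replicates the protein was detected in and its unique-peptide
#' count per replicate.
#'
#' @param quants Protein quant tibble from [rollup_protein_ratios()].
#' @return A tibble with `protein_id`, `gene_symbol`, `detected_in`
#'   (comma-separated replicate ids), `n_replicates`, `n_peptides_A`,
#'   `n_peptides_B` (0 when not detected).
#' @export
detection_records <- function(quants) {
  quants |>
    dplyr::group_by(.data$protein_id, .data$gene_symbol) |>
    dplyr::summarise(
      detected_in = paste(sort(unique(.data$replicate_id)), collapse = ","),
      n_replicates = dplyr::n_distinct(.data$replicate_id),
      n_peptides_A = sum(.data$n_unique_peptides[.data$replicate_id == "A"]),
      n_peptides_B = sum(.data$n_unique_peptides[.data$replicate_id == "B"]),
      .groups = "drop")
}

#' Define the normal-tissue matrisome membership set
#'
#' A protein belongs to the tissue matrisome when it was detected in both
#' biological replicates (no peptide threshold), or in only one replicate but
#' with at least two unique peptides in that replicate.
#'
#' @param records Detection records from [detection_records()].
#' @param min_unique_peptides Peptide threshold for single-replicate proteins
#'   (default 2).
#' @return `records` filtered to members, with a `membership_rule` column
#'   (`both_replicates` or `single_replicate_2_peptides`).
#' @export
define_islet_matrisome <- function(records, min_unique_peptides = 2) {
  both <- records$n_replicates == 2
  single_ok <- records$n_replicates == 1 &
    pmax(records$n_peptides_A, records$n_peptides_B) >= min_unique_peptides
  out <- records[both | single_ok, , drop = FALSE]
  out$membership_rule <- ifelse(out$n_replicates == 2, "both_replicates",
                                "single_replicate_2_peptides")
  out
}

#' Rank proteins by precursor-weighted reference-channel abundance
#'
#' Computes, for each member protein, the precursor-ion-weighted average
#' normalized reference-channel (117, normal tissue) reporter intensity:
#' within each replicate, every PSM's 117 intensity is first divided by the
#' median 117 intensity across all PSMs of that replicate (channel-level
#' location normalization, so the two replicates are comparable), then
#' averaged over the protein's PSMs with precursor-ion intensities as
#' weights. Proteins present in both replicates average the two replicate
#' values with equal weight. Ranks are assigned by descending weighted
#' intensity; ties are broken by gene symbol, lexicographically, for
#' determinism.
#'
#' @param psms Filtered PSM tibble (all PSMs of the experiment; the
#'   per-replicate normalizing median is computed across all of them).
#' @param members Optional character vector of member `protein_id`s (e.g.
#'   from [define_islet_matrisome()]); `NULL` ranks every protein present.
#' @param normal_channel Reporter channel of the normal-tissue sample
#'   (default `"117"`).
#' @return A tibble `rank`, `protein_id`, `gene_symbol`,
#'   `weighted_intensity`, sorted by rank.
#' @export
rank_abundance <- function(psms, members = NULL, normal_channel = REFERENCE_CHANNEL) {
  validate_psm_table(psms)
  col <- paste0("rep_", normal_channel)
  psms$norm_ref <- psms[[col]]
  for (rep_id in unique(psms$replicate_id)) {
    in_rep <- psms$replicate_id == rep_id
    med <- stats::median(psms[[col]][in_rep])
    if (!is.finite(med) || med <= 0) {
      stop("median ", normal_channel, " intensity in replicate ", rep_id,
           " is not positive; cannot normalize")
    }
    psms$norm_ref[in_rep] <- psms[[col]][in_rep] / med
  }
  if (!is.null(members)) {
    psms <- psms[psms$protein_id %in% members, , drop = FALSE]
    missing <- setdiff(members, psms$protein_id)
    if (length(missing)) {
      warning(length(missing), " member protein(s) had no PSMs and were not ranked")
    }
  }
  per_rep <- psms |>
    dplyr::group_by(.data$protein_id, .data$gene_symbol, .data$replicate_id) |>
    dplyr::summarise(
      wsum = sum(.data$precursor_intensity),
      value = if (sum(.data$precursor_intensity) > 0) {
        sum(.data$precursor_intensity * .data$norm_ref) / sum(.data$precursor_intensity)
      } else NA_real_,
      unweighted = mean(.data$norm_ref),
      .groups = "drop")
  if (any(is.na(per_rep$value))) {
    warning(sum(is.na(per_rep$value)), " protein-replicate group(s) with ",
            "all-zero precursor intensities; using the unweighted mean")
    per_rep$value[is.na(per_rep$value)] <- per_rep$unweighted[is.na(per_rep$value)]
  }
  ranked <- per_rep |>
    dplyr::group_by(.data$protein_id, .data$gene_symbol) |>
    dplyr::summarise(weighted_intensity = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$weighted_intensity), .data$gene_symbol,
                   .data$protein_id)
  ranked$rank <- seq_len(nrow(ranked))
  ranked[c("rank", "protein_id", "gene_symbol", "weighted_intensity")]
}
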