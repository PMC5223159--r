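PSM_COLUMNS <- c("protein_id", "gene_symbol", "peptide_seq",
                 "rep_114", "rep_115", "rep_116", "rep_117",
                 "precursor_intensity", "precursor_purity_pct",
                 "delta_fwd_rev", "has_itraq_label", "replicate_id")

#' Read a PSM table
#'
#' Reads the tab-separated peptide-spectrum-match dialect used throughout the
#' pipeline: one row per PSM with protein and gene identifiers, the peptide
#' sequence, the four reporter-ion intensities (channels 114-117), the
#' precursor-ion intensity, the precursor-isolation purity in percent, the
#' delta forward-reverse identification score, a 0/1 iTRAQ-label flag and the
#' replicate identifier.
#'
#' @param path Path to a TSV file (UTF-8, no quoting).
#' @return A tibble with one row per PSM; `has_itraq_label` is logical.
#' @export
read_psm_table <- function(path) {
  psms <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", gene_symbol = "c", peptide_seq = "c",
    rep_114 = "d", rep_115 = "d", rep_116 = "d", rep_117 = "d",
    precursor_intensity = "d", precursor_purity_pct = "d",
    delta_fwd_rev = "d", has_itraq_label = "i", replicate_id = "c"),
    progress = FALSE)
  psms$has_itraq_label <- psms$has_itraq_label != 0L
  validate_psm_table(psms)
  psms
}

#' Write a PSM table
#'
#' @param psms A PSM tibble (see [read_psm_table()] for the schema).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  out <- psms[PSM_COLUMNS]
  out$has_itraq_label <- as.integer(out$has_itraq_label)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_psm_table <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing)) {
    stop("PSM table is missing columns: ", paste(missing, collapse = ", "))
  }
  intens <- as.matrix(psms[c("rep_114", "rep_115", "rep_116", "rep_117",
                             "precursor_intensity")])
  if (any(intens < 0, na.rm = TRUE)) stop("reporter/precursor intensities must be >= 0")
  purity <- psms$precursor_purity_pct
  if (any(purity < 0 | purity > 100, na.rm = TRUE)) {
    stop("precursor_purity_pct must lie in [0, 100]")
  }
  if (!all(psms$replicate_id %in% REPLICATES)) {
    stop("replicate_id must be one of ", paste(REPLICATES, collapse = ", "))
  }
  invisible(TRUE)
}

#' Filter PSMs by quantitation-quality rules
#'
#' Excludes PSMs lacking an iTRAQ label, PSMs with a negative delta
#' forward-reverse score (estimated false-positive identifications), and PSMs
#' whose precursor-isolation purity is below the threshold (co-isolation
#' interference). Only strictly negative delta scores and strictly sub-threshold
#' purities are excluded; boundary values are kept. Row order is preserved and
#' the input is not modified.
#'
#' @param psms A PSM tibble.
#' @param purity_threshold_pct Minimum precursor purity in percent (default 50).
#' @return The surviving PSMs, with an `attrition` attribute tabulating how
#'   many rows each rule removed (rules applied jointly; a PSM failing several
#'   rules is counted once per rule).
#' @export
filter_psms <- function(psms, purity_threshold_pct = 50) {
  validate_psm_table(psms)
  unlabeled <- !psms$has_itraq_label
  neg_delta <- psms$delta_fwd_rev < 0
  low_purity <- psms$precursor_purity_pct < purity_threshold_pct
  keep <- !(unlabeled | neg_delta | low_purity)
  out <- psms[keep, , drop = FALSE]
  attr(out, "attrition") <- tibble::tibble(
    rule = c("no_itraq_label", "negative_delta_score", "low_precursor_purity",
             "total_removed", "kept"),
    n = c(sum(unlabeled), sum(neg_delta), sum(low_purity),
          sum(!keep), sum(keep)))
  out
}

#' Roll PSM-level iTRAQ ratios up to protein-level log2 ratios
#'
#' For each protein and replicate, the per-channel PSM ratio is the reporter
#' intensity divided by the reference-channel intensity, and the protein-level
#' iTRAQ ratio is the median of all contributing PSM ratios (midpoint of the
#' two central ratios for even counts), reported on the log2 scale. PSMs with
#' zero reference-channel intensity have undefined ratios and are dropped with
#' a warning rather than imputed.
#'
#' @param psms A filtered PSM tibble.
#' @param reference_channel Reporter channel used as denominator
#'   (default `"117"`, the wild-type reference).
#' @return A tibble with one row per (protein, replicate): `protein_id`,
#'   `gene_symbol`, `replicate_id`, `log2_T6`, `log2_T9`, `log2_T12`,
#'   `n_psms`, `n_unique_peptides`.
#' @export
rollup_protein_ratios <- function(psms, reference_channel = REFERENCE_CHANNEL) {
  validate_psm_table(psms)
  ref_col <- paste0("rep_", reference_channel)
  ref <- psms[[ref_col]]
  bad <- !is.finite(ref) | ref <= 0
  if (any(bad)) {
    warning(sum(bad), " PSM(s) dropped: zero or missing reference-channel (",
            reference_channel, ") intensity leaves the ratio undefined")
    psms <- psms[!bad, , drop = FALSE]
    ref <- ref[!bad]
  }
  if (nrow(psms) == 0) {
    return(tibble::tibble(protein_id = character(), gene_symbol = character(),
                          replicate_id = character(), log2_T6 = double(),
                          log2_T9 = double(), log2_T12 = double(),
                          n_psms = integer(), n_unique_peptides = integer()))
  }
  for (tp in TIMEPOINTS) {
    psms[[paste0("ratio_", tp)]] <-
      psms[[paste0("rep_", TIMEPOINT_CHANNELS[[tp]])]] / ref
  }
  out <- psms |>
    dplyr::group_by(.data$protein_id, .data$gene_symbol, .data$replicate_id) |>
    dplyr::summarise(
      log2_T6 = log2(stats::median(.data$ratio_T6)),
      log2_T9 = log2(stats::median(.data$ratio_T9)),
      log2_T12 = log2(stats::median(.data$ratio_T12)),
      n_psms = dplyr::n(),
      n_unique_peptides = dplyr::n_distinct(.data$peptide_seq),
      .groups = "drop") |>
    dplyr::arrange(.data$protein_id, .data$replicate_id)
  stopifnot(all(out$n_unique_peptides <= out$n_psms), all(out$n_psms >= 1L))
  out
}

#' Normalize protein-level ratios by the matrisome-protein median
#'
#' For each replicate and each time-point channel, the normalization offset is
#' the median log2 ratio over matrisome proteins only (division not
#' `non_matrisome`); that offset is subtracted from every protein's ratio in
#' the channel, matrisome or not. This accounts for differences in total
#' protein amount and in the extent of ECM enrichment between the four
#' co-labeled samples; after normalization the matrisome-protein median is
#' exactly zero in every channel.
#'
#' @param quants Protein-level quant tibble from [rollup_protein_ratios()].
#' @param annotation Annotation tibble with `gene_symbol` and `division`
#'   (e.g. from [annotate_matrisome()] on `quants$gene_symbol`), or `NULL` to
#'   annotate against the bundled reference.
#' @return The quant tibble with normalized `log2_*` columns and a
#'   `norm_offsets` attribute: a tibble of the subtracted offset per
#'   (replicate, timepoint).
#' @export
normalize_by_matrisome_median <- function(quants, annotation = NULL) {
  if (is.null(annotation)) {
    annotation <- annotate_matrisome(quants$gene_symbol)
  }
  division <- annotation$division[match(tolower(trimws(quants$gene_symbol)),
                                        tolower(trimws(annotation$gene_symbol)))]
  is_matrisome <- !is.na(division) & division != "non_matrisome"
  offsets <- list()
  out <- quants
  for (rep_id in unique(quants$replicate_id)) {
    in_rep <- quants$replicate_id == rep_id
    mat_rows <- in_rep & is_matrisome
    if (!any(mat_rows)) {
      stop("no matrisome proteins in replicate ", rep_id,
           "; the matrisome-median offset is undefined")
    }
    for (tp in TIMEPOINTS) {
      col <- paste0("log2_", tp)
      off <- stats::median(quants[[col]][mat_rows])
      out[[col]][in_rep] <- quants[[col]][in_rep] - off
      offsets[[length(offsets) + 1L]] <-
        tibble::tibble(replicate_id = rep_id, timepoint = tp, offset = off)
    }
  }
  attr(out, "norm_offsets") <- dplyr::bind_rows(offsets)
  out
}
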