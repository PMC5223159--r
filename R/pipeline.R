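# End-to-end orchestration: PSM tables in, result tables out.

#' Run the full matrisome quantitation pipeline
#'
#' Executes annotation, PSM filtering, protein-level ratio rollup,
#' matrisome-median normalization, the moderated F-test with
#' Benjamini-Hochberg adjustment and direction calls, heatmap column
#' clustering, tissue-matrisome membership, precursor-weighted abundance
#' ranking and a composition summary. When `output_dir` is given, every
#' result table is written as TSV along with a JSON run manifest recording
#' the configuration, filter attrition and input checksums.
#'
#' @param psms A PSM tibble (both replicates), or a character vector of PSM
#'   TSV paths (one or more, e.g. one file per replicate) read with
#'   [read_psm_table()].
#' @param reference Matrisome reference tibble or CSV path; defaults to the
#'   bundled reference.
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @param reference_channel Denominator reporter channel (default `"117"`).
#' @param purity_threshold_pct Precursor-purity threshold (default 50).
#' @param alpha Nominal significance threshold (default 0.05).
#' @param minkowski_p Minkowski exponent for column clustering (default 2).
#' @return Invisibly, a list with `quant_raw`, `quant_normalized`,
#'   `norm_offsets`, `ratio_matrix`, `differential`, `cluster_order`,
#'   `membership`, `ranking`, `composition`, `attrition` and `manifest`.
#' @export
run_pipeline <- function(psms, reference = NULL, output_dir = NULL,
                         reference_channel = REFERENCE_CHANNEL,
                         purity_threshold_pct = 50, alpha = 0.05,
                         minkowski_p = 2) {
  input_files <- NULL
  if (is.character(psms)) {
    input_files <- psms
    psms <- dplyr::bind_rows(lapply(psms, read_psm_table))
  }
  validate_psm_table(psms)
  if (is.null(reference)) {
    reference <- matrisome_reference()
  } else if (is.character(reference)) {
    reference <- matrisome_reference(reference)
  }

  filtered <- filter_psms(psms, purity_threshold_pct = purity_threshold_pct)
  attrition <- attr(filtered, "attrition")
  if (nrow(filtered) == 0) stop("no PSMs survive filtering")

  quant_raw <- rollup_protein_ratios(filtered, reference_channel = reference_channel)
  annotation <- annotate_matrisome(quant_raw$gene_symbol, reference = reference)
  quant_norm <- normalize_by_matrisome_median(quant_raw, annotation = annotation)
  offsets <- attr(quant_norm, "norm_offsets")

  ratio_matrix <- build_ratio_matrix(quant_norm, annotation = annotation,
                                     matrisome_only = TRUE)
  differential <- differential_from_ratios(ratio_matrix, alpha = alpha)

  # heatmap columns: per-time-point means of normalized ratios, significant
  # proteins only (the figure the clustering orders)
  sig <- differential[differential$direction %in% c("higher", "lower"), ]
  heat <- as.matrix(sig[paste0("mean_log2_", TIMEPOINTS)])
  colnames(heat) <- TIMEPOINTS
  cluster_order <- if (nrow(heat) >= 1) {
    TIMEPOINTS[as.integer(cluster_columns(heat, minkowski_p = minkowski_p))]
  } else TIMEPOINTS

  # membership is defined over ECM / ECM-associated proteins only
  records <- detection_records(quant_raw)
  rec_annot <- annotate_matrisome(records$gene_symbol, reference = reference)
  membership <- define_islet_matrisome(records[rec_annot$division != "non_matrisome", ,
                                               drop = FALSE])
  ranking <- rank_abundance(filtered, members = membership$protein_id,
                            normal_channel = reference_channel)
  rank_annot <- annotate_matrisome(ranking$gene_symbol, reference = reference)
  ranking$division <- rank_annot$division
  ranking$category <- rank_annot$category

  # composition of the both-replicate (tested) protein set, one entry per
  # protein record
  comp_annot <- annotate_matrisome(ratio_matrix$gene_symbol, reference = reference)
  composition <- summarize_composition(comp_annot)

  results <- list(quant_raw = quant_raw, quant_normalized = quant_norm,
                  norm_offsets = offsets, ratio_matrix = ratio_matrix,
                  differential = differential, cluster_order = cluster_order,
                  membership = membership, ranking = ranking,
                  composition = composition, attrition = attrition)

  results$manifest <- list(
    package_version = as.character(utils::packageVersion("matriquant")),
    config = list(reference_channel = reference_channel,
                  purity_threshold_pct = purity_threshold_pct,
                  alpha = alpha, minkowski_p = minkowski_p),
    input_files = if (!is.null(input_files)) {
      lapply(input_files, function(f) list(path = f,
                                           md5 = unname(tools::md5sum(f))))
    },
    attrition = stats::setNames(as.list(attrition$n), attrition$rule),
    prior = attr(results$differential, "prior"),
    row_counts = lapply(results[c("quant_raw", "ratio_matrix", "differential",
                                  "membership", "ranking")], nrow),
    n_significant = sum(results$differential$direction != "not_significant"),
    n_higher = sum(results$differential$direction == "higher"),
    n_lower = sum(results$differential$direction == "lower"))

  if (!is.null(output_dir)) {
    write_pipeline_results(results, output_dir)
  }
  invisible(results)
}

#' Write pipeline result tables
#'
#' @param results List from [run_pipeline()].
#' @param output_dir Output directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_results <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(output_dir, name)
  readr::write_tsv(results$quant_raw, out("protein_quant_raw.tsv"), progress = FALSE)
  readr::write_tsv(results$quant_normalized, out("protein_quant_normalized.tsv"),
                   progress = FALSE)
  readr::write_tsv(results$norm_offsets, out("norm_offsets.tsv"), progress = FALSE)
  diff_cols <- intersect(c("protein_id", "gene_symbol", "mean_log2_T6",
                           "mean_log2_T9", "mean_log2_T12", "s2", "s2_post",
                           "f_mod", "p_value", "fdr", "direction"),
                         names(results$differential))
  readr::write_tsv(results$differential[diff_cols],
                   out("differential_results.tsv"), progress = FALSE)
  writeLines(results$cluster_order, out("cluster_order.txt"))
  readr::write_tsv(results$membership, out("matrisome_membership.tsv"),
                   progress = FALSE)
  readr::write_tsv(results$ranking, out("abundance_ranking.tsv"), progress = FALSE)
  readr::write_tsv(results$composition, out("composition_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(results$attrition, out("filter_attrition.tsv"), progress = FALSE)
  jsonlite::write_json(results$manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(output_dir)
}

#' Clustered heatmap of significant-protein log2 ratios
#'
#' Draws the progression heatmap: significant proteins in rows, time points
#' in columns (ordered by [cluster_columns()] with complete linkage and
#' Minkowski distance), cell values the across-replicate mean normalized
#' log2 ratios. Requires the pheatmap package.
#'
#' @param differential Differential result tibble from [run_pipeline()] or
#'   [differential_from_ratios()].
#' @param filename Optional output file (png/pdf); `NULL` draws to the
#'   active device.
#' @param minkowski_p Minkowski exponent for the column clustering.
#' @return The pheatmap object, invisibly.
#' @export
plot_ratio_heatmap <- function(differential, filename = NULL, minkowski_p = 2) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_ratio_heatmap() requires the pheatmap package")
  }
  sig <- differential[differential$direction %in% c("higher", "lower"), ]
  if (nrow(sig) == 0) stop("no significant proteins to draw")
  mat <- as.matrix(sig[paste0("mean_log2_", TIMEPOINTS)])
  colnames(mat) <- TIMEPOINTS
  rownames(mat) <- if ("gene_symbol" %in% names(sig)) sig$gene_symbol else sig$protein_id
  ord <- as.integer(cluster_columns(mat, minkowski_p = minkowski_p))
  args <- list(mat = mat[, ord, drop = FALSE], cluster_cols = FALSE,
               cluster_rows = TRUE, silent = !is.null(filename))
  if (!is.null(filename)) args$filename <- filename
  invisible(do.call(pheatmap::pheatmap, args))
}
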