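#' @importFrom rlang .data
NULL

# controlled vocabularies for matrisome annotation
MATRISOME_DIVISIONS <- c("core_matrisome", "matrisome_associated", "non_matrisome")
CORE_CATEGORIES <- c("ecm_glycoprotein", "collagen", "proteoglycan")
ASSOCIATED_CATEGORIES <- c("ecm_affiliated", "ecm_regulator", "secreted_factor")
MATRISOME_CATEGORIES <- c(CORE_CATEGORIES, ASSOCIATED_CATEGORIES, "none")

#' Load the bundled matrisome reference table
#'
#' The reference maps canonical mouse gene symbols to a matrisome division
#' (core matrisome vs matrisome-associated) and one of six categories: ECM
#' glycoproteins, collagens and proteoglycans make up the core matrisome;
#' ECM-affiliated proteins, ECM regulators and secreted factors are
#' matrisome-associated. Symbols absent from the table are treated as
#' non-matrisome by [annotate_matrisome()].
#'
#' @param path Optional path to a CSV with columns
#'   `gene_symbol,division,category`; defaults to the reference shipped with
#'   the package.
#' @return A tibble with columns `gene_symbol`, `division`, `category`.
#' @export
matrisome_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "matrisome_reference.csv",
                        package = "matriquant", mustWork = TRUE)
  }
  ref <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("gene_symbol", "division", "category")
  if (!all(required %in% names(ref))) {
    stop("matrisome reference must have columns ", paste(required, collapse = ", "))
  }
  validate_matrisome_entries(ref$division, ref$category)
  tibble::as_tibble(ref[required])
}

# division <-> category consistency shared by the reference loader and annotate()
validate_matrisome_entries <- function(division, category) {
  if (!all(division %in% MATRISOME_DIVISIONS)) {
    stop("unknown matrisome division: ",
         paste(unique(setdiff(division, MATRISOME_DIVISIONS)), collapse = ", "))
  }
  if (!all(category %in% MATRISOME_CATEGORIES)) {
    stop("unknown matrisome category: ",
         paste(unique(setdiff(category, MATRISOME_CATEGORIES)), collapse = ", "))
  }
  ok <- (division == "core_matrisome" & category %in% CORE_CATEGORIES) |
    (division == "matrisome_associated" & category %in% ASSOCIATED_CATEGORIES) |
    (division == "non_matrisome" & category == "none")
  if (!all(ok)) {
    stop("division/category mismatch for ", sum(!ok), " entries")
  }
  invisible(TRUE)
}

#' Annotate gene symbols against the matrisome reference
#'
#' Matching is case-insensitive with surrounding whitespace stripped; no
#' alias or ortholog resolution is attempted. Symbols not present in the
#' reference are returned as `non_matrisome` / `none`.
#'
#' @param gene_symbols Character vector of gene symbols (one per protein
#'   entry; repeated symbols for distinct isoform entries are allowed and
#'   annotated independently).
#' @param reference A reference tibble from [matrisome_reference()].
#' @return A tibble with one row per input symbol: `gene_symbol` (as given),
#'   `division`, `category`.
#' @export
annotate_matrisome <- function(gene_symbols, reference = matrisome_reference()) {
  if (length(gene_symbols) == 0) {
    return(tibble::tibble(gene_symbol = character(), division = character(),
                          category = character()))
  }
  gene_symbols <- as.character(gene_symbols)
  cleaned <- trimws(gene_symbols)
  if (any(is.na(cleaned)) || any(!nzchar(cleaned))) {
    stop("gene symbols must be non-empty strings")
  }
  idx <- match(tolower(cleaned), tolower(trimws(reference$gene_symbol)))
  division <- ifelse(is.na(idx), "non_matrisome", reference$division[idx])
  category <- ifelse(is.na(idx), "none", reference$category[idx])
  tibble::tibble(gene_symbol = gene_symbols, division = division,
                 category = category)
}

#' Summarize the matrisome composition of a protein set
#'
#' Counts each entry exactly once into its category and totals the core and
#' matrisome-associated divisions. Entries are countable records: a protein
#' list may legitimately contain repeated gene symbols for distinct isoform
#' entries, and each is counted.
#'
#' @param annotated A tibble with a `category` column (and optionally
#'   `division`), e.g. the output of [annotate_matrisome()].
#' @return A one-row tibble with one count column per category plus
#'   `total_core`, `total_associated` and `total`.
#' @export
summarize_composition <- function(annotated) {
  category <- annotated$category
  if (!all(category %in% MATRISOME_CATEGORIES)) {
    stop("unknown category in input")
  }
  counts <- vapply(MATRISOME_CATEGORIES, function(k) sum(category == k), integer(1))
  out <- tibble::as_tibble(as.list(counts))
  out$total_core <- sum(counts[CORE_CATEGORIES])
  out$total_associated <- sum(counts[ASSOCIATED_CATEGORIES])
  out$total <- length(category)
  stopifnot(out$total == out$total_core + out$total_associated + counts[["none"]])
  out
}

#' The published 120-entry quantified ECM protein list
#'
#' Returns the bundled fixture of the 120 ECM and ECM-associated protein
#' entries quantified in both biological replicates of the insulinoma
#' progression experiment, with their printed matrisome categories. Isoform
#' entries sharing a gene symbol (e.g. Fbn1, Anxa6) appear as distinct rows,
#' keyed by `entry_id`.
#'
#' @return A 120-row tibble with columns `entry_id`, `gene_symbol`,
#'   `category` and the derived `division`.
#' @export
table1_entries <- function() {
  path <- system.file("extdata", "table1_entries.csv",
                      package = "matriquant", mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  tab$division <- ifelse(tab$category %in% CORE_CATEGORIES, "core_matrisome",
                         "matrisome_associated")
  validate_matrisome_entries(tab$division, tab$category)
  tibble::as_tibble(tab)
}
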