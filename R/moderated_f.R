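# Empirical-Bayes moderated F-test for non-zero log-ratios across time-point
# groups, with the protein-wise residual variance shrunk toward a prior
# estimated from all observed proteins.

RATIO_CELLS <- as.vector(outer(TIMEPOINTS, REPLICATES, paste, sep = "."))

#' Build the complete-case ratio matrix for statistical testing
#'
#' Pivots normalized protein-level log2 ratios into one row per protein with
#' six observation cells (3 time points x 2 replicates). Only proteins
#' quantified in both replicates (all six cells present) are retained --
#' the "quantified in both replicates" gate -- and by default only matrisome
#' proteins are tested.
#'
#' @param quants Normalized quant tibble (see
#'   [normalize_by_matrisome_median()]).
#' @param annotation Optional annotation tibble with `gene_symbol` and
#'   `division`; defaults to the bundled reference.
#' @param matrisome_only Keep only proteins with a matrisome annotation
#'   (default `TRUE`).
#' @return A tibble with `protein_id`, `gene_symbol` and columns `T6.A`,
#'   `T6.B`, `T9.A`, `T9.B`, `T12.A`, `T12.B`.
#' @export
build_ratio_matrix <- function(quants, annotation = NULL, matrisome_only = TRUE) {
  if (is.null(annotation)) {
    annotation <- annotate_matrisome(quants$gene_symbol)
  }
  if (matrisome_only) {
    division <- annotation$division[match(tolower(trimws(quants$gene_symbol)),
                                          tolower(trimws(annotation$gene_symbol)))]
    quants <- quants[!is.na(division) & division != "non_matrisome", , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    quants[c("protein_id", "gene_symbol", "replicate_id",
             paste0("log2_", TIMEPOINTS))],
    cols = dplyr::starts_with("log2_"),
    names_to = "timepoint", names_prefix = "log2_", values_to = "log2_ratio")
  long$cell <- paste(long$timepoint, long$replicate_id, sep = ".")
  wide <- tidyr::pivot_wider(long[c("protein_id", "gene_symbol", "cell", "log2_ratio")],
                             names_from = "cell", values_from = "log2_ratio")
  for (cell in setdiff(RATIO_CELLS, names(wide))) wide[[cell]] <- NA_real_
  wide <- wide[c("protein_id", "gene_symbol", RATIO_CELLS)]
  complete <- stats::complete.cases(wide[RATIO_CELLS])
  if (any(!complete)) {
    warning(sum(!complete), " protein(s) excluded from testing: not quantified ",
            "in both replicates at every time point")
  }
  wide[complete, , drop = FALSE]
}

# Inverse of the trigamma function by monotone root-finding (trigamma is
# strictly decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, is.finite(y), y > 0)
  lo <- 1e-8
  hi <- 1e8
  if (y >= trigamma(lo)) return(lo)
  if (y <= trigamma(hi)) return(hi)
  root <- stats::uniroot(function(lx) trigamma(exp(lx)) - y,
                         lower = log(lo), upper = log(hi), tol = 1e-12)
  exp(root$root)
}

#' Estimate the variance-shrinkage prior from all proteins
#'
#' Fits the prior degrees of freedom `d0` and prior variance `s0_sq` of a
#' scaled inverse-chi-squared variance prior by moment-matching the
#' log-variances: with `z_g = log(s2_g)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, `d0` solves
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the empirical
#' spread of log-variances does not exceed its sampling expectation the
#' target is non-positive and the prior degenerates to `d0 = Inf` with
#' `s0_sq = exp(mean(e))` (complete shrinkage).
#'
#' @param s2 Protein-wise residual variances.
#' @param df Residual degrees of freedom per protein (recycled if scalar).
#' @return A list with `d0` (positive, possibly `Inf`) and `s0_sq`.
#' @export
fit_shrinkage_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  if (all(s2 <= 0)) stop("all residual variances are zero; prior is degenerate")
  use <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(use) < 2) stop("need at least two proteins with positive variance")
  s2 <- s2[use]
  df <- df[use]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  target <- mean((e - emean)^2 * n / (n - 1) - trigamma(df / 2))
  if (target <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(target)
  list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated F-test for non-zero group means
#'
#' Tests, for each protein, the null hypothesis that all three time-point
#' mean log2 ratios are zero, using the posterior variance
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)` in place of the protein-wise
#' residual variance. The statistic
#' `F = (sum_j n_j * mean_j^2 / k) / s2_post` is referred to an F distribution
#' with `(k, d0 + df)` degrees of freedom; when `d0 = Inf` the reference is
#' `chi^2_k / k`, and `d0 = 0` recovers the classical F-test. The F-shaped
#' test captures trends that are not unidirectional.
#'
#' @param ratios Output of [build_ratio_matrix()] (or any tibble/data.frame
#'   with `protein_id` and the six `T*.A`/`T*.B` cells; a numeric matrix with
#'   such column names is also accepted).
#' @param prior A list with `d0` and `s0_sq`, e.g. from
#'   [fit_shrinkage_prior()]; `NULL` (default) estimates the prior from these
#'   proteins.
#' @return A tibble with per-protein group means (`mean_log2_T6/T9/T12`),
#'   `s2`, `df_resid`, `s2_post`, `f_mod` and `p_value`.
#' @export
moderated_f_test <- function(ratios, prior = NULL) {
  if (is.matrix(ratios)) {
    ratios <- tibble::as_tibble(ratios, .name_repair = "minimal")
    if (!"protein_id" %in% names(ratios)) {
      ratios$protein_id <- sprintf("prot_%04d", seq_len(nrow(ratios)))
    }
  }
  stopifnot(all(RATIO_CELLS %in% names(ratios)))
  y <- as.matrix(ratios[RATIO_CELLS])
  if (anyNA(y)) stop("ratio matrix must be complete-case; filter first")
  k <- length(TIMEPOINTS)
  n_rep <- length(REPLICATES)
  group <- sub("\\..*$", "", RATIO_CELLS)
  means <- sapply(TIMEPOINTS, function(tp) {
    rowMeans(y[, group == tp, drop = FALSE])
  })
  means <- matrix(means, nrow = nrow(y),
                  dimnames = list(NULL, TIMEPOINTS))
  fitted <- means[, group, drop = FALSE]
  df_resid <- ncol(y) - k
  s2 <- rowSums((y - fitted)^2) / df_resid
  if (is.null(prior)) prior <- fit_shrinkage_prior(s2, df_resid)
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  }
  num <- rowSums(n_rep * means^2) / k
  f_mod <- ifelse(num == 0, 0, num / s2_post)
  if (is.infinite(d0)) {
    p <- stats::pchisq(k * f_mod, df = k, lower.tail = FALSE)
  } else {
    p <- stats::pf(f_mod, df1 = k, df2 = d0 + df_resid, lower.tail = FALSE)
  }
  out <- tibble::tibble(
    protein_id = ratios$protein_id,
    mean_log2_T6 = means[, "T6"],
    mean_log2_T9 = means[, "T9"],
    mean_log2_T12 = means[, "T12"],
    s2 = s2, df_resid = df_resid, s2_post = s2_post,
    f_mod = f_mod, p_value = pmin(p, 1))
  if ("gene_symbol" %in% names(ratios)) {
    out <- tibble::add_column(out, gene_symbol = ratios$gene_symbol,
                              .after = "protein_id")
  }
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Returns step-up adjusted values `q_(i) = min_{j >= i} n * p_(j) / j`,
#' capped at 1, in the input order (ties stable).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call abundance directions for significant proteins
#'
#' Proteins with `p_value < alpha` are called `higher` when the average of the
#' three time-point means is positive and `lower` when negative; all others
#' are `not_significant`. A significant protein whose group-mean average is
#' exactly zero cannot be assigned a direction and is flagged `ambiguous`
#' with a warning.
#'
#' @param results Tibble from [moderated_f_test()], with `fdr` added or not.
#' @param alpha Nominal significance threshold in (0, 1); default 0.05.
#' @return `results` with a `direction` column.
#' @export
call_directions <- function(results, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  avg <- rowMeans(results[paste0("mean_log2_", TIMEPOINTS)])
  sig <- results$p_value < alpha
  direction <- rep("not_significant", nrow(results))
  direction[sig & avg > 0] <- "higher"
  direction[sig & avg < 0] <- "lower"
  ambiguous <- sig & avg == 0
  if (any(ambiguous)) {
    warning(sum(ambiguous), " significant protein(s) with group-mean average ",
            "exactly 0 flagged ambiguous")
    direction[ambiguous] <- "ambiguous"
  }
  results$direction <- direction
  results
}

#' Full differential chain on a normalized ratio table
#'
#' Convenience wrapper running prior estimation, the moderated F-test,
#' Benjamini-Hochberg adjustment and direction calling on any complete-case
#' table of normalized protein-level log2 ratios -- e.g. the matrix built by
#' [build_ratio_matrix()], a simulated matrix, or published protein-level
#' ratio tables.
#'
#' @inheritParams moderated_f_test
#' @inheritParams call_directions
#' @return Result tibble with `fdr` and `direction` columns.
#' @export
differential_from_ratios <- function(ratios, alpha = 0.05, prior = NULL) {
  results <- moderated_f_test(ratios, prior = prior)
  results$fdr <- bh_fdr(results$p_value)
  call_directions(results, alpha = alpha)
}

#' Hierarchically cluster heatmap columns
#'
#' Agglomerative clustering of the columns of a proteins x conditions log2
#' ratio matrix with complete linkage and Minkowski distance, as used to order
#' the time-point columns of the progression heatmap. Leaf order is
#' deterministic: at every merge the subtree containing the smaller original
#' column index is placed on the left.
#'
#' @param mat Numeric matrix (proteins in rows, conditions in columns), no
#'   missing values.
#' @param minkowski_p Minkowski exponent (default 2, i.e. Euclidean).
#' @return Integer vector of column indices in dendrogram leaf order, with the
#'   `hclust` object as attribute `"hclust"`. A single column returns the
#'   identity ordering.
#' @export
cluster_columns <- function(mat, minkowski_p = 2) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must not contain missing values")
  if (ncol(mat) == 1) return(1L)
  d <- stats::dist(t(mat), method = "minkowski", p = minkowski_p)
  hc <- stats::hclust(d, method = "complete")
  merge <- hc$merge
  min_leaf <- numeric(nrow(merge))
  orders <- vector("list", nrow(merge))
  node <- function(i) {
    if (i < 0) list(min = -i, ord = -i) else list(min = min_leaf[i], ord = orders[[i]])
  }
  for (r in seq_len(nrow(merge))) {
    a <- node(merge[r, 1])
    b <- node(merge[r, 2])
    ord <- if (a$min <= b$min) c(a$ord, b$ord) else c(b$ord, a$ord)
    min_leaf[r] <- min(a$min, b$min)
    orders[[r]] <- ord
  }
  out <- as.integer(orders[[nrow(merge)]])
  attr(out, "hclust") <- hc
  out
}
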