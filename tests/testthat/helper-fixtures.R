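# Small in-code PSM fixtures. make_psm() yields one schema-complete row with
# innocuous defaults; override only what a test cares about.

make_psm <- function(protein_id = "P1", gene_symbol = "Postn",
                     peptide_seq = "AEGILNPK", rep_114 = 100, rep_115 = 100,
                     rep_116 = 100, rep_117 = 100, precursor_intensity = 1e5,
                     precursor_purity_pct = 90, delta_fwd_rev = 5,
                     has_itraq_label = TRUE, replicate_id = "A") {
  tibble::tibble(protein_id = protein_id, gene_symbol = gene_symbol,
                 peptide_seq = peptide_seq, rep_114 = rep_114,
                 rep_115 = rep_115, rep_116 = rep_116, rep_117 = rep_117,
                 precursor_intensity = precursor_intensity,
                 precursor_purity_pct = precursor_purity_pct,
                 delta_fwd_rev = delta_fwd_rev,
                 has_itraq_label = has_itraq_label, replicate_id = replicate_id)
}

# PSMs for one protein/replicate with given T9 (115/117) ratios; other
# channels flat at the reference intensity
psms_with_t9_ratios <- function(ratios, protein_id = "P1",
                                gene_symbol = "Postn", replicate_id = "A") {
  dplyr::bind_rows(lapply(seq_along(ratios), function(i) {
    make_psm(protein_id = protein_id, gene_symbol = gene_symbol,
             peptide_seq = sprintf("PEP%02dK", i), rep_115 = 100 * ratios[i],
             replicate_id = replicate_id)
  }))
}

# a minimal two-replicate quant table covering both replicates for n proteins
make_quants <- function(symbols, log2_T6 = 0, log2_T9 = 0, log2_T12 = 0,
                        replicate_id = "A", n_psms = 3L,
                        n_unique_peptides = 2L) {
  tibble::tibble(protein_id = paste0("P_", symbols, "_", replicate_id),
                 gene_symbol = symbols, replicate_id = replicate_id,
                 log2_T6 = log2_T6, log2_T9 = log2_T9, log2_T12 = log2_T12,
                 n_psms = n_psms, n_unique_peptides = n_unique_peptides)
}

# classical one-way F-test of H0: all group means zero, via lm() with a
# no-intercept group design (independent route from the package's own code)
classical_f_oracle <- function(y, groups) {
  fit <- lm(y ~ 0 + factor(groups))
  fs <- summary(fit)$fstatistic
  list(f = unname(fs[1]),
       p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
}

# brute-force O(n^2) Benjamini-Hochberg step-up
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:n, function(j) n * p[ord[j]] / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}
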