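test_that("PSM filter applies the three exclusion rules with kept boundaries", {
  psms <- dplyr::bind_rows(
    make_psm(protein_id = "keep_clean"),
    make_psm(protein_id = "drop_purity", precursor_purity_pct = 49,
             delta_fwd_rev = 1),
    make_psm(protein_id = "keep_boundary", precursor_purity_pct = 50,
             delta_fwd_rev = 0),
    make_psm(protein_id = "drop_unlabeled", precursor_purity_pct = 90,
             delta_fwd_rev = 2, has_itraq_label = FALSE),
    make_psm(protein_id = "drop_delta", delta_fwd_rev = -0.01))
  kept <- filter_psms(psms)
  expect_setequal(kept$protein_id, c("keep_clean", "keep_boundary"))
  # order preserved, input untouched
  expect_equal(kept$protein_id, c("keep_clean", "keep_boundary"))
  expect_equal(nrow(psms), 5L)
  attrition <- attr(kept, "attrition")
  expect_equal(attrition$n[attrition$rule == "low_precursor_purity"], 1L)
  expect_equal(attrition$n[attrition$rule == "no_itraq_label"], 1L)
  expect_equal(attrition$n[attrition$rule == "negative_delta_score"], 1L)
  # idempotence on the retained rows (the audit attribute trivially resets)
  strip <- function(x) { attr(x, "attrition") <- NULL; x }
  expect_equal(strip(filter_psms(kept)), strip(kept))
})

test_that("protein rollup takes the median PSM ratio per channel on log2 scale", {
  # single PSM with power-of-two intensities
  one <- rollup_protein_ratios(make_psm(rep_116 = 200))
  expect_equal(one$log2_T6, 1)
  expect_equal(one$log2_T9, 0)
  expect_equal(one$log2_T12, 0)
  expect_equal(one$n_psms, 1L)

  # odd count: median of {2, 4, 8} is 4
  odd <- rollup_protein_ratios(psms_with_t9_ratios(c(2, 4, 8)))
  expect_equal(odd$log2_T9, 2)

  # even count: midpoint of the two central ratios, {1, 1, 2, 4} -> 1.5
  even <- rollup_protein_ratios(psms_with_t9_ratios(c(1, 1, 2, 4)))
  expect_equal(even$log2_T9, log2(1.5))
  expect_equal(even$log2_T9, 0.5849625, tolerance = 1e-7)

  # unique peptides counted by distinct sequence
  dup <- dplyr::bind_rows(make_psm(), make_psm(), make_psm(peptide_seq = "OTHERK"))
  expect_equal(rollup_protein_ratios(dup)$n_unique_peptides, 2L)
  expect_equal(rollup_protein_ratios(dup)$n_psms, 3L)
})

test_that("rollup is invariant to PSM order and matches brute-force medians", {
  withr::with_seed(21, {
    for (n in c(3, 4, 5)) {
      ratios <- round(runif(n, 0.2, 5), 3)
      base <- rollup_protein_ratios(psms_with_t9_ratios(ratios))
      for (k in 1:10) {
        perm <- sample(n)
        shuffled <- rollup_protein_ratios(psms_with_t9_ratios(ratios[perm]))
        expect_equal(shuffled$log2_T9, base$log2_T9)
      }
      # log2(median(r)) = median(log2(r)) by monotonicity -- exact for odd
      # counts; the even-count midpoint convention averages the two central
      # ratios before the log, so the identity becomes a bracketing bound
      if (n %% 2 == 1) {
        expect_equal(base$log2_T9, median(log2(ratios)))
      } else {
        central <- sort(log2(ratios))[c(n / 2, n / 2 + 1)]
        expect_gte(base$log2_T9, central[1])
        expect_lte(base$log2_T9, central[2])
      }
    }
  })
})

test_that("PSMs with zero reference intensity are dropped with a warning", {
  psms <- dplyr::bind_rows(make_psm(), make_psm(rep_117 = 0, rep_115 = 500))
  expect_warning(out <- rollup_protein_ratios(psms), "reference-channel")
  expect_equal(out$n_psms, 1L)
  expect_equal(out$log2_T9, 0)
  # a protein whose every PSM is undefined is absent from the output
  only_bad <- make_psm(protein_id = "gone", rep_117 = 0)
  expect_warning(out2 <- rollup_protein_ratios(only_bad))
  expect_equal(nrow(out2), 0L)
})

test_that("matrisome-median normalization centers matrisome proteins at zero", {
  # matrisome T9 ratios {1,2,3} plus a non-matrisome protein at 0:
  # offset 2 is subtracted everywhere, non-matrisome becomes -2
  quants <- make_quants(c("Postn", "Dcn", "Ctsl", "Zzznot"),
                        log2_T9 = c(1, 2, 3, 0))
  norm <- normalize_by_matrisome_median(quants)
  expect_equal(norm$log2_T9, c(-1, 0, 1, -2))
  offsets <- attr(norm, "norm_offsets")
  expect_equal(offsets$offset[offsets$timepoint == "T9"], 2)
  # zero-median channels are unchanged
  expect_equal(norm$log2_T6, quants$log2_T6)
  # matrisome median is exactly zero afterwards
  expect_equal(median(norm$log2_T9[1:3]), 0)
})

test_that("normalization is shift-invariant and idempotent", {
  withr::with_seed(8, {
    quants <- make_quants(c("Postn", "Dcn", "Ctsl", "Col1a1", "Lum", "Zzznot"),
                          log2_T6 = rnorm(6), log2_T9 = rnorm(6),
                          log2_T12 = rnorm(6))
    norm <- normalize_by_matrisome_median(quants)
    # adding a constant per channel changes nothing after normalization
    shifted <- quants
    shifted$log2_T6 <- shifted$log2_T6 + 3.7
    shifted$log2_T12 <- shifted$log2_T12 - 1.2
    norm_shifted <- normalize_by_matrisome_median(shifted)
    for (col in c("log2_T6", "log2_T9", "log2_T12")) {
      expect_equal(norm_shifted[[col]], norm[[col]])
    }
    # idempotence: re-normalizing yields zero offsets
    again <- normalize_by_matrisome_median(norm)
    expect_equal(attr(again, "norm_offsets")$offset, rep(0, 3))
  })
})

test_that("normalization fails when a replicate has no matrisome proteins", {
  quants <- dplyr::bind_rows(
    make_quants(c("Postn", "Dcn"), replicate_id = "A"),
    make_quants(c("Zzznot1", "Zzznot2"), replicate_id = "B"))
  expect_error(normalize_by_matrisome_median(quants), "replicate B")
})

test_that("PSM tables round-trip through the TSV dialect", {
  withr::with_seed(3, {
    sim <- simulate_experiment(sim_config(n_matrisome_proteins = 5,
                                          n_contaminant_proteins = 2,
                                          n_higher = 1, n_lower = 1, seed = 3))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_psm_table(sim$psms, path)
    back <- read_psm_table(path)
    expect_equal(as.data.frame(back), as.data.frame(sim$psms), tolerance = 1e-12)
  })
})
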