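#!/usr/bin/env Rscript
# Generate the synthetic two-replicate iTRAQ 4-plex experiment that stands in
# for the raw mass-spectrometry data: 120 matrisome proteins (35 with planted
# progression effects, 9 up / 26 down), 30 exocrine-like contaminants with a
# decreasing trend, 20-30% co-isolation compression.

library(matriquant)

seed <- 20170110L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_experiment(cfg)

for (rep_id in c("A", "B")) {
  path <- file.path(outdir, paste0("psms_rep", rep_id, ".tsv"))
  write_psm_table(sim$psms[sim$psms$replicate_id == rep_id, ], path)
  cat("replicate", rep_id, ":",
      sum(sim$psms$replicate_id == rep_id), "PSMs ->", path, "\n")
}
readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"), progress = FALSE)

cat("proteins:", nrow(sim$truth),
    "(matrisome:", sum(sim$truth$is_matrisome),
    ", planted:", sum(sim$truth$is_planted & sim$truth$is_matrisome),
    ", contaminants:", sum(sim$truth$is_contaminant), ")\n")
cat("unlabeled PSM fraction:", round(mean(!sim$psms$has_itraq_label), 4), "\n")
cat("negative-delta PSM fraction:",
    round(mean(sim$psms$delta_fwd_rev < 0), 4), "\n")
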