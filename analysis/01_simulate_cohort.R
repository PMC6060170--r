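#!/usr/bin/env Rscript
# Simulate the study's plasma sequencing inputs: a 20-sample reference panel
# of unaffected plasma profiles and a 10-sample case cohort (5 tumour-bearing
# at 15% tumour fraction with randomly placed CNAs, 5 CNA-free controls) on a
# two-chromosome 150-Mb toy genome gridded into 3000 50-kb bins. Writes
# per-sample bin-count TSVs plus ground-truth records under results/sim/.

suppressPackageStartupMessages(library(plasmaCNA))
seed <- 20260922L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- toy_genome(c(chr1 = 110e6, chr2 = 40e6))
grid <- annotate_bins_synthetic(make_bins(genome, 50000), seed = seed)
cfg <- sim_config(grid, mean_depth = 500, seed = seed)

panel <- simulate_panel(cfg, 20)
for (p in panel)
  write_bin_counts(file.path(out, paste0(p$sample_id, ".tsv")), grid, p)
message("panel: 20 samples at mean depth 500/bin, ",
        nrow(grid), " bins")

truths <- list()
for (k in 1:5) {
  ev <- random_cna_profile(genome, n_events = 1, size_range_mb = c(40, 100),
                           seed = seed + 10 * k, copy_states = 3L)
  truths[[k]] <- simulation_truth(sprintf("case_%02d", k), 0.15, ev,
                                  seed = seed + 100 + k)
}
for (k in 1:5) {
  truths[[5 + k]] <- simulation_truth(sprintf("ctrl_%02d", k), 0,
                                      cna_profile(NULL),
                                      seed = seed + 200 + k)
}
for (t in truths) {
  prof <- simulate_tumor_sample(cfg, t)
  write_bin_counts(file.path(out, paste0(t$sample_id, ".tsv")), grid, prof)
}
write_truth(file.path(out, "cohort"), truths)

# cohort metadata: cases advanced-stage, controls early-stage, with
# synthetic follow-up (cases progress sooner, the association the survival
# stage of the workflow is meant to expose)
set.seed(seed)
cohort <- data.frame(
  sample_id = vapply(truths, `[[`, "", "sample_id"),
  cancer_type = rep(c("ovarian", "endometrial"), 5),
  figo_stage = rep(c("IIIB", "IA"), each = 5),
  pfs_months = round(c(rexp(5, 1 / 8), rexp(5, 1 / 30)), 1),
  pfs_event = c(rbinom(5, 1, 0.9), rbinom(5, 1, 0.3)),
  os_months = round(c(rexp(5, 1 / 14), rexp(5, 1 / 45)), 1),
  os_event = c(rbinom(5, 1, 0.8), rbinom(5, 1, 0.2)))
write_cohort(file.path(out, "cohort_metadata.tsv"), cohort)

message("wrote ", length(truths), " case/control profiles, truth records ",
        "and cohort metadata to ", out)
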