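#!/usr/bin/env Rscript
# Run the full CNA-calling pipeline on the simulated cohort from
# 01_simulate_cohort.R: bin exclusion, LOESS GC adjustment, reference-panel
# fit with PCA smoothing, CBS, CADET classification with the published
# thresholds (|Z| >= 3.95, LOR > 0, BCL >= 0.99, alpha = 0.8, >10 Mb), and
# the cohort detection table. Outputs land in results/run/.

suppressPackageStartupMessages(library(plasmaCNA))
seed <- 20260922L
sim_dir <- "results/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate_cohort.R first")

genome <- toy_genome(c(chr1 = 110e6, chr2 = 40e6))
read_profiles <- function(pattern) {
  files <- sort(list.files(sim_dir, pattern = pattern, full.names = TRUE))
  lapply(files, function(f) read_bin_counts(f, genome))
}
panel_in <- read_profiles("^panel_.*\\.tsv$")
cases_in <- read_profiles("^(case|ctrl)_.*\\.tsv$")
grid <- panel_in[[1]]$grid
check_same_grid(lapply(c(panel_in, cases_in), `[[`, "grid"))

cohort <- read_cohort(file.path(sim_dir, "cohort_metadata.tsv"))

config <- pipeline_config(
  grid,
  panel = lapply(panel_in, `[[`, "profile"),
  samples = lapply(cases_in, `[[`, "profile"),
  cytobands = synthetic_cytobands(genome),
  cohort = cohort,
  out_dir = "results/run",
  seed = seed)
res <- suppressWarnings(run_pipeline(config))

message(sprintf("%d samples processed; %d with reported CNA > 10 Mb",
                length(res$reports),
                sum(vapply(res$reports, `[[`, TRUE, "cna_positive"))))
print(res$detection)
print(res$pooled)

# recovery against the simulated truth
truth <- read.delim(file.path(sim_dir, "cohort_truth.tsv"))
called <- vapply(res$reports, `[[`, TRUE, "cna_positive")
tab <- table(truth = truth$tumor_fraction > 0,
             called = called[truth$sample_id])
message("truth vs called:")
print(tab)
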