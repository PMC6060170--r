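#!/usr/bin/env Rscript
# Cohort-level reproduction and survival stratification.
#
# Part A re-derives the published detection table from the transcribed
# clinical cohort fixture: per cancer type and FIGO stage group (I-II early,
# III-IV advanced), patient counts, CNA detection rates, and the CNA-burden
# medians, plus the advanced-versus-early rate comparison.
#
# Part B runs Kaplan-Meier / log-rank stratification by CNA positivity on
# the simulated cohort's synthetic follow-up (per-patient survival was not
# published, so the clinical curves are not reproducible; the simulated
# cohort exercises the same machinery).

suppressPackageStartupMessages(library(plasmaCNA))
dir.create("results", showWarnings = FALSE)

## Part A: published-table arithmetic
coh <- read_cohort(system.file("extdata", "cohort_table1_transcribed.tsv",
                               package = "plasmaCNA"))
tab <- detection_table(coh)
pooled <- pooled_detection_rates(coh)
write.table(tab, "results/detection_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab)
print(pooled)

k_adv <- pooled$n_detected[pooled$group == "advanced"]
k_ear <- pooled$n_detected[pooled$group == "early"]
p_stage <- compare_rates(k_adv, 27, k_ear, 73)
endo <- tab[tab$cancer_type == "endometrial", ]
p_endo <- compare_rates(endo$n_detected[endo$stage_group == "advanced"], 12,
                        endo$n_detected[endo$stage_group == "early"], 41)
message(sprintf("advanced %.1f%% vs early %.1f%%: Fisher p = %.4f",
                pooled$rate_pct[pooled$group == "advanced"],
                pooled$rate_pct[pooled$group == "early"], p_stage))
message(sprintf("endometrial advanced vs early: Fisher p = %.4f", p_endo))
jsonlite::write_json(
  list(advanced_vs_early = list(p = p_stage),
       endometrial_advanced_vs_early = list(p = p_endo)),
  "results/rate_tests.json", auto_unbox = TRUE, digits = NA)

## Part B: survival stratified by CNA positivity (simulated follow-up)
run_dir <- "results/run"
sim_dir <- "results/sim"
if (file.exists(file.path(sim_dir, "cohort_metadata.tsv")) &&
    dir.exists(run_dir)) {
  meta <- read_cohort(file.path(sim_dir, "cohort_metadata.tsv"))
  reports <- lapply(meta$sample_id, function(s)
    jsonlite::read_json(file.path(run_dir, paste0(s, "_report.json")),
                        simplifyVector = TRUE))
  meta$cna_positive <- vapply(reports, `[[`, TRUE, "cna_positive")
  pos <- meta[meta$cna_positive, ]
  neg <- meta[!meta$cna_positive, ]
  for (endpoint in c("pfs", "os")) {
    tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
    lr <- logrank_test(pos[[tcol]], pos[[ecol]], neg[[tcol]], neg[[ecol]])
    message(sprintf("%s: log-rank chisq = %.2f, p = %.4f (CNA+ n=%d, CNA- n=%d)",
                    toupper(endpoint), lr$chisq, lr$p, nrow(pos), nrow(neg)))
    curves <- rbind(
      cbind(group = "CNA_positive", km_curve(pos[[tcol]], pos[[ecol]])),
      cbind(group = "CNA_negative", km_curve(neg[[tcol]], neg[[ecol]])))
    write.table(curves,
                sprintf("results/km_%s_by_cna.tsv", endpoint),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
} else {
  message("simulated cohort not found; run analysis/01 and 02 first ",
          "for the survival stratification")
}
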