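# Shared fixtures and a memoised store for expensive simulation products so
# independent test blocks can reuse one panel fit.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Two-chromosome toy genome, 3000 bins of 50 kb (150 Mb), the scale used by
# the stochastic end-to-end checks.
toy_study_genome <- function() toy_genome(c(chr1 = 110e6, chr2 = 40e6))

toy_study_grid <- function() {
  cache_get("study_grid", function() {
    annotate_bins_synthetic(make_bins(toy_study_genome(), 50000), seed = 1)
  })
}

# Study conditions: depth 500 per bin, panel of 20.
study_setup <- function(seed = 42) {
  cache_get(paste0("study_setup_", seed), function() {
    grid <- toy_study_grid()
    cfg <- sim_config(grid, mean_depth = 500, seed = seed)
    panel <- simulate_panel(cfg, 20)
    fitted <- fit_panel(panel, grid)
    list(cfg = cfg, panel = panel, grid = fitted$grid, ref = fitted$ref)
  })
}

# 100-Mb single-copy gain used by the spike-in checks.
study_spike_event <- function() {
  cna_profile(data.frame(chrom = "chr1", start = 5e6, end = 105e6,
                         copy_number = 3L), toy_study_genome())
}

# One processed spiked / null replicate against the shared panel.
study_replicate <- function(k, tumor_fraction, event = NULL, seed_base = 700) {
  st <- study_setup()
  profile <- if (is.null(event) || tumor_fraction == 0)
    simulate_tumor_sample(st$cfg, simulation_truth(
      paste0("s", k), 0, cna_profile(NULL), seed = seed_base + k))
  else
    simulate_tumor_sample(st$cfg, simulation_truth(
      paste0("s", k), tumor_fraction, event, seed = seed_base + k))
  suppressWarnings(process_sample(
    profile, st$ref, st$grid,
    cbs = cbs_params(seed = 5 + k),
    thresholds = cadet_thresholds(seed = 6 + k)))
}

# Reciprocal overlap of a called interval with a true event interval.
reciprocal_overlap <- function(call_start, call_end, true_start, true_end) {
  ov <- pmax(0, pmin(call_end, true_end) - pmax(call_start, true_start))
  pmin(ov / (true_end - true_start), ov / (call_end - call_start))
}

# Reference R implementation of the arc statistic, used as the brute-force
# oracle for the compiled scanner.
arc_stat_oracle <- function(x, mw = 3L) {
  n <- length(x)
  bi <- 0L; bj <- mw; bT <- -1
  for (i in 0:(n - mw)) {
    for (j in (i + mw):min(n, i + n - mw)) {
      inn <- x[(i + 1):j]
      out <- x[-((i + 1):j)]
      sp2 <- (sum((inn - mean(inn))^2) + sum((out - mean(out))^2)) / (n - 2)
      T <- if (sp2 <= 0) {
        d <- abs(mean(inn) - mean(out))
        if (d > 1e-9) 1e12 * d else 0
      } else {
        abs(mean(inn) - mean(out)) / sqrt(sp2 * (1 / length(inn) + 1 / length(out)))
      }
      if (T > bT + 1e-12) { bT <- T; bi <- i; bj <- j }
    }
  }
  list(i = bi, j = bj, T = max(bT, 0))
}

# Path to the transcribed clinical cohort fixture.
cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table1_transcribed.tsv", package = "plasmaCNA")
}
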