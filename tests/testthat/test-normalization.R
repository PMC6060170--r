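make_flat_panel <- function(grid, counts) {
  lapply(1:4, function(i) count_profile(paste0("p", i), counts, grid))
}

test_that("exclusion filter applies the three criteria", {
  grid <- make_bins(toy_genome(c(c1 = 25e6)), 50000)
  counts <- rep(100, nrow(grid))
  panel <- make_flat_panel(grid, counts)

  out <- exclusion_filter(panel, grid)
  expect_equal(sum(out$excluded), 0)

  grid2 <- grid
  grid2$mappability[7] <- 0
  out2 <- exclusion_filter(panel, grid2)
  expect_true(out2$excluded[7])
  expect_equal(attr(out2, "exclusion_counts")[["low_mappability"]], 1)

  grid3 <- grid
  grid3$repeat_frac[9] <- 0.9
  expect_true(exclusion_filter(panel, grid3)$excluded[9])

  # a bin with 10x inflated cross-panel variance trips the quantile rule
  set.seed(2)
  cfg <- sim_config(grid, mean_depth = 500, gc_curvature = 0,
                    artifact_scales = numeric(), seed = 2)
  sim <- simulate_panel(cfg, 20)
  j <- 123
  for (s in seq_along(sim))
    sim[[s]]$counts[j] <- round(500 + rnorm(1, 0, sqrt(10 * 1500)))
  out4 <- exclusion_filter(sim, grid)
  expect_true(out4$excluded[j])

  grid5 <- grid
  grid5$mappability[] <- 0
  expect_error(exclusion_filter(panel, grid5), "every bin")
})

test_that("LOESS GC adjustment inverts a known smooth bias", {
  grid <- toy_study_grid()
  # counts = 1000 * g(gc), zero noise: adjusted counts become constant
  g_of <- function(gc) 1 - 2.5 * (gc - 0.4)^2
  counts <- 1000 * g_of(grid$gc)
  prof <- count_profile("clean", counts, grid)
  np <- loess_gc_adjust(prof, grid)
  use <- which(!grid$excluded & grid$autosomal)
  rel <- np$adjusted_counts[use] / median(np$adjusted_counts[use])
  expect_lt(max(abs(rel - 1)), 0.01)

  # no GC dependence: the adjustment moves nothing by more than 2%
  set.seed(31)
  prof2 <- count_profile("flat", rpois(nrow(grid), 1000), grid)
  np2 <- loess_gc_adjust(prof2, grid)
  expect_lt(max(abs(np2$adjusted_counts[use] / prof2$counts[use] - 1)), 0.02)

  # median preservation identity, by construction
  fitted_factor <- np2$adjusted_counts / prof2$counts
  expect_equal(median(np2$adjusted_counts[use]),
               median(prof2$counts[use] * fitted_factor[use]))

  # degenerate GC range falls back to identity with a warning
  grid_c <- grid
  grid_c$gc <- 0.5
  expect_warning(np3 <- loess_gc_adjust(prof2, grid_c), "degenerate")
  expect_identical(np3$adjusted_counts, prof2$counts)
})

test_that("reference panel stores robust per-bin summaries and orthonormal PCs", {
  st <- study_setup()
  ref <- st$ref
  expect_equal(ref$panel_size, 20)
  expect_true(all(ref$bin_mad >= 0))
  R <- ref$rotation
  expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-8)
  expect_lt(ref$K, ref$panel_size)

  # identical panel: degenerate, PCA declines with a warning
  grid <- make_bins(toy_genome(c(c1 = 10e6)), 50000)
  flat <- suppressWarnings(lapply(make_flat_panel(grid, rep(100, nrow(grid))),
                                  loess_gc_adjust, grid = grid))
  expect_warning(refd <- fit_reference_panel(flat, grid, K = 2),
                 "zero variance")
  expect_equal(refd$K, 0)
  expect_true(all(refd$bin_mad == 0))

  expect_error(fit_reference_panel(flat, grid, K = 10), "panel size")
})

test_that("PCA smoothing removes planted artefacts but passes CNA signal", {
  grid <- make_bins(toy_genome(c(c1 = 50e6)), 50000)
  cfg <- sim_config(grid, mean_depth = 2000, gc_curvature = 0,
                    artifact_scales = c(0.3, 0.2), dispersion = 0, seed = 21)
  panel <- simulate_panel(cfg, 20)
  fp <- fit_panel(panel, grid, K = 2)

  # held-out samples from the same artefact subspace: smoothing removes
  # most of the variance the artefacts put in
  fresh <- lapply(31:34, function(s)
    plasmaCNA:::simulate_sample_core(cfg, cfg$seed + 100 + s,
                                     sample_id = paste0("f", s)))
  ratio <- vapply(fresh, function(p) {
    np <- loess_gc_adjust(p, fp$grid)
    frac <- np$adjusted_counts / sum(np$adjusted_counts[!fp$grid$excluded])
    pre <- log2(frac[fp$ref$mask] / fp$ref$bin_median[fp$ref$mask])
    post <- pca_smooth(np, fp$ref, fp$grid)$values
    var(post[!is.na(post)]) / var(pre)
  }, 0)
  expect_true(all(ratio <= 0.25))

  # a profile equal to the panel median maps to all-zero values
  np_med <- structure(
    list(sample_id = "median", batch_id = NULL,
         adjusted_counts = fp$ref$bin_median * 1e6,
         values = rep(NA_real_, nrow(grid)),
         mask = !fp$grid$excluded, grid_hash = grid_hash(fp$grid)),
    class = "normalized_profile")
  sm <- pca_smooth(np_med, fp$ref, fp$grid)
  expect_lt(max(abs(sm$values), na.rm = TRUE), 1e-8)

  # median plus a multiple of component 1 is annihilated by the projection
  v1 <- rep(0, nrow(grid))
  v1[fp$ref$mask] <- fp$ref$rotation[, 1]
  np_c1 <- np_med
  np_c1$adjusted_counts <- fp$ref$bin_median * 2^(0.3 * v1) * 1e6
  sm1 <- pca_smooth(np_c1, fp$ref, fp$grid)
  expect_lt(max(abs(sm1$values), na.rm = TRUE), 1e-3)
})

test_that("a spiked copy-3 segment survives smoothing near log2(1.10)", {
  st <- study_setup()
  ev <- cna_profile(data.frame(chrom = "chr2", start = 5e6, end = 35e6,
                               copy_number = 3L), toy_study_genome())
  tr <- simulation_truth("spike", 0.2, ev, seed = 321)
  prof <- simulate_tumor_sample(st$cfg, tr)
  np <- pca_smooth(loess_gc_adjust(prof, st$grid), st$ref, st$grid)
  rows <- which(st$grid$chrom == "chr2" & st$grid$start >= 5e6 &
                  st$grid$end <= 35e6 & !is.na(np$values))
  rest <- setdiff(which(!is.na(np$values)), rows)
  # the single-copy-gain step over the diploid background survives the
  # normalization stack (the absolute level is median-centered, so the
  # contrast is the robust quantity)
  step <- mean(np$values[rows]) - mean(np$values[rest])
  expect_lt(abs(step - log2(1.10)), 0.2 * log2(1.10))
})

test_that("null samples normalize to flat, uncorrelated values", {
  st <- study_setup()
  meds <- acs <- numeric(3)
  for (k in 1:3) {
    prof <- simulate_tumor_sample(st$cfg, simulation_truth(
      paste0("n", k), 0, cna_profile(NULL), seed = 4000 + k))
    np <- pca_smooth(loess_gc_adjust(prof, st$grid), st$ref, st$grid)
    v <- np$values[!is.na(np$values)]
    meds[k] <- median(v)
    acs[k] <- cor(v[-1], v[-length(v)])
  }
  expect_true(all(abs(meds) < 0.01))
  expect_true(all(acs < 0.1))

  # determinism: identical inputs give identical outputs
  prof <- simulate_tumor_sample(st$cfg, simulation_truth(
    "n1", 0, cna_profile(NULL), seed = 4001))
  np_a <- pca_smooth(loess_gc_adjust(prof, st$grid), st$ref, st$grid)
  np_b <- pca_smooth(loess_gc_adjust(prof, st$grid), st$ref, st$grid)
  expect_identical(np_a$values, np_b$values)
})

test_that("reference panels serialize to a single archive and refuse foreign grids", {
  st <- study_setup()
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_panel(path, st$ref)
  back <- read_reference_panel(path, st$grid)
  expect_equal(back$bin_median, st$ref$bin_median, ignore_attr = TRUE)
  expect_equal(back$rotation, st$ref$rotation, ignore_attr = TRUE)
  expect_equal(dim(back$fractions), dim(st$ref$fractions))
  other <- make_bins(toy_genome(c(c9 = 10e6)), 50000)
  expect_error(read_reference_panel(path, other), "different bin grid")
})
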