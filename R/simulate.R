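#' Simulation configuration for synthetic cfDNA bin counts
#'
#' The simulator emulates the statistical structure the normalization stack
#' is built to remove: a smooth multiplicative GC bias, low-rank batch
#' artefacts shared across samples, per-sample depth variation, and
#' overdispersed (gamma-Poisson) count noise.
#'
#' Per-bin mean for sample s: `depth_s * g(gc_b) * exp(sum_k lambda_k *
#' u_{s,k} * v_{k,b})`, where `g` is a quadratic in GC with `g(0.4) = 1`,
#' `v_k` are fixed smooth artefact loadings drawn once from the config seed,
#' and `u_{s,k} ~ N(0,1)` are per-sample scores. Counts are negative binomial
#' with variance `m + dispersion * m^2` (`dispersion = 0` recovers Poisson).
#'
#' @param grid A `bin_grid`.
#' @param mean_depth Expected reads per bin (default 500, typical of
#'   low-coverage cfDNA screening depth on 50-kb bins).
#' @param gc_curvature Curvature of the quadratic GC bias
#'   `g(gc) = 1 - gc_curvature * (gc - 0.4)^2` (floored at 0.1).
#' @param artifact_scales Numeric vector `lambda_k`; its length is the number
#'   of batch-artefact components. Defaults to 1% and 0.5% of depth (RMS), the
#'   order of residual higher-order artefacts left after GC correction in
#'   homogeneous sequencing batches.
#' @param dispersion Negative-binomial overdispersion (>= 0). The default
#'   0.004 gives a variance-to-mean ratio of 3 at 500 reads per bin, the
#'   mild residual overdispersion typical of GC-corrected low-coverage
#'   bin counts.
#' @param depth_cv Coefficient of variation of per-sample depth (lognormal).
#' @param seed RNG seed recorded in all outputs.
#' @return A `sim_config`.
#' @export
sim_config <- function(grid, mean_depth = 500, gc_curvature = 2.5,
                       artifact_scales = c(0.01, 0.005), dispersion = 0.004,
                       depth_cv = 0.1, seed = 1L) {
  stopifnot(inherits(grid, "bin_grid"), mean_depth > 0, dispersion >= 0)
  k <- length(artifact_scales)
  loadings <- NULL
  if (k > 0) {
    set.seed(seed + 90001L)
    n <- nrow(grid)
    pos <- seq_len(n)
    loadings <- vapply(seq_len(k), function(j) {
      # smooth pseudo-batch pattern: a couple of random sinusoids
      freq <- runif(2, 1, 8)
      phase <- runif(2, 0, 2 * pi)
      v <- sin(2 * pi * freq[1] * pos / n + phase[1]) +
        0.5 * sin(2 * pi * freq[2] * pos / n + phase[2])
      v / sqrt(sum(v^2)) * sqrt(n)  # unit RMS so lambda is a log-scale sd
    }, numeric(nrow(grid)))
  }
  structure(
    list(grid = grid, mean_depth = mean_depth, gc_curvature = gc_curvature,
         artifact_scales = artifact_scales, artifact_loadings = loadings,
         dispersion = dispersion, depth_cv = depth_cv, seed = as.integer(seed)),
    class = "sim_config")
}

gc_bias_curve <- function(config, gc) {
  pmax(0.1, 1 - config$gc_curvature * (gc - 0.4)^2)
}

# Draw one profile's counts given a per-bin copy-state multiplier.
simulate_sample_core <- function(config, seed, multiplier = 1,
                                 sample_id = "sample", batch_id = NULL) {
  grid <- config$grid
  set.seed(seed)
  depth <- config$mean_depth *
    exp(rnorm(1, 0, config$depth_cv) - config$depth_cv^2 / 2)
  m <- depth * gc_bias_curve(config, grid$gc)
  k <- length(config$artifact_scales)
  if (k > 0) {
    u <- rnorm(k)
    logart <- as.vector(config$artifact_loadings %*% (config$artifact_scales * u))
    m <- m * exp(logart)
  }
  m <- m * multiplier
  counts <- if (config$dispersion == 0) rpois(length(m), m)
            else rnbinom(length(m), mu = m, size = 1 / config$dispersion)
  count_profile(sample_id, counts, grid, batch_id = batch_id)
}

#' Simulate a reference panel of unaffected samples
#'
#' @param config A `sim_config`.
#' @param n_samples Number of panel samples (>= 2).
#' @param batch_id Optional batch label applied to all samples.
#' @return List of `count_profile`s; excluded bins are still emitted (they
#'   are masked downstream, not here).
#' @export
simulate_panel <- function(config, n_samples, batch_id = NULL) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 2)
  lapply(seq_len(n_samples), function(s) {
    simulate_sample_core(config, config$seed + s,
                         sample_id = sprintf("panel_%02d", s),
                         batch_id = batch_id)
  })
}

#' Copy-number alteration profile (simulation ground truth)
#'
#' @param events data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (integer copy states; 2 = diploid baseline).
#' @param genome Optional `genome_build` to validate coordinates against.
#' @return A `cna_profile`.
#' @export
cna_profile <- function(events = NULL, genome = NULL) {
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), copy_number = integer())
  }
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$end <= events$start)) stop("empty or inverted event")
    if (!is.null(genome)) {
      if (!all(events$chrom %in% names(genome$chromosomes)))
        stop("event on unknown chromosome")
      lens <- genome$chromosomes[events$chrom]
      if (any(events$start < 0 | events$end > lens))
        stop("event outside chromosome bounds")
    }
    ev <- events[order(events$chrom, events$start), ]
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)]))
      stop("overlapping CNA events")
  }
  structure(list(events = events), class = "cna_profile")
}

#' Ground-truth record for one simulated tumour sample
#'
#' @param sample_id Sample identifier.
#' @param tumor_fraction Tumour DNA fraction f in [0, 1).
#' @param profile A `cna_profile`.
#' @param seed RNG seed used to draw the sample.
#' @return A `simulation_truth`.
#' @export
simulation_truth <- function(sample_id, tumor_fraction, profile, seed) {
  stopifnot(tumor_fraction >= 0, tumor_fraction < 1,
            inherits(profile, "cna_profile"))
  structure(list(sample_id = sample_id, tumor_fraction = tumor_fraction,
                 cna_profile = profile, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Per-bin mean multiplier implied by a CNA profile
#'
#' The two-population mixture for a diploid background: a bin fully inside a
#' copy-`c` event has its expected depth multiplied by `1 + f * (c - 2) / 2`;
#' partial overlap is weighted by the overlapped fraction of the bin.
#'
#' @param grid A `bin_grid`.
#' @param profile A `cna_profile`.
#' @param tumor_fraction f in [0, 1).
#' @return Numeric multiplier per bin.
#' @export
cna_bin_multiplier <- function(grid, profile, tumor_fraction) {
  mult <- rep(1, nrow(grid))
  ev <- profile$events
  if (nrow(ev) == 0 || tumor_fraction == 0) return(mult)
  genome <- bin_grid_genome(grid)
  if (!all(ev$chrom %in% names(genome$chromosomes)))
    stop("event on chromosome absent from genome")
  if (any(ev$start < 0 | ev$end > genome$chromosomes[ev$chrom]))
    stop("event outside genome")
  for (i in seq_len(nrow(ev))) {
    rows <- which(grid$chrom == ev$chrom[i] &
                    grid$end > ev$start[i] & grid$start < ev$end[i])
    if (!length(rows)) next
    ov <- pmin(grid$end[rows], ev$end[i]) - pmax(grid$start[rows], ev$start[i])
    w <- ov / (grid$end[rows] - grid$start[rows])
    mult[rows] <- mult[rows] +
      tumor_fraction * w * (ev$copy_number[i] - 2) / 2
  }
  mult
}

#' Simulate a tumour-bearing plasma sample
#'
#' @param config A `sim_config`.
#' @param truth A `simulation_truth` on the config's grid.
#' @param batch_id Optional batch label.
#' @return A `count_profile`. With `tumor_fraction = 0` and the same seed the
#'   counts are identical to an unaffected sample drawn with that seed.
#' @export
simulate_tumor_sample <- function(config, truth, batch_id = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "simulation_truth"))
  mult <- cna_bin_multiplier(config$grid, truth$cna_profile,
                             truth$tumor_fraction)
  simulate_sample_core(config, truth$seed, multiplier = mult,
                       sample_id = truth$sample_id, batch_id = batch_id)
}

#' Draw a random non-overlapping CNA profile
#'
#' @param genome A `genome_build`.
#' @param n_events Number of events.
#' @param size_range_mb Length-2 numeric: event size range in Mb.
#' @param seed RNG seed.
#' @param copy_states Copy numbers to sample events from.
#' @param max_tries Placement retries before giving up.
#' @return A `cna_profile`.
#' @export
random_cna_profile <- function(genome, n_events, size_range_mb = c(20, 100),
                               seed = 1L, copy_states = c(1L, 3L),
                               max_tries = 1000L) {
  if (n_events == 0) return(cna_profile(NULL))
  set.seed(seed)
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       copy_number = integer(), stringsAsFactors = FALSE)
  lens <- genome$chromosomes
  for (i in seq_len(n_events)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      size <- runif(1, size_range_mb[1], size_range_mb[2]) * 1e6
      fits <- lens[lens >= size]
      if (!length(fits))
        stop("event of ", round(size / 1e6), " Mb does not fit any chromosome")
      ch <- sample(names(fits), 1, prob = as.numeric(fits))
      start <- floor(runif(1, 0, lens[[ch]] - size))
      end <- start + round(size)
      clash <- placed$chrom == ch & placed$start < end & placed$end > start
      if (!any(clash)) {
        placed <- rbind(placed, data.frame(
          chrom = ch, start = start, end = end,
          copy_number = copy_states[sample.int(length(copy_states), 1)],
          stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n_events,
                  " non-overlapping events after ", max_tries, " tries")
  }
  cna_profile(placed, genome)
}

#' Synthetic bin annotations for a toy grid
#'
#' Assigns a smooth GC track (so the LOESS stage has a recoverable bias to
#' undo), near-one mappability with occasional low-mappability bins, and a
#' small repeat fraction with occasional repeat-rich bins.
#'
#' @param grid A `bin_grid`.
#' @param seed RNG seed.
#' @param frac_bad Fraction of bins given poor mappability / high repeat
#'   content (default 0.5% each).
#' @return The annotated `bin_grid`.
#' @export
annotate_bins_synthetic <- function(grid, seed = 1L, frac_bad = 0.005) {
  set.seed(seed + 70001L)
  n <- nrow(grid)
  pos <- seq_len(n)
  gc <- 0.45 + 0.08 * sin(2 * pi * 3.3 * pos / n) +
    0.04 * sin(2 * pi * 11.7 * pos / n + 1) + rnorm(n, 0, 0.01)
  grid$gc <- pmin(0.75, pmax(0.25, gc))
  grid$mappability <- pmin(1, pmax(0, 1 - abs(rnorm(n, 0, 0.02))))
  grid$repeat_frac <- pmin(1, pmax(0, abs(rnorm(n, 0.1, 0.05))))
  bad_map <- sample.int(n, max(0, round(frac_bad * n)))
  grid$mappability[bad_map] <- runif(length(bad_map), 0, 0.5)
  bad_rep <- sample.int(n, max(0, round(frac_bad * n)))
  grid$repeat_frac[bad_rep] <- runif(length(bad_rep), 0.6, 0.95)
  grid
}

#' Write simulation truth records
#'
#' Writes `<prefix>_truth.tsv` (`sample_id tumor_fraction seed`) and one BED
#' of events per sample, `<prefix>_<sample_id>_events.bed`
#' (`chrom start end copy_number`).
#'
#' @param prefix Output path prefix.
#' @param truths List of `simulation_truth` records.
#' @return Path of the truth TSV, invisibly.
#' @export
write_truth <- function(prefix, truths) {
  tab <- data.frame(
    sample_id = vapply(truths, `[[`, "", "sample_id"),
    tumor_fraction = vapply(truths, `[[`, 0, "tumor_fraction"),
    seed = vapply(truths, function(t) as.integer(t$seed), 0L))
  path <- paste0(prefix, "_truth.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in truths) {
    ev <- t$cna_profile$events
    ev$start <- as.integer(ev$start)
    ev$end <- as.integer(ev$end)
    write.table(ev[c("chrom", "start", "end", "copy_number")],
                paste0(prefix, "_", t$sample_id, "_events.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
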