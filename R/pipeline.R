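#' Pipeline run configuration
#'
#' Bundles every stage's options. All randomness (CBS permutations, CADET
#' bootstrap) derives from `seed`, so re-running the same configuration is
#' bit-identical.
#'
#' @param grid A `bin_grid` shared by panel and samples.
#' @param panel List of panel `count_profile`s.
#' @param samples List of test-sample `count_profile`s.
#' @param cytobands Optional `cytoband_map`.
#' @param cohort Optional cohort data.frame (joined to the per-sample calls
#'   for the detection table).
#' @param tf_model Optional `tf_model`; without it the log odds ratio uses
#'   the floor tumour fraction.
#' @param out_dir Optional output directory; when given, per-sample SEG and
#'   JSON reports, the detection table and a manifest are written there.
#' @param K Principal components for panel smoothing.
#' @param loess_span LOESS span of the GC fit.
#' @param var_quantile,min_mappability,max_repeat Exclusion thresholds.
#' @param cbs A `cbs_params`.
#' @param thresholds A `cadet_thresholds`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(grid, panel, samples, cytobands = NULL,
                            cohort = NULL, tf_model = NULL, out_dir = NULL,
                            K = 10, loess_span = 0.3, var_quantile = 0.99,
                            min_mappability = 0.75, max_repeat = 0.5,
                            cbs = NULL, thresholds = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(cbs)) cbs <- cbs_params(seed = derive_seed(seed, 11))
  if (is.null(thresholds))
    thresholds <- cadet_thresholds(seed = derive_seed(seed, 13))
  if (length(panel) < 2) stop("need at least 2 panel samples")
  check_same_grid(rep(list(grid), 1))
  structure(
    list(grid = grid, panel = panel, samples = samples,
         cytobands = cytobands, cohort = cohort, tf_model = tf_model,
         out_dir = out_dir, K = K, loess_span = loess_span,
         var_quantile = var_quantile, min_mappability = min_mappability,
         max_repeat = max_repeat, cbs = cbs, thresholds = thresholds,
         seed = seed),
    class = "pipeline_config")
}

#' Build the normalization reference from a panel
#'
#' Stage bundle: exclusion filter, per-sample LOESS GC adjustment, panel fit.
#'
#' @param panel List of `count_profile`s.
#' @param grid A `bin_grid`.
#' @inheritParams pipeline_config
#' @return List with the updated `grid` and the `reference_panel` `ref`.
#' @export
fit_panel <- function(panel, grid, K = 10, loess_span = 0.3,
                      var_quantile = 0.99, min_mappability = 0.75,
                      max_repeat = 0.5) {
  grid <- exclusion_filter(panel, grid, var_quantile = var_quantile,
                           min_mappability = min_mappability,
                           max_repeat = max_repeat)
  nprofiles <- lapply(panel, loess_gc_adjust, grid = grid, span = loess_span)
  ref <- fit_reference_panel(nprofiles, grid, K = K)
  list(grid = grid, ref = ref)
}

#' Normalize, segment and classify one sample
#'
#' @param profile A `count_profile`.
#' @param ref A `reference_panel`.
#' @param grid The (exclusion-filtered) `bin_grid`.
#' @param cbs A `cbs_params`.
#' @param thresholds A `cadet_thresholds`.
#' @param cytobands Optional `cytoband_map`.
#' @param tf_model Optional `tf_model`.
#' @param loess_span LOESS span.
#' @return A `sample_report` (the `normalized_profile` and segment table ride
#'   along as attributes `nprofile` and `segments`).
#' @export
process_sample <- function(profile, ref, grid, cbs = cbs_params(),
                           thresholds = cadet_thresholds(), cytobands = NULL,
                           tf_model = NULL, loess_span = 0.3) {
  np <- loess_gc_adjust(profile, grid, span = loess_span)
  np <- pca_smooth(np, ref, grid)
  segs <- segment_sample(np, grid, cbs)
  tf <- if (!is.null(tf_model))
    as.numeric(estimate_tumor_fraction(tf_model, np, grid)) else NULL
  report <- call_sample(np, segs, ref, grid, cytobands = cytobands,
                        thresholds = thresholds,
                        tumor_fraction_estimate = tf)
  attr(report, "nprofile") <- np
  attr(report, "segments") <- segs
  report
}

#' Run the full CNA pipeline
#'
#' Stages in order: bin exclusion, LOESS GC adjustment, reference-panel fit,
#' PCA smoothing, CBS, CADET classification, tumour-fraction estimation, and
#' the cohort detection table. Per-sample seeds are derived from the config
#' seed and the sample order, so the run is reproducible bit-for-bit.
#'
#' @param config A `pipeline_config`.
#' @return List with `grid`, `ref`, `reports` (per-sample), `calls` (bound
#'   SEG table), `detection` (per type/stage detection table), `pooled`
#'   (pooled rates) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_same_grid(c(list(config$grid)))
  fitted <- fit_panel(config$panel, config$grid, K = config$K,
                      loess_span = config$loess_span,
                      var_quantile = config$var_quantile,
                      min_mappability = config$min_mappability,
                      max_repeat = config$max_repeat)
  grid <- fitted$grid
  ref <- fitted$ref
  reports <- vector("list", length(config$samples))
  for (s in seq_along(config$samples)) {
    prof <- config$samples[[s]]
    cbs <- config$cbs
    cbs$seed <- derive_seed(config$seed, 21, s)
    th <- config$thresholds
    th$seed <- derive_seed(config$seed, 23, s)
    reports[[s]] <- tryCatch(
      process_sample(prof, ref, grid, cbs = cbs, thresholds = th,
                     cytobands = config$cytobands,
                     tf_model = config$tf_model,
                     loess_span = config$loess_span),
      error = function(e)
        stop("pipeline failed at sample '", prof$sample_id, "': ",
             conditionMessage(e)))
  }
  names(reports) <- vapply(reports, `[[`, "", "sample_id")

  calls <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$calls) == 0) return(NULL)
    data.frame(sample = r$sample_id, chrom = r$calls$chrom,
               start = r$calls$start_bp, end = r$calls$end_bp,
               n_bins = r$calls$n_bins, log2_ratio = r$calls$mean_value,
               segment_fraction = r$calls$segment_fraction,
               z_cbs = r$calls$z_cbs, lor = r$calls$lor, bcl = r$calls$bcl,
               call = r$calls$call, size_mb = r$calls$size_mb,
               label = r$calls$label, stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(sample = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        n_bins = integer(), log2_ratio = numeric(),
                        segment_fraction = numeric(), z_cbs = numeric(),
                        lor = numeric(), bcl = numeric(), call = character(),
                        size_mb = numeric(), label = character())

  detection <- NULL
  pooled <- NULL
  if (!is.null(config$cohort)) {
    coh <- config$cohort
    idx <- match(coh$sample_id, names(reports))
    coh$cna_positive <- vapply(idx, function(i)
      if (is.na(i)) NA else reports[[i]]$cna_positive, NA)
    coh$total_cna_mb <- vapply(idx, function(i)
      if (is.na(i)) NA_real_ else reports[[i]]$total_cna_mb, 0)
    detection <- detection_table(coh)
    pooled <- pooled_detection_rates(coh)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("plasmaCNA")),
    seed = config$seed,
    n_panel = length(config$panel),
    samples = names(reports),
    n_bins = nrow(grid), n_excluded = sum(grid$excluded),
    K = ref$K,
    cbs = unclass(config$cbs),
    thresholds = unclass(config$thresholds))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_seg(file.path(config$out_dir, "calls.seg"), calls)
    for (r in reports)
      write_sample_report(
        file.path(config$out_dir, paste0(r$sample_id, "_report.json")), r)
    if (!is.null(detection))
      write.table(detection, file.path(config$out_dir, "detection_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
  }

  list(grid = grid, ref = ref, reports = reports, calls = calls,
       detection = detection, pooled = pooled, manifest = manifest)
}
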