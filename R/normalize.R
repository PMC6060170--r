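#' Exclude unreliable bins from a grid
#'
#' A bin is flagged excluded when (a) its variance-to-mean ratio across the
#' reference panel (after scaling each sample to a common mean depth) exceeds
#' the given quantile of all bins, (b) its mappability is below
#' `min_mappability`, or (c) its repeat fraction exceeds `max_repeat`.
#'
#' @param panel List of `count_profile`s (the reference panel).
#' @param grid The shared `bin_grid`.
#' @param var_quantile Quantile of the variance/mean ratio above which a bin
#'   is excluded (default 0.99).
#' @param min_mappability Mappability threshold (default 0.75).
#' @param max_repeat Repeat-fraction threshold (default 0.5).
#' @return Copy of `grid` with updated `excluded` flags; attribute
#'   `exclusion_counts` holds the per-criterion tallies.
#' @export
exclusion_filter <- function(panel, grid, var_quantile = 0.99,
                             min_mappability = 0.75, max_repeat = 0.5) {
  if (length(panel) == 0) stop("empty reference panel")
  counts <- vapply(panel, `[[`, numeric(nrow(grid)), "counts")
  # remove per-sample depth so the ratio reflects bin behaviour, not depth
  depth <- colMeans(counts)
  scaled <- sweep(counts, 2, mean(depth) / depth, `*`)
  m <- rowMeans(scaled)
  v <- apply(scaled, 1, stats::var)
  vmr <- ifelse(m > 0, v / m, 0)
  cut <- stats::quantile(vmr, var_quantile, names = FALSE)
  by_var <- vmr > cut
  by_map <- grid$mappability < min_mappability
  by_rep <- grid$repeat_frac > max_repeat
  excl <- by_var | by_map | by_rep | grid$excluded
  if (all(excl)) stop("exclusion filter removed every bin")
  out <- grid
  out$excluded <- excl
  attr(out, "exclusion_counts") <- c(high_variance = sum(by_var),
                                     low_mappability = sum(by_map),
                                     high_repeat = sum(by_rep),
                                     total = sum(excl))
  out
}

#' LOESS sample-specific GC adjustment
#'
#' Fits count versus GC fraction over unmasked autosomal bins (robust LOESS)
#' and rescales each bin by `median(fitted) / fitted(gc_bin)`, removing the
#' sample's own GC bias while preserving its median count level. Prediction
#' is clamped to the fitted GC range.
#'
#' @param profile A `count_profile`.
#' @param grid A `bin_grid` with annotations and exclusion flags.
#' @param span LOESS span (default 0.3).
#' @param degree LOESS degree (default 2).
#' @return A `normalized_profile` with `adjusted_counts` set for every bin
#'   and `mask` TRUE on usable bins; log-ratio `values` are filled later by
#'   [pca_smooth()].
#' @export
loess_gc_adjust <- function(profile, grid, span = 0.3, degree = 2) {
  stopifnot(inherits(profile, "count_profile"))
  if (profile$grid_hash != grid_hash(grid))
    stop("profile was built on a different bin grid")
  if (length(profile$counts) != nrow(grid))
    stop("profile has ", length(profile$counts), " counts for ",
         nrow(grid), " bins")
  use <- usable_bins(grid, autosomal_only = TRUE)
  gc <- grid$gc[use]
  y <- profile$counts[use]
  adjusted <- profile$counts
  if (length(use) < 100 || diff(range(gc)) <= 0.05) {
    warning("degenerate GC range or too few bins; identity GC adjustment")
  } else {
    fit <- stats::loess(y ~ gc, span = span, degree = degree,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    gc_all <- pmin(max(gc), pmax(min(gc), grid$gc))
    fitted_all <- predict(fit, newdata = data.frame(gc = gc_all))
    fitted_all[!is.finite(fitted_all) | fitted_all <= 0] <- NA
    ref <- median(fitted_all[use], na.rm = TRUE)
    factor <- ref / fitted_all
    factor[is.na(factor)] <- 1
    adjusted <- unname(profile$counts * factor)
  }
  structure(
    list(sample_id = profile$sample_id, batch_id = profile$batch_id,
         adjusted_counts = adjusted,
         values = rep(NA_real_, nrow(grid)),
         mask = !grid$excluded,
         grid_hash = profile$grid_hash),
    class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile '%s': %d bins, %d usable%s>\n",
              x$sample_id, length(x$adjusted_counts), sum(x$mask),
              if (all(is.na(x$values))) " (log-ratios not yet computed)" else ""))
  invisible(x)
}

# GC-adjusted bin fractions: adjusted count / autosomal unmasked total.
bin_fractions <- function(nprofile, grid) {
  tot <- sum(nprofile$adjusted_counts[usable_bins(grid, TRUE)])
  if (tot <= 0) stop("zero autosomal total for sample ", nprofile$sample_id)
  nprofile$adjusted_counts / tot
}

#' Fit a reference panel for population-based correction
#'
#' Computes per-bin medians and MADs of GC-adjusted bin fractions across the
#' panel, and the top-K principal components of the centered log2
#' fraction/median matrix over unmasked bins ("higher order artefact"
#' directions removed by [pca_smooth()]). When batch labels are present and a
#' batch has at least `min_batch` samples, per-batch bin medians are stored
#' and used for centering profiles from that batch.
#'
#' @param nprofiles List of `normalized_profile`s (after GC adjustment).
#' @param grid The shared `bin_grid`.
#' @param K Number of principal components (default 10, capped at
#'   `panel_size - 2`).
#' @param min_batch Minimum batch size for batch-specific medians (default 8).
#' @return A `reference_panel`.
#' @export
fit_reference_panel <- function(nprofiles, grid, K = 10, min_batch = 8) {
  n <- length(nprofiles)
  if (K >= n) stop("K must be smaller than the panel size")
  frac <- vapply(nprofiles, bin_fractions, numeric(nrow(grid)), grid = grid)
  bin_median <- apply(frac, 1, median)
  bin_mad <- apply(frac, 1, mad, constant = 1)
  mask <- !grid$excluded & bin_median > 0
  K <- min(K, n - 2)
  logmat <- t(log2(sweep(frac[mask, , drop = FALSE], 1,
                         bin_median[mask], `/`)))  # samples x bins
  # per-sample median centering: a depth-normalization constant is not an
  # artefact direction worth a component
  logmat <- sweep(logmat, 1, apply(logmat, 1, median))
  rotation <- NULL
  if (all(apply(logmat, 2, stats::var) == 0)) {
    warning("panel has zero variance; PCA smoothing disabled")
    K <- 0
  } else if (K > 0) {
    pc <- stats::prcomp(logmat, center = TRUE, scale. = FALSE, rank. = K)
    rotation <- pc$rotation
    K <- ncol(rotation)
  }
  batches <- vapply(nprofiles, function(p)
    if (is.null(p$batch_id)) NA_character_ else p$batch_id, "")
  batch_medians <- NULL
  for (b in unique(batches[!is.na(batches)])) {
    idx <- which(batches == b)
    if (length(idx) >= min_batch) {
      if (is.null(batch_medians)) batch_medians <- list()
      batch_medians[[b]] <- apply(frac[, idx, drop = FALSE], 1, median)
    }
  }
  structure(
    list(grid_hash = grid_hash(grid), panel_size = n, K = K,
         mask = mask, bin_median = bin_median, bin_mad = bin_mad,
         rotation = rotation, fractions = frac, batches = batches,
         batch_medians = batch_medians),
    class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel: %d samples, %d usable bins, K = %d%s>\n",
              x$panel_size, sum(x$mask), x$K,
              if (!is.null(x$batch_medians))
                sprintf(", %d batch(es)", length(x$batch_medians)) else ""))
  invisible(x)
}

# Panel bin medians used for centering this sample (batch-specific if known).
panel_medians_for <- function(panel, batch_id) {
  if (!is.null(batch_id) && !is.null(panel$batch_medians) &&
      batch_id %in% names(panel$batch_medians))
    panel$batch_medians[[batch_id]]
  else
    panel$bin_median
}

#' PCA-based population smoothing
#'
#' Sets the profile's log2 ratio values (sample fraction over panel median)
#' and removes their projection onto the panel's top-K principal components.
#' A copy-number signal absent from the panel subspace passes through intact;
#' shared artefacts captured by the components are subtracted.
#'
#' @param nprofile A `normalized_profile` (after [loess_gc_adjust()]).
#' @param panel A `reference_panel` on the same grid.
#' @param grid The shared `bin_grid`.
#' @return The `normalized_profile` with `values` filled (NA on masked bins)
#'   and its mask intersected with the panel mask.
#' @export
pca_smooth <- function(nprofile, panel, grid) {
  if (nprofile$grid_hash != panel$grid_hash)
    stop("profile and reference panel are on different grids")
  frac <- bin_fractions(nprofile, grid)
  med <- panel_medians_for(panel, nprofile$batch_id)
  mask <- nprofile$mask & panel$mask
  v <- log2(frac[panel$mask] / med[panel$mask])
  v[!is.finite(v)] <- 0
  # median-center so the diploid baseline sits at zero regardless of the
  # sample's total-count normalization
  v <- v - median(v)
  if (panel$K > 0) {
    R <- panel$rotation
    v <- v - as.vector(R %*% crossprod(R, v))
    v <- v - median(v)
  }
  values <- rep(NA_real_, length(frac))
  values[panel$mask] <- v
  values[!mask] <- NA_real_
  nprofile$values <- values
  nprofile$mask <- mask
  nprofile
}

#' Serialize a reference panel to a single JSON archive
#'
#' Layout: grid hash, panel size, K, mask, per-bin medians and MADs,
#' component matrix, per-sample fractions, and batch medians. The loader
#' refuses a panel whose grid hash does not match the supplied grid.
#'
#' @param path Output file.
#' @param panel A `reference_panel`.
#' @export
write_reference_panel <- function(path, panel) {
  obj <- panel
  class(obj) <- NULL
  enc <- function(m) if (is.null(m)) NULL else
    list(data = as.vector(m), nrow = nrow(m), ncol = ncol(m))
  obj$rotation <- enc(obj$rotation)
  obj$fractions <- enc(obj$fractions)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a reference panel written by [write_reference_panel()]
#' @param path Input file.
#' @param grid The `bin_grid` the panel must match.
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path, grid) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$grid_hash, grid_hash(grid)))
    stop("reference panel was built on a different bin grid")
  dec <- function(m) if (is.null(m) || length(m) == 0) NULL else
    matrix(m$data, nrow = m$nrow, ncol = m$ncol)
  obj$rotation <- dec(obj$rotation)
  obj$fractions <- dec(obj$fractions)
  if (!is.null(obj$batch_medians) && length(obj$batch_medians) == 0)
    obj$batch_medians <- NULL
  obj$mask <- as.logical(obj$mask)
  class(obj) <- "reference_panel"
  obj
}
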