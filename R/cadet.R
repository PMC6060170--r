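#' CADET decision thresholds
#'
#' Defaults follow the published decision rule: a segment is significant when
#' `|Z_CBS| >= 3.95`, `LOR_CBS > 0` and `BCL >= 0.99`; `|Z_CBS| <
#' alpha_whole * |Z_CHR|` (alpha_whole = 0.8) marks a whole-chromosome event;
#' CNAs are reported when they exceed 10 Mb; the bootstrap uses 1000
#' resamples. `mad_consistency` (1.4826) puts "MADs away from the median" on
#' a standard-deviation-comparable scale; set it to 1 for raw MAD units.
#'
#' @param z_cut Z threshold (default 3.95).
#' @param bcl_cut Bootstrap confidence level threshold (default 0.99).
#' @param alpha_whole Whole-chromosome comparison factor (default 0.8).
#' @param n_bootstrap Bootstrap resamples (default 1000).
#' @param min_cna_mb Minimum reported CNA size in Mb, strict (default 10).
#' @param mad_consistency MAD-to-sigma consistency factor (default 1.4826).
#' @param seed Seed; per-segment bootstrap seeds are derived from it and the
#'   segment coordinates so results are order-independent.
#' @return A `cadet_thresholds` list.
#' @export
cadet_thresholds <- function(z_cut = 3.95, bcl_cut = 0.99, alpha_whole = 0.8,
                             n_bootstrap = 1000L, min_cna_mb = 10,
                             mad_consistency = 1.4826, seed = 1L) {
  stopifnot(z_cut > 0, bcl_cut > 0, bcl_cut <= 1, alpha_whole > 0,
            alpha_whole <= 1, n_bootstrap > 0, min_cna_mb > 0)
  structure(list(z_cut = z_cut, bcl_cut = bcl_cut, alpha_whole = alpha_whole,
                 n_bootstrap = as.integer(n_bootstrap),
                 min_cna_mb = min_cna_mb, mad_consistency = mad_consistency,
                 seed = as.integer(seed)),
            class = "cadet_thresholds")
}

#' Segment fraction
#'
#' Fraction of autosomal reads falling in a segment: sum of (GC-adjusted)
#' counts over the segment's bins divided by the sum over all unmasked
#' autosomal bins.
#'
#' @param adjusted_counts Per-bin GC-adjusted counts.
#' @param seg_bins Integer row indices (1-based) of the segment's bins.
#' @param autosomal_total Denominator: sum over unmasked autosomal bins.
#' @return Numeric fraction.
#' @export
segment_fraction <- function(adjusted_counts, seg_bins, autosomal_total) {
  if (autosomal_total <= 0) stop("zero autosomal total")
  sum(adjusted_counts[seg_bins]) / autosomal_total
}

#' Reference distribution of a segment's fraction across the panel
#'
#' Evaluates exactly the segment's bin interval in every panel sample. The
#' median is batch-specific when the sample's batch has enough panel members;
#' the MAD is the "static" one pooled across the whole panel.
#'
#' @param panel A `reference_panel`.
#' @param seg_bins Integer row indices of the segment's bins.
#' @param batch_id Optional batch of the test sample.
#' @return List with `median`, `mad` (raw, unscaled), and the per-panel-sample
#'   fractions `values`.
#' @export
panel_segment_reference <- function(panel, seg_bins, batch_id = NULL) {
  f <- colSums(panel$fractions[seg_bins, , drop = FALSE])
  med <- if (!is.null(batch_id) && !is.null(panel$batch_medians) &&
             batch_id %in% names(panel$batch_medians))
    median(f[panel$batches == batch_id])
  else median(f)
  list(median = med, mad = mad(f, constant = 1), values = f)
}

#' MAD-scaled z statistic of an observed segment fraction
#'
#' `z = (f_obs - ref_median) / (mad_consistency * ref_mad)`; at the decision
#' boundary an observation 3.95 scaled MADs from the reference median scores
#' exactly 3.95.
#'
#' @param f_obs Observed segment fraction.
#' @param ref_median,ref_mad Reference median and raw MAD.
#' @param mad_consistency Consistency factor (default 1.4826).
#' @return Numeric z.
#' @export
z_statistic <- function(f_obs, ref_median, ref_mad, mad_consistency = 1.4826) {
  if (ref_mad <= 0)
    stop("reference MAD is zero; use the pooled-MAD fallback")
  (f_obs - ref_median) / (mad_consistency * ref_mad)
}

# Segment reference with a pooled fallback when the segment MAD degenerates:
# per-bin panel MADs aggregated under independence (sqrt of summed squares).
segment_reference_safe <- function(panel, seg_bins, batch_id = NULL) {
  ref <- panel_segment_reference(panel, seg_bins, batch_id)
  if (ref$mad <= 0) {
    warning("segment reference MAD is zero; using pooled per-bin fallback")
    ref$mad <- sqrt(sum(panel$bin_mad[seg_bins]^2))
    if (ref$mad <= 0) ref$mad <- .Machine$double.eps
  }
  ref
}

#' Whole-chromosome z statistic
#'
#' The same computation as [z_statistic()] with the segment taken to be all
#' of the chromosome's unmasked bins (autosomal denominator as always).
#'
#' @param nprofile A `normalized_profile`.
#' @param chrom Chromosome name.
#' @param panel A `reference_panel`.
#' @param grid The `bin_grid`.
#' @param thresholds A `cadet_thresholds`.
#' @return Numeric z for the chromosome.
#' @export
chromosome_z <- function(nprofile, chrom, panel, grid,
                         thresholds = cadet_thresholds()) {
  bins <- which(grid$chrom == chrom & nprofile$mask & panel$mask)
  if (!length(bins)) stop("chromosome ", chrom, " has no unmasked bins")
  tot <- sum(nprofile$adjusted_counts[usable_bins(grid, TRUE)])
  f_obs <- segment_fraction(nprofile$adjusted_counts, bins, tot)
  ref <- segment_reference_safe(panel, bins, nprofile$batch_id)
  z_statistic(f_obs, ref$median, ref$mad, thresholds$mad_consistency)
}

#' Gaussian log odds ratio for a candidate CNA
#'
#' Likelihood ratio of the observed segment fraction under a single-copy
#' CNA at the estimated tumour fraction versus the diploid null:
#' `lor = log N(f_obs; f_alt, sigma) - log N(f_obs; f_null, sigma)`. The
#' alternative mean renormalizes the read budget for the event itself,
#' `f_alt = f_null (1 +/- tf/2) / (1 +/- f_null tf/2)` (gain / loss), which
#' reduces to `f_null (1 +/- tf/2)` for small segments. Positive lor means
#' the observation sits closer to the CNA hypothesis.
#'
#' @param f_obs Observed segment fraction.
#' @param f_null Reference (diploid) segment fraction.
#' @param tumor_fraction Estimated tumour DNA fraction in [0, 1).
#' @param sigma Gaussian scale (typically `mad_consistency * ref_mad`).
#' @param direction "gain" or "loss".
#' @return Numeric lor; exactly 0 (flagged indeterminate) when
#'   `tumor_fraction` is 0.
#' @export
log_odds_ratio <- function(f_obs, f_null, tumor_fraction, sigma,
                           direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(sigma > 0, tumor_fraction >= 0, tumor_fraction < 1)
  if (tumor_fraction == 0) {
    out <- 0
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  s <- if (direction == "gain") 1 else -1
  f_alt <- f_null * (1 + s * tumor_fraction / 2) /
    (1 + s * f_null * tumor_fraction / 2)
  ((f_obs - f_null)^2 - (f_obs - f_alt)^2) / (2 * sigma^2)
}

#' Bootstrap confidence level of a candidate segment
#'
#' Within-sample resampling check that a candidate CNA's shift is consistent
#' along the segment: (1) the median shift of the segment's bin counts from
#' the rest of its chromosome is computed; (2) the segment is shifted back to
#' baseline and pooled with the out-of-segment chromosome bins; (3) a
#' pseudo-segment of the same bin length is resampled with replacement from
#' the baseline, the shift re-applied, and its segment fraction computed;
#' (4) after `n_bootstrap` rounds the BCL is the proportion of bootstrap
#' fractions whose |z| against the panel reference meets the threshold. The
#' fraction denominator is held at the sample's observed autosomal total.
#'
#' @param adjusted_counts Per-bin GC-adjusted counts of the sample.
#' @param seg_bins Row indices of the segment's bins.
#' @param chrom_bins Row indices of all unmasked bins on the host chromosome.
#' @param ref Reference list with `median` and `mad` (raw).
#' @param autosomal_total Autosomal denominator.
#' @param thresholds A `cadet_thresholds`.
#' @return BCL in [0, 1].
#' @export
bootstrap_bcl <- function(adjusted_counts, seg_bins, chrom_bins, ref,
                          autosomal_total, thresholds = cadet_thresholds()) {
  stopifnot(thresholds$n_bootstrap >= 100)
  y_seg <- adjusted_counts[seg_bins]
  out_bins <- setdiff(chrom_bins, seg_bins)
  if (length(out_bins) == 0) {
    warning("segment covers its whole chromosome; baseline from the segment")
    shift <- 0
    baseline <- y_seg
  } else {
    shift <- median(y_seg) - median(adjusted_counts[out_bins])
    baseline <- c(y_seg - shift, adjusted_counts[out_bins])
  }
  L <- length(y_seg)
  nb <- thresholds$n_bootstrap
  set.seed(derive_seed(thresholds$seed, min(seg_bins), max(seg_bins)))
  draws <- matrix(baseline[sample.int(length(baseline), L * nb, replace = TRUE)],
                  nrow = L)
  f_boot <- (colSums(draws) + L * shift) / autosomal_total
  z_boot <- (f_boot - ref$median) / (thresholds$mad_consistency * ref$mad)
  mean(abs(z_boot) >= thresholds$z_cut)
}

#' Apply the CADET classification rule
#'
#' A segment is a significant event iff `|z_cbs| >= z_cut`, `lor > 0` and
#' `bcl >= bcl_cut`; its direction is gain for positive z, loss otherwise;
#' `|z_cbs| < alpha_whole * |z_chr|` assigns whole-chromosome scope.
#'
#' @param z_cbs,z_chr Segment and host-chromosome z statistics.
#' @param lor Log odds ratio.
#' @param bcl Bootstrap confidence level.
#' @param thresholds A `cadet_thresholds`.
#' @return List with `call` ("gain", "loss" or "none") and `scope`
#'   ("whole_chromosome", "subchromosomal", or NA for non-calls).
#' @export
classify_segment <- function(z_cbs, z_chr, lor, bcl,
                             thresholds = cadet_thresholds()) {
  stopifnot(is.finite(z_cbs), is.finite(z_chr), is.finite(lor), is.finite(bcl))
  significant <- abs(z_cbs) >= thresholds$z_cut && lor > 0 &&
    bcl >= thresholds$bcl_cut
  if (!significant) return(list(call = "none", scope = NA_character_))
  list(call = if (z_cbs > 0) "gain" else "loss",
       scope = if (abs(z_cbs) < thresholds$alpha_whole * abs(z_chr))
         "whole_chromosome" else "subchromosomal")
}

# Score one segment (fraction, z, lor, bcl, classification).
score_segment <- function(nprofile, seg_bins, chrom_bins, panel, grid,
                          thresholds, tumor_fraction, z_chr,
                          autosomal_total, whole_chrom = FALSE) {
  f_obs <- segment_fraction(nprofile$adjusted_counts, seg_bins, autosomal_total)
  ref <- segment_reference_safe(panel, seg_bins, nprofile$batch_id)
  z <- z_statistic(f_obs, ref$median, ref$mad, thresholds$mad_consistency)
  dir <- if (z > 0) "gain" else "loss"
  lor <- log_odds_ratio(f_obs, ref$median, tumor_fraction,
                        thresholds$mad_consistency * ref$mad, dir)
  bcl <- bootstrap_bcl(nprofile$adjusted_counts, seg_bins, chrom_bins, ref,
                       autosomal_total, thresholds)
  cls <- classify_segment(z, z_chr, as.numeric(lor), bcl, thresholds)
  # a segment that IS the whole chromosome is whole-chromosome scope by
  # construction (z_cbs == z_chr there, so the alpha rule cannot fire)
  if (cls$call != "none" && whole_chrom) cls$scope <- "whole_chromosome"
  list(f_obs = f_obs, z = z, lor = as.numeric(lor), bcl = bcl,
       call = cls$call, scope = cls$scope)
}

#' Score and classify every CBS segment of a sample
#'
#' Runs the full decision layer over a segmented profile: segment fractions
#' against the panel reference, z statistics, Gaussian log odds ratio at the
#' estimated tumour fraction, bootstrap confidence levels, the four-condition
#' classification, merging of adjacent same-direction significant segments
#' separated only by masked bins, the strict >`min_cna_mb` reporting rule,
#' and trisomy flags for whole-chromosome gains on chr13/18/21.
#'
#' @param nprofile A `normalized_profile` (GC-adjusted and smoothed).
#' @param segments Segment table from [segment_sample()].
#' @param panel A `reference_panel`.
#' @param grid The `bin_grid`.
#' @param cytobands Optional `cytoband_map` for labels.
#' @param thresholds A `cadet_thresholds`.
#' @param tumor_fraction_estimate Estimated tumour fraction; when NULL or
#'   below 0.01 the log odds ratio uses a floor of 0.01 to keep the two
#'   hypotheses distinct (recorded in the report).
#' @return A `sample_report`: segment call table, reported calls, trisomy
#'   flags, `total_cna_mb`, `cna_positive`, tumour fraction used.
#' @export
call_sample <- function(nprofile, segments, panel, grid, cytobands = NULL,
                        thresholds = cadet_thresholds(),
                        tumor_fraction_estimate = NULL) {
  if (is.null(panel)) stop("a reference panel is required")
  tf_floored <- is.null(tumor_fraction_estimate) ||
    tumor_fraction_estimate < 0.01
  tf <- if (tf_floored) 0.01 else tumor_fraction_estimate
  autosomal_total <- sum(nprofile$adjusted_counts[usable_bins(grid, TRUE)])
  chroms <- unique(segments$chrom)
  z_chr <- vapply(chroms, function(ch)
    chromosome_z(nprofile, ch, panel, grid, thresholds), 0)
  names(z_chr) <- chroms

  score_row <- function(start_bin, end_bin, chrom) {
    rows <- (start_bin + 1L):end_bin
    seg_bins <- rows[nprofile$mask[rows] & panel$mask[rows]]
    chrom_bins <- which(grid$chrom == chrom & nprofile$mask & panel$mask)
    whole <- length(seg_bins) == length(chrom_bins)
    score_segment(nprofile, seg_bins, chrom_bins, panel, grid, thresholds,
                  tf, z_chr[[chrom]], autosomal_total, whole_chrom = whole)
  }

  scored <- segments
  sc <- mapply(score_row, segments$start_bin, segments$end_bin,
               segments$chrom, SIMPLIFY = FALSE)
  scored$segment_fraction <- vapply(sc, `[[`, 0, "f_obs")
  scored$z_cbs <- vapply(sc, `[[`, 0, "z")
  scored$z_chr <- z_chr[scored$chrom]
  scored$lor <- vapply(sc, `[[`, 0, "lor")
  scored$bcl <- vapply(sc, `[[`, 0, "bcl")
  scored$call <- vapply(sc, `[[`, "", "call")
  scored$scope <- vapply(sc, `[[`, "", "scope")

  # merge runs of adjacent same-direction significant segments (they are
  # separated only by masked bins within a chromosome) and re-score
  merged <- scored[0, ]
  k <- 1
  while (k <= nrow(scored)) {
    run <- k
    while (run < nrow(scored) &&
           scored$chrom[run + 1] == scored$chrom[k] &&
           scored$call[run + 1] != "none" &&
           scored$call[run + 1] == scored$call[k]) run <- run + 1
    if (run > k && scored$call[k] != "none") {
      row <- scored[k, ]
      row$end_bin <- scored$end_bin[run]
      row$end_idx <- scored$end_idx[run]
      row$n_bins <- sum(scored$n_bins[k:run])
      rows <- (row$start_bin + 1L):row$end_bin
      row$mean_value <- mean(nprofile$values[rows], na.rm = TRUE)
      res <- score_row(row$start_bin, row$end_bin, row$chrom)
      row$segment_fraction <- res$f_obs
      row$z_cbs <- res$z
      row$lor <- res$lor
      row$bcl <- res$bcl
      row$call <- res$call
      row$scope <- res$scope
      merged <- rbind(merged, row)
      k <- run + 1
    } else {
      merged <- rbind(merged, scored[k, ])
      k <- k + 1
    }
  }
  merged <- segments_to_bp(merged, grid)

  merged$reported <- merged$call != "none" &
    merged$size_mb > thresholds$min_cna_mb
  merged$label <- NA_character_
  if (!is.null(cytobands)) {
    for (r in which(merged$call != "none")) {
      merged$label[r] <- tryCatch(
        cytoband_label(cytobands, merged$chrom[r], merged$start_bp[r],
                       merged$end_bp[r], merged$call[r]),
        error = function(e) NA_character_)
    }
  }

  trisomy_of <- function(ch) {
    hit <- merged$call == "gain" & merged$scope == "whole_chromosome" &
      sub("^chr", "", merged$chrom) == ch
    any(hit)
  }
  trisomy <- c(trisomy_13 = trisomy_of("13"), trisomy_18 = trisomy_of("18"),
               trisomy_21 = trisomy_of("21"))
  reported <- merged[merged$reported, , drop = FALSE]
  structure(
    list(sample_id = nprofile$sample_id,
         segments = merged,
         calls = reported,
         trisomy = trisomy,
         total_cna_mb = sum(reported$size_mb),
         cna_positive = nrow(reported) > 0 || any(trisomy),
         estimated_tumor_fraction = tumor_fraction_estimate,
         tumor_fraction_used = tf,
         tumor_fraction_floored = tf_floored,
         thresholds = thresholds),
    class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report '%s': %d segments, %d reported calls, %s%.0f Mb%s>\n",
              x$sample_id, nrow(x$segments), nrow(x$calls),
              if (x$cna_positive) "CNA-positive, " else "CNA-negative, ",
              x$total_cna_mb,
              if (any(x$trisomy))
                paste0(", ", paste(names(x$trisomy)[x$trisomy], collapse = "+"))
              else ""))
  invisible(x)
}

#' Write a per-sample JSON report
#'
#' @param path Output file.
#' @param report A `sample_report`.
#' @export
write_sample_report <- function(path, report) {
  obj <- list(
    sample_id = report$sample_id,
    cna_positive = report$cna_positive,
    total_cna_mb = report$total_cna_mb,
    trisomy_13 = unname(report$trisomy[["trisomy_13"]]),
    trisomy_18 = unname(report$trisomy[["trisomy_18"]]),
    trisomy_21 = unname(report$trisomy[["trisomy_21"]]),
    estimated_tumor_fraction = report$estimated_tumor_fraction,
    tumor_fraction_used = report$tumor_fraction_used,
    tumor_fraction_floored = report$tumor_fraction_floored,
    thresholds = unclass(report$thresholds),
    calls = report$calls[c("chrom", "start_bp", "end_bp", "call", "size_mb",
                           "z_cbs", "lor", "bcl", "label")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
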