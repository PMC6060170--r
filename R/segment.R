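#' CBS tuning parameters
#'
#' @param alpha Permutation significance level for accepting a split.
#' @param n_permutations Permutations per split test.
#' @param min_width Minimum arc width in bins.
#' @param merge_tol Adjacent segments whose means differ by less than this
#'   (log2 units) are merged after splitting.
#' @param seed Seed for the permutation RNG; per-stretch seeds are derived
#'   from it and the stretch coordinates so results are order-independent.
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 1000L, min_width = 3L,
                       merge_tol = 0.05, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_width = as.integer(min_width), merge_tol = merge_tol,
                 seed = as.integer(seed)),
            class = "cbs_params")
}

# Deterministic sub-seed below 2^31.
derive_seed <- function(seed, a = 0, b = 0, c = 0) {
  as.integer((as.numeric(seed) * 1000003 + a * 7919 + b * 104729 + c * 131) %%
               2147483647)
}

#' Maximal circular-arc t statistic
#'
#' Treating `values` circularly, finds the arc `(i, j]` (0-based half-open,
#' i.e. elements `i+1 .. j` in 1-based indexing) maximizing the two-sample
#' t-like statistic `|mean_in - mean_out| / (s * sqrt(1/n_in + 1/n_out))`
#' with pooled standard deviation `s`. Ties are broken by smallest `i`, then
#' smallest `j`; a constant vector returns `T = 0` with arc `(0, min_width]`.
#'
#' @param values Numeric vector (missing values must be removed beforehand).
#' @param min_width Minimum bins in the arc and in its complement.
#' @return List with elements `i`, `j`, `T`.
#' @export
cbs_max_statistic <- function(values, min_width = 3L) {
  if (length(values) < 2 * min_width)
    stop("need at least 2 * min_width values")
  if (anyNA(values)) stop("remove missing values before scanning")
  cbs_scan_cpp(as.numeric(values), as.integer(min_width))
}

# Recursive splitter over a stretch of values; returns boundaries (1-based
# inclusive start/end index pairs).
split_stretch <- function(values, lo, hi, params) {
  n <- hi - lo + 1L
  mw <- params$min_width
  if (n < 2L * mw) return(list(c(lo, hi)))
  x <- values[lo:hi]
  scan <- cbs_scan_cpp(x, mw)
  if (scan$T <= 0) return(list(c(lo, hi)))
  set.seed(derive_seed(params$seed, lo, hi))
  perm <- cbs_perm_cpp(x, mw, params$n_permutations, params$alpha, scan$T)
  if (!perm$significant) return(list(c(lo, hi)))
  i <- scan$i; j <- scan$j
  parts <- list()
  if (i > 0) parts <- c(parts, list(c(lo, lo + i - 1L)))
  parts <- c(parts, list(c(lo + i, lo + j - 1L)))
  if (j < n) parts <- c(parts, list(c(lo + j, hi)))
  if (length(parts) == 1L) return(list(c(lo, hi)))
  out <- list()
  for (p in parts) out <- c(out, split_stretch(values, p[1], p[2], params))
  out
}

#' Circular binary segmentation of one chromosome's values
#'
#' Recursively splits the vector at the maximal arc statistic whenever the
#' permutation p-value is at or below `alpha`, then merges adjacent segments
#' whose means differ by less than `merge_tol`. Deterministic given the
#' params seed.
#'
#' @param values Numeric vector of log2 ratios for one chromosome's unmasked
#'   bins.
#' @param params A `cbs_params`.
#' @return data.frame with columns `start_idx`, `end_idx` (1-based inclusive
#'   indices into `values`), `n_bins`, `mean_value`; rows partition the
#'   vector.
#' @export
cbs_segment <- function(values, params = cbs_params()) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0) return(data.frame(start_idx = integer(), end_idx = integer(),
                                n_bins = integer(), mean_value = numeric()))
  pieces <- split_stretch(values, 1L, n, params)
  pieces <- pieces[order(vapply(pieces, `[`, 0L, 1))]
  seg <- data.frame(start_idx = vapply(pieces, `[`, 0L, 1),
                    end_idx = vapply(pieces, `[`, 0L, 2))
  seg$mean_value <- mapply(function(a, b) mean(values[a:b]),
                           seg$start_idx, seg$end_idx)
  # merge adjacent near-equal segments
  k <- 1L
  while (k < nrow(seg)) {
    if (abs(seg$mean_value[k + 1] - seg$mean_value[k]) < params$merge_tol) {
      a <- seg$start_idx[k]; b <- seg$end_idx[k + 1]
      seg$start_idx[k] <- a; seg$end_idx[k] <- b
      seg$mean_value[k] <- mean(values[a:b])
      seg <- seg[-(k + 1), , drop = FALSE]
    } else k <- k + 1L
  }
  seg$n_bins <- seg$end_idx - seg$start_idx + 1L
  rownames(seg) <- NULL
  seg[c("start_idx", "end_idx", "n_bins", "mean_value")]
}

#' Segment a normalized profile genome-wide
#'
#' Runs CBS per chromosome on the unmasked log2-ratio values and maps the
#' resulting segments back to grid bin indices (half-open, with masked gaps
#' inside a segment included in its genomic span).
#'
#' @param nprofile A `normalized_profile` with `values` filled.
#' @param grid The `bin_grid`.
#' @param params A `cbs_params`.
#' @return data.frame of segments: `chrom`, `start_bin`, `end_bin` (half-open
#'   global grid row indices, 0-based), `start_bp`, `end_bp`, `n_bins`
#'   (unmasked bins used), `mean_value`, `size_mb`.
#' @export
segment_sample <- function(nprofile, grid, params = cbs_params()) {
  out <- list()
  for (ch in unique(grid$chrom)) {
    rows <- which(grid$chrom == ch & nprofile$mask &
                    !is.na(nprofile$values))
    if (!length(rows)) next
    vals <- nprofile$values[rows]
    p <- params
    p$seed <- derive_seed(params$seed, match(ch, unique(grid$chrom)))
    seg <- cbs_segment(vals, p)
    seg$chrom <- ch
    seg$start_bin <- rows[seg$start_idx] - 1L       # 0-based half-open
    seg$end_bin <- rows[seg$end_idx]
    out[[ch]] <- seg
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  segments_to_bp(seg, grid)
}

#' Attach bp coordinates and Mb sizes to segments
#'
#' `start_bp` is the grid start of the first bin, `end_bp` the grid end of
#' the last bin; masked gaps spanned by a segment are included, so
#' `size_mb = (end_bp - start_bp) / 1e6`.
#'
#' @param segments data.frame with `start_bin`, `end_bin` (0-based half-open
#'   grid row indices).
#' @param grid The `bin_grid`.
#' @return The segments with `start_bp`, `end_bp`, `size_mb` columns.
#' @export
segments_to_bp <- function(segments, grid) {
  segments$start_bp <- grid$start[segments$start_bin + 1L]
  segments$end_bp <- grid$end[segments$end_bin]
  segments$size_mb <- (segments$end_bp - segments$start_bp) / 1e6
  segments
}
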