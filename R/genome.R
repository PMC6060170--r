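#' Genome build description
#'
#' A genome build is the coordinate backbone of every profile: an ordered set
#' of chromosomes with their lengths and the subset that counts as autosomal.
#' Only names and lengths are ever used; no sequence is required.
#'
#' @param name Text label for the build.
#' @param chromosomes Named numeric vector of chromosome lengths in bp, in
#'   genome order.
#' @param autosomes Character vector of autosome names (defaults to all
#'   chromosomes not named like X/Y).
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(name, chromosomes, autosomes = NULL) {
  if (length(chromosomes) == 0L) stop("genome has no chromosomes")
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosome names must be present and unique")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(autosomes)) {
    autosomes <- names(chromosomes)[!grepl("(X|Y)$", names(chromosomes))]
  }
  if (!all(autosomes %in% names(chromosomes)))
    stop("autosomes must be a subset of chromosome names")
  structure(
    list(name = name,
         chromosomes = chromosomes,
         autosomes = autosomes),
    class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s': %d chromosomes, %.1f Mb, %d autosomes>\n",
              x$name, length(x$chromosomes), sum(x$chromosomes) / 1e6,
              length(x$autosomes)))
  invisible(x)
}

# hg19 (GRCh37) chromosome lengths, chr1-22, X, Y.
.HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)

#' hg19 genome build
#'
#' Chromosome lengths for hg19 (chr1-22, X, Y) compiled in as constants.
#' @return A `genome_build`.
#' @export
hg19_genome <- function() {
  genome_build("hg19", .HG19_LENGTHS,
               autosomes = names(.HG19_LENGTHS)[1:22])
}

#' Toy genome builder
#'
#' Convenience constructor for small test genomes.
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param name Build label.
#' @param autosomes Optional autosome subset.
#' @return A `genome_build`.
#' @export
toy_genome <- function(lengths, name = "toy", autosomes = NULL) {
  genome_build(name, lengths, autosomes)
}

#' Tile a genome into fixed-width bins
#'
#' Produces the non-overlapping bin grid (default 50 kb) onto which mapped
#' reads are aggregated. Coordinates are 0-based half-open; the last bin of
#' each chromosome may be shorter. Annotation columns (GC fraction,
#' mappability, repeat fraction, exclusion flag) start at neutral defaults
#' until set by an annotation or exclusion step.
#'
#' @param genome A `genome_build`.
#' @param bin_size Bin width in bp (default 50000).
#' @return A `bin_grid`: a data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `mappability`, `repeat_frac`, `excluded`, `autosomal`, carrying the
#'   genome and bin size as attributes.
#' @export
make_bins <- function(genome, bin_size = 50000L) {
  stopifnot(inherits(genome, "genome_build"))
  if (bin_size <= 0) stop("bin_size must be > 0")
  chroms <- names(genome$chromosomes)
  pieces <- lapply(chroms, function(ch) {
    len <- genome$chromosomes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid$gc <- 0.5
  grid$mappability <- 1
  grid$repeat_frac <- 0
  grid$excluded <- FALSE
  grid$autosomal <- grid$chrom %in% genome$autosomes
  rownames(grid) <- NULL
  attr(grid, "genome") <- genome
  attr(grid, "bin_size") <- as.integer(bin_size)
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' @export
print.bin_grid <- function(x, ...) {
  g <- attr(x, "genome")
  cat(sprintf("<bin_grid: %d bins of %d bp on %s (%d excluded)>\n",
              nrow(x), attr(x, "bin_size"), g$name, sum(x$excluded)))
  invisible(x)
}

bin_grid_genome <- function(grid) attr(grid, "genome")

#' Stable fingerprint of a bin grid
#'
#' Used to refuse applying a reference panel or tumour-fraction model to a
#' profile built on a different grid.
#' @param grid A `bin_grid`.
#' @return A hash string.
#' @export
grid_hash <- function(grid) {
  rlang::hash(list(grid$chrom, grid$start, grid$end, attr(grid, "bin_size")))
}

#' Construct a count profile
#'
#' @param sample_id Sample identifier.
#' @param counts Per-bin non-negative integer read counts, aligned to a grid.
#' @param grid The `bin_grid` the counts live on.
#' @param batch_id Optional batch (flow-cell surrogate) label.
#' @param n_dropped Reads that fell on unknown chromosomes (bookkeeping).
#' @return A `count_profile`.
#' @export
count_profile <- function(sample_id, counts, grid, batch_id = NULL,
                          n_dropped = 0L) {
  if (length(counts) != nrow(grid))
    stop("counts length (", length(counts), ") != number of bins (",
         nrow(grid), ")")
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(
    list(sample_id = sample_id, batch_id = batch_id,
         counts = as.numeric(counts), n_dropped = as.integer(n_dropped),
         grid_hash = grid_hash(grid)),
    class = "count_profile")
}

#' @export
print.count_profile <- function(x, ...) {
  cat(sprintf("<count_profile '%s': %d bins, %.0f reads%s>\n",
              x$sample_id, length(x$counts), sum(x$counts),
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Aggregate mapped read positions into bin counts
#'
#' Each read is assigned to the bin containing its 5' start (0-based);
#' single-end data, so reads rather than fragments are counted. Reads on
#' chromosomes absent from the grid are counted and reported as dropped.
#'
#' @param positions data.frame with columns `chrom` and `pos` (0-based start).
#' @param grid A `bin_grid`.
#' @param sample_id Sample identifier for the resulting profile.
#' @param batch_id Optional batch label.
#' @return A `count_profile`.
#' @export
bin_counts_from_positions <- function(positions, grid, sample_id = "sample",
                                      batch_id = NULL) {
  stopifnot(is.data.frame(positions), all(c("chrom", "pos") %in% names(positions)))
  if (nrow(positions) > 0 && any(positions$pos < 0))
    stop("negative read position")
  counts <- numeric(nrow(grid))
  known <- positions$chrom %in% unique(grid$chrom)
  dropped <- sum(!known)
  pos <- positions[known, , drop = FALSE]
  bin_size <- attr(grid, "bin_size")
  if (nrow(pos) > 0) {
    # per-chromosome offset into the grid; bins are fixed-width so the bin
    # index is integer division of the position
    for (ch in unique(pos$chrom)) {
      rows <- which(grid$chrom == ch)
      chlen <- attr(grid, "genome")$chromosomes[[ch]]
      p <- pos$pos[pos$chrom == ch]
      if (any(p >= chlen))
        stop("position beyond end of ", ch)
      idx <- rows[1] + (p %/% bin_size)
      tab <- tabulate(idx, nbins = nrow(grid))
      counts <- counts + tab
    }
  }
  count_profile(sample_id, counts, grid, batch_id = batch_id,
                n_dropped = dropped)
}

# Row indices of usable bins: not excluded, optionally autosomal only.
usable_bins <- function(grid, autosomal_only = FALSE) {
  ok <- !grid$excluded
  if (autosomal_only) ok <- ok & grid$autosomal
  which(ok)
}
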