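#' Read a UCSC-format cytoband table
#'
#' Tab-separated `chrom start end name gieStain` without a header
#' (cytoBand.txt dialect). Records are sorted into per-chromosome order and
#' validated to be contiguous and non-overlapping.
#'
#' @param path Input file.
#' @return data.frame with columns `chrom`, `start`, `end`, `band`, `stain`,
#'   class `cytoband_map`.
#' @export
read_cytobands <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "band", "stain"))
  cytoband_map(df)
}

#' Construct a cytoband map from a data.frame
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `band`, `stain`.
#' @return A `cytoband_map`.
#' @export
cytoband_map <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(df)))
  if (!"stain" %in% names(df)) df$stain <- "gneg"
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("cytobands on ", ch, " are not contiguous")
  }
  rownames(df) <- NULL
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Cytoband label for a genomic interval
#'
#' Produces the reporting-style label for a called segment, e.g.
#' "19p13.3-19p13.11 gain" or, when a single band is overlapped,
#' "11p15.4 loss". The chromosome prefix drops any leading "chr".
#'
#' @param bands A `cytoband_map`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param direction "gain" or "loss".
#' @return Label string.
#' @export
cytoband_label <- function(bands, chrom, start, end, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  b <- bands[bands$chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0)
    stop("no cytobands for chromosome ", chrom)
  if (end <= min(b$start) || start >= max(b$end))
    stop("interval outside chromosome ", chrom)
  hit <- b[b$end > start & b$start < end, , drop = FALSE]
  if (nrow(hit) == 0) stop("interval overlaps no band on ", chrom)
  cn <- sub("^chr", "", chrom)
  if (nrow(hit) == 1)
    sprintf("%s%s %s", cn, hit$band[1], direction)
  else
    sprintf("%s%s-%s%s %s", cn, hit$band[1], cn, hit$band[nrow(hit)], direction)
}

#' Synthetic cytoband map for a toy genome
#'
#' Builds a plausible banding pattern: a centromere at 40% of each chromosome,
#' p bands numbered outward from the centromere toward the telomere and q
#' bands outward toward the long-arm end, with roughly `band_mb`-sized bands.
#' Useful to exercise labelling on simulated genomes.
#'
#' @param genome A `genome_build`.
#' @param band_mb Approximate band size in Mb.
#' @return A `cytoband_map`.
#' @export
synthetic_cytobands <- function(genome, band_mb = 10) {
  rows <- list()
  for (ch in names(genome$chromosomes)) {
    len <- genome$chromosomes[[ch]]
    cen <- round(0.4 * len)
    bw <- band_mb * 1e6
    p_edges <- unique(c(rev(seq(cen, 0, by = -bw)), 0))
    p_edges <- sort(unique(p_edges))
    q_edges <- unique(c(seq(cen, len, by = bw), len))
    q_edges <- sort(unique(q_edges))
    np <- length(p_edges) - 1
    # p bands numbered outward from the centromere, so coordinate order
    # (telomere -> centromere) runs pN ... p11
    p_names <- paste0("p", 10 + rev(seq_len(np)))
    nq <- length(q_edges) - 1
    q_names <- paste0("q", 10 + seq_len(nq))
    rows[[ch]] <- data.frame(
      chrom = ch,
      start = c(p_edges[-length(p_edges)], q_edges[-length(q_edges)]),
      end = c(p_edges[-1], q_edges[-1]),
      band = c(p_names, q_names),
      stain = "gneg", stringsAsFactors = FALSE)
  }
  cytoband_map(do.call(rbind, rows))
}
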