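#' Write a per-sample bin-count table
#'
#' TSV dialect: header `chrom start end gc mappability repeat_frac count`,
#' with `#`-prefixed comment lines; the sample and batch ids are stored in
#' comments so a read round-trips the profile.
#'
#' @param path Output file.
#' @param grid A `bin_grid`.
#' @param profile A `count_profile` on that grid.
#' @export
write_bin_counts <- function(path, grid, profile) {
  stopifnot(inherits(profile, "count_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s", profile$sample_id), con)
  if (!is.null(profile$batch_id))
    writeLines(sprintf("# batch_id=%s", profile$batch_id), con)
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   gc = grid$gc, mappability = grid$mappability,
                   repeat_frac = grid$repeat_frac, count = profile$counts)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample bin-count table
#'
#' @param path Input TSV (dialect of [write_bin_counts()]).
#' @param genome Optional `genome_build`; reconstructed from the bins when
#'   absent (chromosome length = last bin end).
#' @return A list with elements `grid` (a `bin_grid`) and `profile`
#'   (a `count_profile`).
#' @export
read_bin_counts <- function(path, genome = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^#\\s*%s=", key), "", hit[1]) else NULL
  }
  sample_id <- get_meta("sample_id")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  body <- which(!startsWith(lines, "#"))
  df <- utils::read.delim(textConnection(lines[body]), stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "mappability", "repeat_frac", "count")
  if (!all(need %in% names(df)))
    stop("bin-count file ", path, " missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!complete.cases(df[need]) | df$count < 0)
  if (length(bad))
    stop("malformed bin-count rows in ", path, " at line(s): ",
         paste(body[bad + 1L], collapse = ", "))
  if (is.null(genome)) {
    lens <- vapply(split(df$end, df$chrom), max, numeric(1))
    lens <- lens[unique(df$chrom)]  # preserve file order
    genome <- genome_build(paste0("from:", basename(path)), lens)
  }
  bin_size <- max(df$end - df$start)
  grid <- make_bins(genome, bin_size)
  if (nrow(grid) != nrow(df) ||
      any(grid$chrom != df$chrom | grid$start != df$start | grid$end != df$end)) {
    i <- which(grid$chrom != df$chrom | grid$start != df$start |
                 grid$end != df$end)[1]
    stop("bin grid in ", path, " does not tile the genome; first mismatch at ",
         "bin ", i)
  }
  grid$gc <- df$gc
  grid$mappability <- df$mappability
  grid$repeat_frac <- df$repeat_frac
  list(grid = grid,
       profile = count_profile(sample_id, df$count, grid,
                               batch_id = get_meta("batch_id")))
}

#' Check that panel samples share one bin grid
#'
#' @param grids List of `bin_grid`s.
#' @return TRUE invisibly; errors naming the first mismatching bin otherwise.
#' @export
check_same_grid <- function(grids) {
  ref <- grids[[1]]
  for (k in seq_along(grids)[-1]) {
    g <- grids[[k]]
    if (nrow(g) != nrow(ref))
      stop("panel grids differ in bin count (", nrow(ref), " vs ", nrow(g), ")")
    bad <- which(g$chrom != ref$chrom | g$start != ref$start | g$end != ref$end)
    if (length(bad))
      stop("panel grid mismatch at bin ", bad[1], " (",
           ref$chrom[bad[1]], ":", ref$start[bad[1]], "-", ref$end[bad[1]],
           " vs ", g$chrom[bad[1]], ":", g$start[bad[1]], "-", g$end[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Read mapped read positions from BED or SAM
#'
#' Only the chromosome and 0-based start of each record are used (5' read
#' starts of single-end data). SAM: header lines are skipped, unmapped reads
#' (flag 0x4) dropped, POS converted from 1-based.
#'
#' @param path Input file.
#' @param format "bed" or "sam"; guessed from the extension by default.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_positions <- function(path, format = c("auto", "bed", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  lines <- readLines(path)
  if (format == "bed") {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(chrom = vapply(parts, `[[`, "", 1),
               pos = as.numeric(vapply(parts, `[[`, "", 2)),
               stringsAsFactors = FALSE)
  } else {
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    flag <- as.integer(vapply(parts, `[[`, "", 2))
    keep <- bitwAnd(flag, 4L) == 0L
    data.frame(chrom = vapply(parts, `[[`, "", 3)[keep],
               pos = as.numeric(vapply(parts, `[[`, "", 4)[keep]) - 1,
               stringsAsFactors = FALSE)
  }
}

#' Write segment calls as a SEG-like TSV
#'
#' Columns: `sample chrom start end n_bins log2_ratio segment_fraction z_cbs
#' lor bcl call size_mb label`.
#'
#' @param path Output file.
#' @param calls data.frame of segment calls (see [call_sample()]).
#' @export
write_seg <- function(path, calls) {
  cols <- c("sample", "chrom", "start", "end", "n_bins", "log2_ratio",
            "segment_fraction", "z_cbs", "lor", "bcl", "call", "size_mb",
            "label")
  missing <- setdiff(cols, names(calls))
  if (length(missing))
    stop("calls table missing columns: ", paste(missing, collapse = ", "))
  write.table(calls[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-like TSV written by [write_seg()]
#' @param path Input file.
#' @return data.frame of segment calls.
#' @export
read_seg <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.CANCER_TYPES <- c("ovarian", "cervical", "endometrial")

#' Read a cohort metadata table
#'
#' TSV with columns `sample_id cancer_type figo_stage pfs_months pfs_event
#' os_months os_event`, plus optional `cna_positive` and `total_cna_mb`
#' columns for pre-computed calls. FIGO stage may carry a sub-stage letter
#' (e.g. IIIB); the major stage I-IV is extracted and the early (I-II) /
#' advanced (III-IV) grouping derived.
#'
#' @param path Input TSV.
#' @return data.frame of cohort records with derived `figo_major` and
#'   `stage_group` columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "#")
  need <- c("sample_id", "cancer_type", "figo_stage", "pfs_months",
            "pfs_event", "os_months", "os_event")
  if (!all(need %in% names(df)))
    stop("cohort file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  major <- sub("^(IV|III|II|I).*$", "\\1", df$figo_stage)
  suffix <- substring(df$figo_stage, nchar(major) + 1)
  bad <- which(!(major %in% c("I", "II", "III", "IV")) |
                 !(suffix %in% c("", "A", "B", "C")))
  if (length(bad))
    stop("invalid FIGO stage in cohort row(s): ",
         paste(bad, collapse = ", "), " (", df$figo_stage[bad[1]], ")")
  badtype <- which(!df$cancer_type %in% .CANCER_TYPES)
  if (length(badtype))
    stop("unknown cancer_type in cohort row(s): ",
         paste(badtype, collapse = ", "))
  if (any(df$pfs_months < 0 | df$os_months < 0, na.rm = TRUE))
    stop("negative survival time in cohort")
  df$figo_major <- major
  df$stage_group <- ifelse(major %in% c("I", "II"), "early", "advanced")
  if (!"cna_positive" %in% names(df)) df$cna_positive <- NA
  if (!"total_cna_mb" %in% names(df)) df$total_cna_mb <- NA_real_
  df$cna_positive <- as.logical(df$cna_positive)
  df
}

#' Write a cohort metadata table
#' @param path Output TSV.
#' @param records Cohort data.frame (as from [read_cohort()]).
#' @export
write_cohort <- function(path, records) {
  cols <- c("sample_id", "cancer_type", "figo_stage", "pfs_months",
            "pfs_event", "os_months", "os_event")
  extra <- intersect(c("cna_positive", "total_cna_mb"), names(records))
  write.table(records[c(cols, extra)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
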