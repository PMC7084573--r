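#' Build genomic intervals from BED-style coordinates
#'
#' Constructs a [GenomicRanges::GRanges] from 0-based half-open coordinates,
#' the native convention of BED/narrowPeak files. Internally all regions are
#' held as `GRanges` (1-based closed); the +1 shift happens here and in the
#' writers, so half-open boundary semantics (`[100,200)` does not touch
#' `[200,300)`) are preserved exactly.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return `GRanges` of the same length.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start < 0L)) stop("start must be >= 0")
  if (any(start >= end)) stop("start must be < end (0-based half-open)")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Pairwise half-open overlap test
#'
#' `TRUE` iff the intervals share a chromosome and overlap by >= 1 bp under
#' half-open semantics. Vectors are recycled pairwise.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  same & IRanges::poverlaps(IRanges::ranges(a), IRanges::ranges(b))
}

#' Read called peaks
#'
#' Parses ENCODE narrowPeak (BED6+4) or plain BED6 into a `GRanges` with a
#' `summit` metadata column (0-based absolute position, as in narrowPeak).
#' For narrowPeak the summit is `start + offset` (column 10); an offset of
#' -1, and all BED6 records, fall back to the interval midpoint. Records
#' whose declared summit lies outside the interval are dropped with a
#' warning; malformed coordinates raise an error naming the line.
#'
#' @param path file path, tab-separated.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @return `GRanges` with metadata columns `name`, `score`, `summit`
#'   (0-based), and for narrowPeak also `signalValue`, `pValue`, `qValue`,
#'   `peak_offset`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  need <- if (format == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("parse error at line %d of %s: expected >= %d fields, got %d",
                 lineno[which(nf < need)[1]], path, need, min(nf)))
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d of %s: invalid coordinates '%s\t%s'",
                 lineno[bad[1]], path, m[bad[1], 2], m[bad[1], 3]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  score[is.na(score)] <- 0
  if (any(score < 0))
    stop(sprintf("parse error at line %d of %s: negative score",
                 lineno[which(score < 0)[1]], path))
  mid <- (start + end) %/% 2L
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.integer(m[, 10]))
    if (anyNA(off))
      stop(sprintf("parse error at line %d of %s: non-integer summit offset",
                   lineno[which(is.na(off))[1]], path))
    summit <- ifelse(off == -1L, mid, start + off)
  } else {
    summit <- mid
  }
  outside <- summit < start | summit >= end
  if (any(outside)) {
    warning(sprintf("%d record(s) in %s rejected: summit outside interval",
                    sum(outside), path))
  }
  ok <- !outside
  gr <- GenomicRanges::GRanges(
    m[ok, 1],
    IRanges::IRanges(start[ok] + 1L, end[ok]),
    strand = ifelse(m[ok, 6] %in% c("+", "-"), m[ok, 6], "*")
  )
  gr$name <- m[ok, 4]
  gr$score <- score[ok]
  gr$summit <- as.integer(summit[ok])
  if (format == "narrowPeak") {
    gr$signalValue <- as.numeric(m[ok, 7])
    gr$pValue <- as.numeric(m[ok, 8])
    gr$qValue <- as.numeric(m[ok, 9])
    gr$peak_offset <- as.integer(m[ok, 10])
  }
  gr
}

#' Write peaks back to narrowPeak / BED6
#'
#' Inverse of [read_peaks()]: emits 0-based half-open coordinates. Files
#' written by this function re-read and re-write byte-identically.
#'
#' @param peaks `GRanges` as returned by [read_peaks()] (or with compatible
#'   metadata columns).
#' @param path output path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  nm <- if (!is.null(peaks$name)) peaks$name else paste0("peak_", seq_along(peaks))
  sc <- if (!is.null(peaks$score)) peaks$score else 0
  str <- as.character(GenomicRanges::strand(peaks))
  str[str == "*"] <- "."
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, start0, end0, nm,
                     num_fmt(sc), str)
  } else {
    sv <- if (!is.null(peaks$signalValue)) peaks$signalValue else sc
    pv <- if (!is.null(peaks$pValue)) peaks$pValue else -1
    qv <- if (!is.null(peaks$qValue)) peaks$qValue else -1
    off <- if (!is.null(peaks$peak_offset)) peaks$peak_offset
           else peaks$summit - start0
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
                     chrom, start0, end0, nm, num_fmt(sc), str,
                     num_fmt(sv), num_fmt(pv), num_fmt(qv), as.integer(off))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 blacklist
#'
#' @param path BED3 file of regions to exclude.
#' @return `GRanges`.
#' @export
read_blacklist <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  genomic_interval(df[[1]], df[[2]], df[[3]])
}

#' Remove blacklisted peaks
#'
#' Drops every peak that overlaps a blacklist interval by >= 1 bp; input
#' order of the survivors is preserved.
#'
#' @param peaks `GRanges` of peaks.
#' @param blacklist `GRanges` of excluded regions (may be empty).
#' @return filtered `GRanges`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist)]
}

#' Coverage track container
#'
#' Couples per-chromosome read-count intervals (a `GRanges` whose `score`
#' holds the number of reads assigned to each interval) with the library
#' size used for per-million normalisation. The library size comes from the
#' sequencing run, not from the stored intervals, so no consistency between
#' the two is required.
#'
#' @param gr `GRanges` with a non-negative numeric `score` column; intervals
#'   must be disjoint within each chromosome.
#' @param total_mapped_reads positive number, the library size.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(gr, total_mapped_reads) {
  if (is.null(gr$score) || any(gr$score < 0))
    stop("coverage track needs a non-negative 'score' column")
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0)
    stop("total_mapped_reads must be positive")
  gr <- GenomicRanges::sort(gr)
  if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0)
    stop("coverage intervals must be disjoint within each chromosome")
  structure(list(gr = gr, total_mapped_reads = as.numeric(total_mapped_reads)),
            class = "coverage_track")
}

#' Read a 4-column bedGraph as a coverage track
#'
#' The bedGraph value is interpreted as the number of reads whose 5' ends
#' fall in the interval; the library size is supplied separately (it is a
#' property of the sequencing run, not of the file).
#'
#' @param path bedGraph path.
#' @param total_mapped_reads library size.
#' @return `coverage_track`.
#' @export
read_bedgraph <- function(path, total_mapped_reads) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(gr, total_mapped_reads)
}

#' Write a coverage track as bedGraph
#'
#' @param track `coverage_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track$gr
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   num_fmt(gr$score))
  writeLines(lines, path)
  invisible(path)
}

#' Summit-centred windows
#'
#' Returns the half-open window `[summit - h, summit + h)` (length `2 h` bp)
#' around each peak's 0-based summit.
#'
#' @param peaks `GRanges` with a `summit` metadata column (0-based).
#' @param halfwidth positive half-width in bp.
#' @return `GRanges` of windows carrying the same metadata.
#' @export
summit_window <- function(peaks, halfwidth) {
  stopifnot(halfwidth > 0, !is.null(peaks$summit))
  s0 <- peaks$summit
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(pmax(s0 - halfwidth + 1L, 1L),
                                                 s0 + halfwidth))
  S4Vectors::mcols(win) <- S4Vectors::mcols(peaks)
  win
}

#' Summit RPKM from a coverage track
#'
#' Computes reads per kilobase per million mapped reads over summit windows
#' (or over the given regions when `halfwidth` is `NULL`):
#' `RPKM = reads / (length/1000) / (library/1e6)`. A stored read interval
#' contributes its full read count to a window if it overlaps it by >= 1 bp
#' (`mode = "overlap"`, default) or if its 5' end lies inside
#' (`mode = "start"`); no fractional weighting is applied.
#'
#' @param track `coverage_track`.
#' @param regions `GRanges`; with `halfwidth` set they must carry `summit`.
#' @param halfwidth window half-width in bp, or `NULL` to use the regions
#'   as-is.
#' @param mode read-attribution rule, see above.
#' @return numeric vector of RPKM values, one per region.
#' @export
compute_rpkm <- function(track, regions, halfwidth = NULL,
                         mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  if (track$total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  win <- if (!is.null(halfwidth)) summit_window(regions, halfwidth) else regions
  counts <- window_read_counts(track, win, mode)
  counts / (GenomicRanges::width(win) / 1000) / (track$total_mapped_reads / 1e6)
}

# Raw read counts per window under the chosen attribution rule.
window_read_counts <- function(track, win, mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  src <- track$gr
  if (mode == "start") src <- GenomicRanges::resize(src, 1L, fix = "start")
  hits <- GenomicRanges::findOverlaps(win, src)
  counts <- rep(0, length(win))
  if (length(hits) > 0) {
    agg <- tapply(track$gr$score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  counts
}

#' Tag density of regions (rpm/bp)
#'
#' Reads per million mapped reads per base pair, the signal on which
#' stitched enhancer candidates are ranked.
#'
#' @inheritParams compute_rpkm
#' @return numeric vector, one density per region.
#' @export
tag_density <- function(track, regions, mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  counts <- window_read_counts(track, regions, mode)
  counts / GenomicRanges::width(regions) / (track$total_mapped_reads / 1e6)
}
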