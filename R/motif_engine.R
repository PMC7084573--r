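DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' An `L x 4` probability matrix over (A, C, G, T) with a background
#' distribution. Rows are regularised with a pseudocount of 0.001 and
#' renormalised so every entry is strictly positive.
#'
#' @param id motif identifier.
#' @param mat numeric `L x 4` matrix of per-position counts or
#'   probabilities; columns in A, C, G, T order.
#' @param background background base probabilities (defaults to uniform).
#' @param pseudocount added to each entry before row renormalisation.
#' @return object of class `pwm` with elements `id`, `mat` (probabilities),
#'   `lods` (log2-odds against the background) and `background`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  if (any(rowSums(mat) <= 0)) stop("every PWM row needs positive mass")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  p <- mat + pseudocount
  p <- p / rowSums(p)
  colnames(p) <- DNA_BASES
  structure(list(id = id, mat = p, lods = log2(sweep(p, 2, background, "/")),
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d bp), consensus %s, max score %.2f bits\n",
              x$id, nrow(x$mat), pwm_consensus(x), pwm_max_score(x)))
  invisible(x)
}

#' Length of a PWM in base pairs
#' @param x `pwm`.
#' @return integer.
#' @export
pwm_length <- function(x) nrow(x$mat)

#' Consensus sequence of a PWM (per-position argmax)
#' @param x `pwm`.
#' @return character string of length `pwm_length(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$mat, 1, which.max)], collapse = "")
}

#' Maximum attainable log2-odds score of a PWM
#' @param x `pwm`.
#' @return numeric, bits.
#' @export
pwm_max_score <- function(x) sum(apply(x$lods, 1, max))

#' Build a PWM from a consensus string
#'
#' Convenience constructor used by the synthetic-data generator: consensus
#' bases receive `strength` probability (the rest split evenly); `N`
#' positions are uniform.
#'
#' @param id motif identifier.
#' @param consensus string over A/C/G/T/N.
#' @param strength probability of the consensus base.
#' @return `pwm`.
#' @export
consensus_pwm <- function(id, consensus, strength = 0.88) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c(DNA_BASES, "N"))) stop("consensus must be A/C/G/T/N")
  rows <- t(vapply(bases, function(b) {
    if (b == "N") rep(0.25, 4)
    else ifelse(DNA_BASES == b, strength, (1 - strength) / 3)
  }, numeric(4)))
  pwm(id, rows)
}

#' Read a JASPAR-style PFM file
#'
#' Accepts the 4-row JASPAR text format: an optional `>` header line, then
#' one row per base, either `A [ 12 0 3 ... ]` or a bare whitespace-
#' separated row (rows in A, C, G, T order). Counts or probabilities are
#' converted to a regularised probability matrix.
#'
#' @param path PFM file path.
#' @param id motif id; default is the header word or the file name.
#' @return `pwm`.
#' @export
read_pfm <- function(path, id = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    if (is.null(id))
      id <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) != 4)
    stop("PFM must have exactly 4 matrix rows (A, C, G, T); got ",
         length(lines))
  rows <- lapply(lines, function(ln) {
    ln <- sub("^[ACGTacgt]\\s*", "", ln)
    ln <- gsub("\\[|\\]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric PFM entry in ", path)
    vals
  })
  if (length(unique(lengths(rows))) != 1)
    stop("PFM rows have unequal length in ", path)
  mat <- t(do.call(rbind, rows))  # positions x 4
  if (any(mat < 0)) stop("negative PFM entry in ", path)
  pwm(id, mat)
}

#' Write a PWM in JASPAR PFM format
#'
#' @param x `pwm` (probabilities are written).
#' @param path output path.
#' @export
write_pfm <- function(x, path) {
  lines <- c(sprintf(">%s", x$id),
             vapply(seq_len(4), function(j) {
               sprintf("%s  [ %s ]", DNA_BASES[j],
                       paste(formatC(x$mat[, j], digits = 6, format = "g"),
                             collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param seq character string over A/C/G/T/N.
#' @return character string.
#' @export
revcomp <- function(seq) {
  paste(rev(REVCOMP[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the summed log2-odds
#' `sum_j log2(p_j(base) / bg(base))`; the minus strand scores the reverse
#' complement of each window. Windows containing `N` are skipped. No
#' thresholding is applied here.
#'
#' @param seq character string over A/C/G/T/N (or a
#'   [Biostrings::DNAString]).
#' @param x `pwm`.
#' @return data.frame with columns `offset` (0-based window start in `seq`),
#'   `strand` and `score` (bits).
#' @export
scan_pwm <- function(seq, x) {
  seq <- toupper(as.character(seq))
  L <- pwm_length(x)
  n <- nchar(seq)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)  # N -> NA
  noff <- n - L + 1L
  per_pos <- function(lods) {
    m <- matrix(vapply(seq_len(L), function(j) {
      lods[j, ][idx[seq_len(noff) + j - 1L]]
    }, numeric(noff)), nrow = noff)
    rowSums(m)
  }
  plus <- per_pos(x$lods)
  # minus strand: score of the reverse complement of the same window;
  # complementing swaps A<->T and C<->G, i.e. column reversal, and reversing
  # the window flips the row order.
  minus <- per_pos(x$lods[rev(seq_len(L)), rev(seq_len(4)), drop = FALSE])
  out <- data.frame(offset = rep(0:(noff - 1L), 2L),
                    strand = rep(c("+", "-"), each = noff),
                    score = c(plus, minus), stringsAsFactors = FALSE)
  out[!is.na(out$score), , drop = FALSE]
}

# Extract the sequence of [center0 - halfwidth, center0 + halfwidth) from a
# DNAStringSet genome, clipped to the chromosome; center0 is 0-based.
extract_window_seq <- function(genome, chrom, center0, halfwidth) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  from <- max(center0 - halfwidth + 1L, 1L)
  to <- min(center0 + halfwidth, len)
  if (from > to) return("")
  as.character(Biostrings::subseq(genome[[chrom]], from, to))
}

#' Top motif score around a summit
#'
#' Maximum scan score over both strands within
#' `[summit - halfwidth, summit + halfwidth)`. Returns `-Inf` when no valid
#' window exists (region shorter than the motif, or all windows contain N).
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param summit 0-based summit position.
#' @param x `pwm`.
#' @param halfwidth half-width of the scanned window, bp.
#' @return numeric scalar in bits, possibly `-Inf`.
#' @export
top_motif_score <- function(genome, chrom, summit, x, halfwidth) {
  seq <- extract_window_seq(genome, chrom, summit, halfwidth)
  hits <- scan_pwm(seq, x)
  if (nrow(hits) == 0) return(-Inf)
  max(hits$score)
}

#' Top motif scores for a set of peaks
#'
#' Vectorised [top_motif_score()] over the summits of `peaks` for each PWM
#' in a list.
#'
#' @param genome `DNAStringSet`.
#' @param peaks `GRanges` with a 0-based `summit` column.
#' @param pwms named list of `pwm` objects.
#' @param halfwidth window half-width, bp.
#' @return numeric matrix, peaks x motifs.
#' @export
top_motif_scores <- function(genome, peaks, pwms, halfwidth) {
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  out <- vapply(pwms, function(p) {
    vapply(seq_along(peaks), function(i) {
      top_motif_score(genome, chroms[i], peaks$summit[i], p, halfwidth)
    }, numeric(1))
  }, numeric(length(peaks)))
  out <- matrix(out, nrow = length(peaks),
                dimnames = list(peaks$name, names(pwms)))
  out
}

#' Motif hits in summit-centred frames
#'
#' Scans the `frame`-bp window centred on each peak summit with each PWM
#' and keeps hits at or above the per-PWM threshold.
#'
#' @param genome `DNAStringSet`.
#' @param peaks `GRanges` with 0-based `summit`.
#' @param pwms named list of `pwm`.
#' @param frame frame length in bp (window is `[summit - frame/2,
#'   summit + frame/2)`).
#' @param thresholds named numeric vector of score thresholds (bits) per
#'   PWM id.
#' @return data.frame with `region` (peak index), `pwm`, `offset` (0-based,
#'   relative to frame start), `strand`, `score`.
#' @export
motif_hits <- function(genome, peaks, pwms, frame, thresholds) {
  half <- frame %/% 2L
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  res <- list()
  for (pid in names(pwms)) {
    thr <- thresholds[[pid]]
    if (is.null(thr) || !is.finite(thr))
      stop("missing/non-finite threshold for PWM ", pid)
    for (i in seq_along(peaks)) {
      seq <- extract_window_seq(genome, chroms[i], peaks$summit[i], half)
      hits <- scan_pwm(seq, pwms[[pid]])
      hits <- hits[hits$score >= thr, , drop = FALSE]
      if (nrow(hits) > 0) {
        hits$region <- i
        hits$pwm <- pid
        res[[length(res) + 1L]] <- hits
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(region = integer(0), pwm = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("region", "pwm", "offset", "strand", "score")]
}

#' Binned motif distribution matrix
#'
#' Counts thresholded hits in `window`-bp bins across the `frame`-bp
#' summit-centred frames (50 bins of 30 bp at the defaults). A hit is
#' assigned by its centre, `offset + floor(L/2)` relative to the frame
#' start; hits whose centre falls outside the frame are dropped.
#'
#' @param hits data.frame from [motif_hits()].
#' @param n_regions number of scanned regions.
#' @param pwms named list of `pwm` (needed for motif lengths).
#' @param frame,window frame and bin width in bp; `frame` must be divisible
#'   by `window`.
#' @return 3-d array `[region, bin, pwm]` of hit counts.
#' @export
motif_distribution <- function(hits, n_regions, pwms, frame, window) {
  if (frame %% window != 0) stop("frame must be divisible by window")
  nbin <- frame %/% window
  arr <- array(0L, dim = c(n_regions, nbin, length(pwms)),
               dimnames = list(NULL, paste0("bin", seq_len(nbin) - 1L),
                               names(pwms)))
  if (nrow(hits) > 0) {
    L <- vapply(pwms, pwm_length, integer(1))[hits$pwm]
    center <- hits$offset + L %/% 2L
    bin <- floor(center / window)
    keep <- bin >= 0 & bin < nbin
    for (k in which(keep)) {
      arr[hits$region[k], bin[k] + 1L, hits$pwm[k]] <-
        arr[hits$region[k], bin[k] + 1L, hits$pwm[k]] + 1L
    }
  }
  arr
}

#' Motif presence matrix
#'
#' @param scores matrix from [top_motif_scores()].
#' @param thresholds named numeric vector per PWM id.
#' @return logical matrix, peaks x motifs: top score >= threshold.
#' @export
motif_presence <- function(scores, thresholds) {
  thr <- thresholds[colnames(scores)]
  if (anyNA(thr)) stop("thresholds missing for some PWMs")
  t(t(scores) >= unlist(thr))
}

#' Sub-cluster regions by motif presence pattern
#'
#' Labels every region by its binary presence/absence pattern over an
#' ordered subset of motifs (e.g. `"10"` = first motif present, second
#' absent) and returns the lexicographic ordering used for heat-map export.
#'
#' @param presence logical matrix, regions x motifs.
#' @param subset character vector of motif ids in priority order.
#' @return list with `label` (character per region) and `order`
#'   (permutation sorting regions by pattern, descending so
#'   all-present sorts first).
#' @export
cluster_by_motif_presence <- function(presence, subset) {
  if (!all(subset %in% colnames(presence)))
    stop("unknown motif id(s) in subset")
  pat <- apply(presence[, subset, drop = FALSE], 1,
               function(r) paste(as.integer(r), collapse = ""))
  list(label = pat, order = order(pat, decreasing = TRUE))
}

#' Known-motif enrichment (binomial tail)
#'
#' A region "has" the motif iff its top score is at or above the threshold.
#' The background hit fraction is treated as a rate and the one-sided
#' p-value is the binomial upper tail `P(X >= k_target)` at that rate. A
#' zero background rate with target hits present is replaced by
#' `1 / (n_background + 1)`.
#'
#' @param target_scores numeric vector of top scores in target regions.
#' @param background_scores numeric vector of top scores in background
#'   regions (non-empty).
#' @param threshold score threshold in bits (finite).
#' @return list with `target_fraction`, `background_fraction`, `p_value`,
#'   `n_target`, `n_background`.
#' @export
enrichment_test <- function(target_scores, background_scores, threshold) {
  if (length(target_scores) == 0) stop("empty target set")
  if (length(background_scores) == 0) stop("empty background set")
  if (!is.finite(threshold)) stop("threshold must be finite")
  k <- sum(target_scores >= threshold)
  n <- length(target_scores)
  bg_frac <- mean(background_scores >= threshold)
  rate <- bg_frac
  if (rate == 0 && k > 0) rate <- 1 / (length(background_scores) + 1)
  p <- if (k == 0) 1 else stats::pbinom(k - 1, n, rate, lower.tail = FALSE)
  list(target_fraction = k / n, background_fraction = bg_frac,
       p_value = p, n_target = n, n_background = length(background_scores))
}

#' Select a motif score threshold from a score distribution
#'
#' Heuristic for placing the threshold just before the last markedly high
#' peak of the score histogram: scores are binned at `bin_width` bits, the
#' rightmost local maximum whose height is at least `peak_ratio` times the
#' median bin height (empty bins included) and holds at least 2 scores is
#' found, and the left edge of that bin is returned. A manual override
#' takes precedence.
#'
#' @param scores numeric vector of top scores (>= 20 values unless a manual
#'   override is given); non-finite values are ignored.
#' @param bin_width histogram bin width in bits.
#' @param manual optional manual threshold; returned as-is with provenance
#'   `"manual"`.
#' @param peak_ratio multiple of the median bin height that makes a mode
#'   "markedly high".
#' @return list with `threshold` (bits) and `provenance` (`"manual"` or
#'   `"heuristic"`).
#' @export
select_score_threshold <- function(scores, bin_width = 0.5, manual = NULL,
                                   peak_ratio = 2) {
  if (!is.null(manual)) {
    if (!is.finite(manual)) stop("manual threshold must be finite")
    return(list(threshold = as.numeric(manual), provenance = "manual"))
  }
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20)
    stop("fewer than 20 finite scores; supply a manual threshold")
  lo <- floor(min(scores) / bin_width) * bin_width
  hi <- ceiling(max(scores) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE)
  counts <- h$counts
  med <- stats::median(counts)
  floor_height <- max(peak_ratio * med, 2)
  nb <- length(counts)
  is_peak <- vapply(seq_len(nb), function(i) {
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < nb) counts[i + 1] else -Inf
    counts[i] >= left && counts[i] >= right && counts[i] >= floor_height
  }, logical(1))
  if (!any(is_peak)) {
    # no markedly high mode: fall back to the tallest bin
    pick <- which.max(counts)
  } else {
    pick <- max(which(is_peak))
  }
  list(threshold = h$breaks[pick], provenance = "heuristic")
}
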