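#' Classify constituents of two cistromes
#'
#' A constituent is SHARED when a peak of one cell line overlaps (>= 1 bp)
#' a peak of the other; overlapping groups are merged into one shared
#' constituent whose region is the hull of its members and whose summit is
#' the summit of the member with the higher own-line summit RPKM. Peaks
#' without a cross-line overlap keep their cell line of origin. The output
#' is sorted by the heat-map sort key
#' `log2(RPKM_B + eps) - log2(RPKM_A + eps)` (eps = 0.1), so A-specific
#' constituents sort first.
#'
#' @param peaks_A,peaks_B blacklist-filtered `GRanges` of master-TF peaks
#'   (with 0-based `summit`).
#' @param track_A,track_B master-TF `coverage_track` per cell line, used
#'   for the summit RPKM values; may be `NULL`, in which case the peak
#'   `score` column is used instead.
#' @param config `analysis_config` (RPKM half-width, pseudocount).
#' @return `GRanges` of constituents with metadata `label` (one of
#'   `A_SPECIFIC`, `SHARED`, `B_SPECIFIC`), `summit`, `rpkm_A`, `rpkm_B`
#'   and `sort_key`, sorted by `sort_key`.
#' @export
classify_constituents <- function(peaks_A, peaks_B, track_A = NULL,
                                  track_B = NULL,
                                  config = analysis_config()) {
  h <- config$rpkm_halfwidth_bp
  eps <- config$fpkm_pseudocount
  own_rpkm <- function(peaks, track) {
    if (length(peaks) == 0) return(numeric(0))
    if (is.null(track)) as.numeric(peaks$score)
    else compute_rpkm(track, peaks, halfwidth = h,
                      mode = config$read_count_mode)
  }
  rA <- own_rpkm(peaks_A, track_A)
  rB <- own_rpkm(peaks_B, track_B)
  nA <- length(peaks_A); nB <- length(peaks_B)
  all_peaks <- suppressWarnings(
    c(GenomicRanges::granges(peaks_A, use.mcols = FALSE),
      GenomicRanges::granges(peaks_B, use.mcols = FALSE)))
  all_peaks$summit <- c(if (nA) peaks_A$summit else integer(0),
                        if (nB) peaks_B$summit else integer(0))
  all_peaks$own_rpkm <- c(rA, rB)
  all_peaks$side <- rep(c("A", "B"), c(nA, nB))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks_A, peaks_B, ignore.strand = TRUE))
  root <- uf_union_all(nA + nB, S4Vectors::queryHits(ov),
                       S4Vectors::subjectHits(ov) + nA)
  comp <- split(seq_len(nA + nB), root)
  regions <- list(); meta <- list()
  for (members in comp) {
    sides <- all_peaks$side[members]
    hull <- range(all_peaks[members], ignore.strand = TRUE)
    if (length(unique(sides)) == 2) {
      label <- "SHARED"
      best <- members[which.max(all_peaks$own_rpkm[members])]
      summit <- all_peaks$summit[best]
    } else {
      label <- if (sides[1] == "A") "A_SPECIFIC" else "B_SPECIFIC"
      summit <- all_peaks$summit[members[1]]
    }
    regions[[length(regions) + 1L]] <- hull
    meta[[length(meta) + 1L]] <- list(label = label, summit = summit)
  }
  out <- do.call(c, regions)
  out$label <- vapply(meta, `[[`, character(1), "label")
  out$summit <- vapply(meta, `[[`, integer(1), "summit")
  cross_rpkm <- function(track) {
    if (is.null(track)) return(rep(NA_real_, length(out)))
    compute_rpkm(track, out, halfwidth = h, mode = config$read_count_mode)
  }
  out$rpkm_A <- cross_rpkm(track_A)
  out$rpkm_B <- cross_rpkm(track_B)
  if (all(is.na(out$rpkm_A))) {
    # score fallback (no tracks supplied): use own-line scores, 0 elsewhere
    sc <- vapply(comp, function(members) {
      c(A = max(c(0, all_peaks$own_rpkm[members][all_peaks$side[members] == "A"])),
        B = max(c(0, all_peaks$own_rpkm[members][all_peaks$side[members] == "B"])))
    }, numeric(2))
    out$rpkm_A <- sc["A", ]
    out$rpkm_B <- sc["B", ]
  }
  out$sort_key <- log2(out$rpkm_B + eps) - log2(out$rpkm_A + eps)
  out[order(out$sort_key, GenomicRanges::start(out))]
}

#' Overlap super-enhancer regions of two cell lines
#'
#' Reports every pair of SE regions that overlap by >= 1 bp across the two
#' cell lines, and merges connected overlap groups (an A region overlapping
#' two B regions, chains, etc.) into one "shared SE" hull for downstream
#' constituent breakdown.
#'
#' @param ses_A,ses_B `GRanges` of called SE regions per cell line.
#' @return list with `pairs` (data.frame of overlapping index pairs) and
#'   `hulls` (`GRanges` with `n_A`/`n_B` member counts).
#' @export
overlap_se_regions <- function(ses_A, ses_B) {
  nA <- length(ses_A); nB <- length(ses_B)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(ses_A, ses_B, ignore.strand = TRUE))
  pairs <- data.frame(a = S4Vectors::queryHits(ov),
                      b = S4Vectors::subjectHits(ov))
  comb <- suppressWarnings(
    c(GenomicRanges::granges(ses_A, use.mcols = FALSE),
      GenomicRanges::granges(ses_B, use.mcols = FALSE)))
  root <- uf_union_all(nA + nB, pairs$a, pairs$b + nA)
  comp <- split(seq_len(nA + nB), root)
  shared <- Filter(function(m) any(m <= nA) && any(m > nA), comp)
  if (length(shared) == 0) {
    hulls <- GenomicRanges::GRanges()
    hulls$n_A <- integer(0); hulls$n_B <- integer(0)
  } else {
    hulls <- do.call(c, unname(lapply(shared, function(m)
      range(comb[m], ignore.strand = TRUE))))
    hulls$n_A <- vapply(shared, function(m) sum(m <= nA), integer(1))
    hulls$n_B <- vapply(shared, function(m) sum(m > nA), integer(1))
  }
  list(pairs = pairs, hulls = GenomicRanges::sort(hulls))
}

#' Constituent breakdown of shared SE hulls
#'
#' Counts A-specific, shared and B-specific constituents falling in each
#' shared hull; a constituent belongs to a hull iff its (0-based) summit
#' lies within the hull under half-open semantics.
#'
#' @param hulls `GRanges` from [overlap_se_regions()].
#' @param constituents labelled `GRanges` from [classify_constituents()].
#' @return list with `per_hull` (data.frame of counts per hull) and
#'   `totals` (named vector over the three labels).
#' @export
shared_se_constituent_breakdown <- function(hulls, constituents) {
  labels <- c("A_SPECIFIC", "SHARED", "B_SPECIFIC")
  summ <- GenomicRanges::GRanges(GenomicRanges::seqnames(constituents),
                                 IRanges::IRanges(constituents$summit + 1L,
                                                  width = 1L))
  ov <- GenomicRanges::findOverlaps(summ, hulls, ignore.strand = TRUE)
  tab <- matrix(0L, nrow = length(hulls), ncol = 3,
                dimnames = list(NULL, labels))
  if (length(ov) > 0) {
    lab <- constituents$label[S4Vectors::queryHits(ov)]
    for (k in seq_along(ov)) {
      i <- S4Vectors::subjectHits(ov)[k]
      tab[i, lab[k]] <- tab[i, lab[k]] + 1L
    }
  }
  per_hull <- data.frame(chrom = as.character(GenomicRanges::seqnames(hulls)),
                         start = GenomicRanges::start(hulls) - 1L,
                         end = GenomicRanges::end(hulls),
                         tab, check.names = FALSE, stringsAsFactors = FALSE)
  list(per_hull = per_hull, totals = colSums(tab))
}

#' TF density matrix over constituents
#'
#' Summit RPKM of every constituent in every supplied coverage track
#' (typically one per TF/treatment/cell-line combination).
#'
#' @param constituents `GRanges` with 0-based `summit`.
#' @param tracks named list of `coverage_track`; names become columns.
#' @param halfwidth RPKM window half-width, bp.
#' @param mode read-attribution rule.
#' @return numeric matrix, constituents x tracks.
#' @export
build_density_matrix <- function(constituents, tracks, halfwidth = 50,
                                 mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list")
  bad <- !vapply(tracks, inherits, logical(1), "coverage_track")
  if (any(bad))
    stop("missing coverage track for column(s): ",
         paste(names(tracks)[bad], collapse = ", "))
  m <- vapply(tracks, function(tr)
    compute_rpkm(tr, constituents, halfwidth = halfwidth, mode = mode),
    numeric(length(constituents)))
  matrix(m, nrow = length(constituents),
         dimnames = list(NULL, names(tracks)))
}

#' Per-group column averages of a density matrix
#'
#' @param mat matrix from [build_density_matrix()].
#' @param groups character/factor of group labels per row.
#' @return matrix, groups x columns, of mean densities.
#' @export
density_group_means <- function(mat, groups) {
  g <- factor(groups)
  out <- t(vapply(levels(g), function(lv)
    colMeans(mat[g == lv, , drop = FALSE]), numeric(ncol(mat))))
  rownames(out) <- levels(g)
  out
}

#' Pairwise TF density correlations
#'
#' Pearson correlation between track columns, by default on
#' `log2(RPKM + eps)`. Columns with zero variance get `NA` against every
#' other column; the diagonal is 1.
#'
#' @param mat density matrix (>= 3 rows).
#' @param scale `"log2"` or `"raw"`.
#' @param eps pseudocount for the log transform.
#' @return symmetric correlation matrix.
#' @export
correlation_matrix <- function(mat, scale = c("log2", "raw"), eps = 0.1) {
  scale <- match.arg(scale)
  if (nrow(mat) < 3) stop("need at least 3 rows")
  tx <- if (scale == "log2") log2(mat + eps) else mat
  sds <- apply(tx, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(tx))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- 1
  cm
}

#' Co-binding fractions of constituents
#'
#' For each constituent, counts how many collaborating TFs (master TF
#' excluded by the caller) have a peak overlapping the constituent's
#' summit +/- `halfwidth` window, and reports the fraction bound by at
#' least `min_tfs` collaborators and its complement (bound by at most
#' `min_tfs - 1`).
#'
#' @param constituents `GRanges` with 0-based `summit`.
#' @param collaborators named list of `GRanges` peak sets, one per TF.
#' @param halfwidth window half-width, bp.
#' @param min_tfs co-binding threshold.
#' @return list with `counts` (per-constituent collaborator count),
#'   `fraction_cobound` (>= min_tfs) and `fraction_low` (<= min_tfs - 1).
#' @export
count_cobound <- function(constituents, collaborators, halfwidth = 100,
                          min_tfs = 2) {
  if (length(constituents) == 0)
    return(list(counts = integer(0), fraction_cobound = NA_real_,
                fraction_low = NA_real_))
  win <- summit_window(constituents, halfwidth)
  bound <- vapply(collaborators, function(p)
    IRanges::overlapsAny(win, p, ignore.strand = TRUE),
    logical(length(constituents)))
  bound <- matrix(bound, nrow = length(constituents))
  counts <- rowSums(bound)
  list(counts = counts,
       fraction_cobound = mean(counts >= min_tfs),
       fraction_low = mean(counts <= min_tfs - 1))
}

#' Motif composition table
#'
#' Assigns each constituent exactly one category: the single motif present
#' when exactly one PWM has a hit, `"multiple"` when two or more do (the
#' combination is recorded), `"none"` otherwise; then tabulates per label
#' with percentages summing to 100.
#'
#' @param presence logical matrix, constituents x motifs.
#' @param labels character vector of constituent labels (same length as
#'   rows of `presence`).
#' @return list with `table` (data.frame label x category percentages and
#'   counts) and `combinations` (data.frame of multi-motif combination
#'   frequencies per label).
#' @export
motif_composition <- function(presence, labels) {
  stopifnot(nrow(presence) == length(labels))
  nhit <- rowSums(presence)
  cat <- character(nrow(presence))
  combo <- rep(NA_character_, nrow(presence))
  for (i in seq_len(nrow(presence))) {
    if (nhit[i] == 0) cat[i] <- "none"
    else if (nhit[i] == 1) cat[i] <- colnames(presence)[which(presence[i, ])]
    else {
      cat[i] <- "multiple"
      combo[i] <- paste(colnames(presence)[which(presence[i, ])],
                        collapse = "+")
    }
  }
  cats <- c(colnames(presence), "multiple", "none")
  labs <- unique(labels)
  rows <- lapply(labs, function(lb) {
    sel <- labels == lb
    n <- sum(sel)
    cnt <- vapply(cats, function(cc) sum(cat[sel] == cc), integer(1))
    data.frame(label = lb, category = cats, count = cnt,
               percent = if (n > 0) 100 * cnt / n else rep(0, length(cats)),
               stringsAsFactors = FALSE)
  })
  combos <- lapply(labs, function(lb) {
    sel <- labels == lb & !is.na(combo)
    if (!any(sel)) return(NULL)
    tt <- sort(table(combo[sel]), decreasing = TRUE)
    data.frame(label = lb, combination = names(tt),
               count = as.integer(tt),
               percent = 100 * as.integer(tt) / sum(labels == lb),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       combinations = do.call(rbind, combos),
       category = cat)
}

#' Specific-to-shared constituent abundance ratios
#'
#' The two-cistrome comparison summarises cluster sizes as the abundance of
#' each cell line's specific constituents relative to the shared ones.
#'
#' @param n_A_specific,n_shared,n_B_specific cluster sizes.
#' @return named numeric vector with `A_to_shared` and `B_to_shared`.
#' @export
cluster_abundance_ratios <- function(n_A_specific, n_shared, n_B_specific) {
  if (n_shared <= 0) stop("shared cluster size must be positive")
  c(A_to_shared = n_A_specific / n_shared,
    B_to_shared = n_B_specific / n_shared)
}
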