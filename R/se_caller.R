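#' Stitch peaks into enhancer candidates
#'
#' Merges peaks on the same chromosome whenever the gap between their
#' interval edges is strictly smaller than `max_gap` (transitive closure;
#' 12.5 kb by default in the pipeline). Each candidate region is the hull of
#' its constituent peaks. Stitching an already stitched set changes nothing.
#'
#' @param peaks `GRanges` of peaks (metadata preserved through the
#'   `constituents` index list).
#' @param max_gap strict gap threshold in bp.
#' @return `GRanges` of candidate regions with metadata columns
#'   `constituents` (IntegerList of indices into `peaks`) and
#'   `n_constituents`.
#' @export
stitch_peaks <- function(peaks, max_gap) {
  stopifnot(max_gap > 0)
  if (length(peaks) == 0) {
    out <- GenomicRanges::GRanges()
    out$constituents <- IRanges::IntegerList()
    out$n_constituents <- integer(0)
    return(out)
  }
  red <- GenomicRanges::reduce(GenomicRanges::granges(peaks, use.mcols = FALSE),
                               min.gapwidth = max_gap, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(peaks, red, ignore.strand = TRUE)
  idx <- S4Vectors::split(S4Vectors::queryHits(ov),
                          factor(S4Vectors::subjectHits(ov),
                                 levels = seq_along(red)))
  red$constituents <- unname(IRanges::IntegerList(idx))
  red$n_constituents <- lengths(red$constituents)
  red
}

#' Rank stitched candidates by tag density
#'
#' Computes each candidate's tag density (rpm/bp, see [tag_density()]),
#' sorts ascending (ties broken deterministically by region start, then
#' chromosome) and scales both axes to `[0, 1]`: `x = rank / (n - 1)` with
#' 0-based ranks, `y = density / max(density)`.
#'
#' @param candidates `GRanges` from [stitch_peaks()] (>= 2 candidates).
#' @param track master-TF `coverage_track` used for ranking.
#' @param mode read-attribution rule passed to [tag_density()].
#' @return object of class `ranked_curve`: a list with `candidates` (in the
#'   ranked, ascending order), `density`, `x`, `y` and `order` (permutation
#'   applied to the input).
#' @export
rank_candidates <- function(candidates, track, mode = c("overlap", "start")) {
  mode <- match.arg(mode)
  n <- length(candidates)
  if (n < 2) stop("need at least 2 candidates to build a ranked curve")
  dens <- tag_density(track, candidates, mode)
  if (all(dens == 0)) stop("all candidate densities are zero: no signal")
  ord <- order(dens, GenomicRanges::start(candidates),
               as.character(GenomicRanges::seqnames(candidates)))
  dens_s <- dens[ord]
  structure(list(candidates = candidates[ord],
                 density = dens_s,
                 x = (seq_len(n) - 1) / (n - 1),
                 y = dens_s / max(dens_s),
                 order = ord),
            class = "ranked_curve")
}

#' Call super-enhancers by the slope-1 tangent rule
#'
#' On the scaled rank curve the cutoff is the discrete tangent point of a
#' slope-1 line: the index minimising `y - x` (ties resolved to the largest
#' index). Candidates strictly above that point are super-enhancers; the
#' tangent-point candidate itself is not.
#'
#' @param curve `ranked_curve` from [rank_candidates()].
#' @return object of class `se_call`: list with `candidates` (ranked order,
#'   now carrying `is_super`, `rank` and `tag_density` metadata) and
#'   `cutoff_index` (1-based index into the ranked order).
#' @export
call_superenhancers <- function(curve) {
  stopifnot(inherits(curve, "ranked_curve"))
  d <- curve$y - curve$x
  # ties (within numerical noise) resolve to the largest index
  cutoff <- max(which(d <= min(d) + 1e-12))
  cand <- curve$candidates
  cand$tag_density <- curve$density
  cand$rank <- seq_along(cand)
  cand$is_super <- seq_along(cand) > cutoff
  structure(list(candidates = cand, cutoff_index = cutoff),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call: %d candidates, %d super-enhancers (cutoff index %d)\n",
              length(x$candidates), sum(x$candidates$is_super),
              x$cutoff_index))
  invisible(x)
}

#' Flat table of an SE call
#'
#' @param call `se_call`.
#' @return data.frame with chrom, 0-based start/end, constituent count, tag
#'   density, rank and the super-enhancer flag, ranked order.
#' @export
se_call_table <- function(call) {
  cand <- call$candidates
  data.frame(chrom = as.character(GenomicRanges::seqnames(cand)),
             start = GenomicRanges::start(cand) - 1L,
             end = GenomicRanges::end(cand),
             n_constituents = cand$n_constituents,
             tag_density = cand$tag_density,
             rank = cand$rank,
             is_super = cand$is_super,
             stringsAsFactors = FALSE)
}

#' Super-enhancer regions of a call
#'
#' @param call `se_call`.
#' @return `GRanges` of the candidates flagged `is_super`.
#' @export
se_regions <- function(call) {
  call$candidates[call$candidates$is_super]
}
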