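#' Analysis parameters
#'
#' Central container for every tunable length, threshold and toggle used by
#' the pipeline. The defaults follow the conventions of ROSE-style
#' super-enhancer calling and summit-centred ChIP-seq quantification:
#' enhancers closer than 12.5 kb are stitched, read densities are taken in
#' +/-50 bp summit windows, motifs are mapped in 30-bp windows over 1.5-kb
#' frames, SEs reach +/-100 kb for gene annotation, and expression is
#' compared with a 2-fold band on FPKM values (pseudocount 0.1).
#'
#' @param stitch_gap_bp maximum gap (strict, bp) between enhancer edges that
#'   still merges them into one stitched candidate.
#' @param rpkm_halfwidth_bp half-width of the summit window used for RPKM;
#'   the window `[summit - h, summit + h)` has length `2 h`.
#' @param motif_halfwidth_bp half-width of the summit window used for top
#'   motif scores and motif presence calls.
#' @param motif_window_bp bin width of the motif distribution matrix.
#' @param motif_frame_bp frame length of the motif distribution matrix,
#'   centred on the summit; must be divisible by `motif_window_bp`.
#' @param annot_halfwidth_bp reach (bp) of the SE-centred annotation window.
#' @param min_fpkm minimum mean FPKM for the nearest-gene annotation
#'   fallback.
#' @param fold_threshold fold-change band for expression classification
#'   (strictly greater than this value counts as "exceeds").
#' @param fpkm_pseudocount added to FPKM before forming fold ratios.
#' @param promoter_upstream_bp,promoter_downstream_bp strand-oriented
#'   promoter extent around the TSS.
#' @param min_cobind_tfs number of collaborating TFs defining a "co-bound"
#'   constituent.
#' @param read_count_mode how a stored read interval is attributed to a
#'   window: `"overlap"` counts it if the interval overlaps the window by
#'   >= 1 bp, `"start"` only if its 5' end lies in the window.
#' @param correlation_scale scale on which TF density correlations are
#'   computed: `"log2"` (log2(RPKM + 0.1), default) or `"raw"`.
#' @param replicate_rule expression classification rule: `"all_pairs"`
#'   requires every cross-cell-line replicate pair to exceed the band,
#'   `"mean"` compares replicate means.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(stitch_gap_bp = 12500L,
                            rpkm_halfwidth_bp = 50L,
                            motif_halfwidth_bp = 100L,
                            motif_window_bp = 30L,
                            motif_frame_bp = 1500L,
                            annot_halfwidth_bp = 100000L,
                            min_fpkm = 1.0,
                            fold_threshold = 2.0,
                            fpkm_pseudocount = 0.1,
                            promoter_upstream_bp = 1000L,
                            promoter_downstream_bp = 100L,
                            min_cobind_tfs = 2L,
                            read_count_mode = c("overlap", "start"),
                            correlation_scale = c("log2", "raw"),
                            replicate_rule = c("all_pairs", "mean")) {
  cfg <- list(
    stitch_gap_bp = as.integer(stitch_gap_bp),
    rpkm_halfwidth_bp = as.integer(rpkm_halfwidth_bp),
    motif_halfwidth_bp = as.integer(motif_halfwidth_bp),
    motif_window_bp = as.integer(motif_window_bp),
    motif_frame_bp = as.integer(motif_frame_bp),
    annot_halfwidth_bp = as.integer(annot_halfwidth_bp),
    min_fpkm = as.numeric(min_fpkm),
    fold_threshold = as.numeric(fold_threshold),
    fpkm_pseudocount = as.numeric(fpkm_pseudocount),
    promoter_upstream_bp = as.integer(promoter_upstream_bp),
    promoter_downstream_bp = as.integer(promoter_downstream_bp),
    min_cobind_tfs = as.integer(min_cobind_tfs),
    read_count_mode = match.arg(read_count_mode),
    correlation_scale = match.arg(correlation_scale),
    replicate_rule = match.arg(replicate_rule)
  )
  problems <- character(0)
  lengths_pos <- c("stitch_gap_bp", "rpkm_halfwidth_bp", "motif_halfwidth_bp",
                   "motif_window_bp", "motif_frame_bp", "annot_halfwidth_bp",
                   "promoter_upstream_bp", "promoter_downstream_bp")
  for (nm in lengths_pos) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      problems <- c(problems, sprintf("'%s' must be a positive length", nm))
  }
  if (cfg$fold_threshold <= 1)
    problems <- c(problems, "'fold_threshold' must be > 1")
  if (cfg$fpkm_pseudocount < 0)
    problems <- c(problems, "'fpkm_pseudocount' must be >= 0")
  if (cfg$min_cobind_tfs < 1)
    problems <- c(problems, "'min_cobind_tfs' must be >= 1")
  if (length(problems) == 0 && cfg$motif_frame_bp %% cfg$motif_window_bp != 0L)
    problems <- c(problems,
                  "'motif_frame_bp' must be divisible by 'motif_window_bp'")
  if (length(problems) > 0)
    stop("invalid analysis_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
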