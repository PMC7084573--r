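#' Read a gene model table
#'
#' Tab-separated gene model with columns `gene_id`, `chrom`, `strand`,
#' `tss` (0-based position), `start`, `end` (0-based half-open body) and
#' `biotype` (`protein_coding` or anything else).
#'
#' @param path TSV path (with header).
#' @return data.frame with those columns plus `is_protein_coding`.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end", "biotype")
  if (!all(need %in% colnames(df)))
    stop("gene model must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in gene model")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  df$is_protein_coding <- df$biotype == "protein_coding"
  df
}

#' Read an expression matrix with sample metadata
#'
#' The FPKM table is genes x samples (first column `gene_id`); the sidecar
#' metadata TSV has columns `sample`, `cell_line`, `timepoint`
#' (minutes of ligand treatment) and `replicate`.
#'
#' @param path FPKM TSV path.
#' @param meta_path sample metadata TSV path.
#' @return object of class `expression_matrix`: list with `fpkm` (numeric
#'   matrix, rownames = gene ids) and `samples` (data.frame).
#' @export
read_expression <- function(path, meta_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("sample", "cell_line", "timepoint", "replicate")
  if (!all(need %in% colnames(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  fpkm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fpkm) <- df[[1]]
  if (!setequal(colnames(fpkm), meta$sample))
    stop("FPKM columns and sample metadata do not match")
  fpkm <- fpkm[, meta$sample, drop = FALSE]
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  structure(list(fpkm = fpkm, samples = meta), class = "expression_matrix")
}

# Mean FPKM over replicates of one (cell line, timepoint); named by gene.
mean_fpkm <- function(expr, cell_line, timepoint) {
  sel <- expr$samples$cell_line == cell_line &
    expr$samples$timepoint == timepoint
  if (!any(sel)) stop("no samples for ", cell_line, " at ", timepoint, " min")
  rowMeans(expr$fpkm[, expr$samples$sample[sel], drop = FALSE])
}

# Strand-oriented promoter [TSS - up, TSS + down) as 0-based half-open
# genomic coordinates.
promoter_bounds <- function(tss, strand, up, down) {
  s <- ifelse(strand == "+", tss - up, tss - down + 1L)
  e <- ifelse(strand == "+", tss + down, tss + up + 1L)
  cbind(start = pmax(s, 0L), end = e)
}

#' Annotate a super-enhancer to its target gene
#'
#' The SE is extended to +/- `annot_halfwidth_bp` around its centre. Among
#' protein-coding genes whose promoter overlaps that window, the one with
#' the highest mean FPKM (replicates at the given cell line/timepoint) is
#' assigned (ties: nearest TSS to the SE centre, then lexicographic id).
#' If no promoter overlaps, the nearest protein-coding gene on the same
#' chromosome with mean FPKM >= `min_fpkm` is assigned instead; if none
#' exists, the SE stays unannotated.
#'
#' @param se `GRanges` of SE regions (any length).
#' @param genes gene model data.frame from [read_gene_model()].
#' @param expr `expression_matrix`.
#' @param cell_line,timepoint which expression samples define "expressed".
#' @param config `analysis_config` (annotation reach, promoter extent,
#'   FPKM floor).
#' @return data.frame with one row per SE: `se_index`, `gene_id` (NA when
#'   unannotated), `rule` (`promoter_overlap`, `nearest_fallback` or
#'   `none`), `mean_fpkm`, `distance_bp` (TSS to SE centre).
#' @export
annotate_se <- function(se, genes, expr, cell_line, timepoint,
                        config = analysis_config()) {
  if (nrow(genes) == 0) stop("empty gene model")
  mf <- mean_fpkm(expr, cell_line, timepoint)
  genes$mean_fpkm <- unname(mf[genes$gene_id])
  if (anyNA(genes$mean_fpkm))
    stop("genes missing from the expression matrix: ",
         paste(utils::head(genes$gene_id[is.na(genes$mean_fpkm)], 3),
               collapse = ", "))
  pb <- promoter_bounds(genes$tss, genes$strand,
                        config$promoter_upstream_bp,
                        config$promoter_downstream_bp)
  H <- config$annot_halfwidth_bp
  res <- lapply(seq_along(se), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(se[i]))
    center <- (GenomicRanges::start(se[i]) - 1L + GenomicRanges::end(se[i])) %/% 2L
    wstart <- center - H; wend <- center + H
    cand <- genes$is_protein_coding & genes$chrom == chrom &
      pb[, "start"] < wend & wstart < pb[, "end"]
    if (any(cand)) {
      sub <- genes[cand, , drop = FALSE]
      dist <- abs(sub$tss - center)
      ord <- order(-sub$mean_fpkm, dist, sub$gene_id)
      g <- sub[ord[1], ]
      return(data.frame(se_index = i, gene_id = g$gene_id,
                        rule = "promoter_overlap", mean_fpkm = g$mean_fpkm,
                        distance_bp = abs(g$tss - center),
                        stringsAsFactors = FALSE))
    }
    fb <- genes$is_protein_coding & genes$chrom == chrom &
      genes$mean_fpkm >= config$min_fpkm
    if (any(fb)) {
      sub <- genes[fb, , drop = FALSE]
      dist <- abs(sub$tss - center)
      ord <- order(dist, sub$gene_id)
      g <- sub[ord[1], ]
      return(data.frame(se_index = i, gene_id = g$gene_id,
                        rule = "nearest_fallback", mean_fpkm = g$mean_fpkm,
                        distance_bp = abs(g$tss - center),
                        stringsAsFactors = FALSE))
    }
    data.frame(se_index = i, gene_id = NA_character_, rule = "none",
               mean_fpkm = NA_real_, distance_bp = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Replicate-aware 2-fold expression classification
#'
#' For each gene, every cross-cell-line replicate pair at the stated
#' timepoints yields a fold value `(FPKM_A + c) / (FPKM_B + c)`. A gene is
#' `A_SPECIFIC` iff all pairs exceed the fold threshold (strictly),
#' `B_SPECIFIC` iff all pairs fall below its reciprocal, otherwise
#' `SIMILAR`. With `replicate_rule = "mean"` a single fold of replicate
#' means is used instead.
#'
#' @param expr `expression_matrix`.
#' @param gene_ids genes to classify.
#' @param cell_lines length-2 character, (A, B).
#' @param timepoints length-2 numeric, timepoint per cell line.
#' @param config `analysis_config` (fold threshold, pseudocount, rule).
#' @return data.frame with `gene_id`, `class`, `min_fold`, `max_fold`
#'   (cross-pair extremes of A/B fold values).
#' @export
classify_expression <- function(expr, gene_ids, cell_lines, timepoints,
                                config = analysis_config()) {
  stopifnot(length(cell_lines) == 2, length(timepoints) == 2)
  thr <- config$fold_threshold
  c0 <- config$fpkm_pseudocount
  cols <- function(cl, tp) {
    sel <- expr$samples$cell_line == cl & expr$samples$timepoint == tp
    if (sum(sel) < 2)
      stop("need >= 2 replicates for ", cl, " at ", tp, " min")
    expr$samples$sample[sel][order(expr$samples$replicate[sel])]
  }
  sA <- cols(cell_lines[1], timepoints[1])
  sB <- cols(cell_lines[2], timepoints[2])
  missing <- setdiff(gene_ids, rownames(expr$fpkm))
  if (length(missing) > 0)
    stop("genes missing from the expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  res <- lapply(gene_ids, function(g) {
    a <- expr$fpkm[g, sA] + c0
    b <- expr$fpkm[g, sB] + c0
    if (config$replicate_rule == "mean") {
      folds <- mean(a) / mean(b)
    } else {
      folds <- as.vector(outer(a, b, "/"))
    }
    cls <- if (all(folds > thr)) "A_SPECIFIC"
           else if (all(folds < 1 / thr)) "B_SPECIFIC"
           else "SIMILAR"
    data.frame(gene_id = g, class = cls, min_fold = min(folds),
               max_fold = max(folds), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Expression-class summary per SE label
#'
#' Counts and percentages of SIMILAR / A_SPECIFIC / B_SPECIFIC genes for
#' each SE label (A-specific, shared, B-specific SE sets). A gene annotated
#' to several SEs is counted once per SE label.
#'
#' @param classes data.frame with columns `se_label`, `gene_id`, `class`.
#' @return data.frame, one row per SE label, with counts, percentages and
#'   the total annotated-gene count.
#' @export
expression_summary <- function(classes) {
  labs <- unique(classes$se_label)
  cls <- c("SIMILAR", "A_SPECIFIC", "B_SPECIFIC")
  if (length(labs) == 0) {
    out <- data.frame(se_label = character(0), n_genes = integer(0))
    for (cc in cls) {
      out[[paste0("n_", tolower(cc))]] <- integer(0)
      out[[paste0("pct_", tolower(cc))]] <- numeric(0)
    }
    return(out)
  }
  rows <- lapply(labs, function(lb) {
    sub <- unique(classes[classes$se_label == lb, c("gene_id", "class")])
    n <- nrow(sub)
    cnt <- vapply(cls, function(cc) sum(sub$class == cc), integer(1))
    pct <- if (n > 0) 100 * cnt / n else rep(0, 3)
    out <- data.frame(se_label = lb, n_genes = n, stringsAsFactors = FALSE)
    for (j in seq_along(cls)) {
      out[[paste0("n_", tolower(cls[j]))]] <- cnt[j]
      out[[paste0("pct_", tolower(cls[j]))]] <- pct[j]
    }
    out
  })
  do.call(rbind, rows)
}
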