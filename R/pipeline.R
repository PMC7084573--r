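#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes an equivalent list), resolves every path
#' against the config's directory, injects [analysis_config()] defaults for
#' omitted analysis fields and reports all problems in a single error.
#'
#' The config declares: `genome` (FASTA), `motif_dir` (JASPAR PFMs),
#' `genes`, `expression` + `samples`, `library_sizes` (TSV `track`,
#' `total_reads`), `master_tf`, a `cells` block with entries `A` and `B`
#' (each with `name`, `timepoint`, named `peaks` and `tracks` including the
#' master TF), `seed`, and optionally `blacklist`, `analysis` (parameter
#' overrides), `thresholds` (manual per-motif score thresholds),
#' `motif_subset` (sub-clustering priority order) and
#' `n_background_regions`.
#'
#' @param config path to a YAML file, or a list.
#' @param base_dir directory against which relative paths resolve
#'   (defaults to the config file's directory).
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  problems <- character(0)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!startsWith(p, "/")) p <- file.path(base_dir, p)
    p
  }
  need_file <- function(p, what) {
    p <- resolve(p)
    if (is.null(p)) {
      problems <<- c(problems, paste0("missing config entry: ", what))
      return(NULL)
    }
    if (!file.exists(p))
      problems <<- c(problems, sprintf("%s does not exist: %s", what, p))
    p
  }
  config$genome <- need_file(config$genome, "genome")
  config$motif_dir <- need_file(config$motif_dir, "motif_dir")
  config$genes <- need_file(config$genes, "genes")
  config$expression <- need_file(config$expression, "expression")
  config$samples <- need_file(config$samples, "samples")
  config$library_sizes <- need_file(config$library_sizes, "library_sizes")
  if (!is.null(config$blacklist))
    config$blacklist <- need_file(config$blacklist, "blacklist")
  if (is.null(config$master_tf))
    problems <- c(problems, "missing config entry: master_tf")
  if (is.null(config$seed)) config$seed <- 1L
  for (side in c("A", "B")) {
    cell <- config$cells[[side]]
    if (is.null(cell)) {
      problems <- c(problems, paste0("missing cells entry: ", side))
      next
    }
    if (is.null(cell$name))
      problems <- c(problems, paste0("cells$", side, " needs a name"))
    if (is.null(cell$timepoint))
      problems <- c(problems, paste0("cells$", side, " needs a timepoint"))
    for (kind in c("peaks", "tracks")) {
      entries <- cell[[kind]]
      if (is.null(entries) || is.null(names(entries))) {
        problems <- c(problems,
                      sprintf("cells$%s needs named %s entries", side, kind))
        next
      }
      if (!is.null(config$master_tf) &&
          !(config$master_tf %in% names(entries)))
        problems <- c(problems,
                      sprintf("cells$%s$%s lacks the master TF '%s'",
                              side, kind, config$master_tf))
      for (nm in names(entries)) {
        config$cells[[side]][[kind]][[nm]] <-
          need_file(entries[[nm]], sprintf("cells$%s$%s$%s", side, kind, nm))
      }
    }
  }
  ac_args <- config$analysis
  config$analysis <- tryCatch(
    do.call(analysis_config, if (is.null(ac_args)) list() else ac_args),
    error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
  if (is.null(config$n_background_regions))
    config$n_background_regions <- 200L
  if (length(problems) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(config, class = "pipeline_config")
}

# Uniform random summit "windows" used as the enrichment background:
# returns a GRanges of width-1 anchors with a `summit` column.
sample_background_regions <- function(genome, n, halfwidth) {
  lens <- Biostrings::width(genome)
  chrom_idx <- rint(n, 1L, length(genome))
  summits <- vapply(chrom_idx, function(ci)
    rint(1, halfwidth, lens[ci] - halfwidth - 1L), numeric(1))
  gr <- GenomicRanges::GRanges(names(genome)[chrom_idx],
                               IRanges::IRanges(summits + 1L, width = 1L))
  gr$summit <- as.integer(summits)
  gr$name <- sprintf("bg_region_%03d", seq_len(n))
  gr
}

#' Run the full comparative SE pipeline
#'
#' Executes every stage on a validated config and writes all tables under
#' `outdir`: blacklist filtering, per-cell-line SE calling, constituent
#' classification, motif thresholds/presence/distribution/enrichment, TF
#' density and correlation matrices, co-binding fractions, shared-SE
#' overlap/breakdown/composition, SE-to-gene annotation and 2-fold
#' expression classification, plus a machine-readable run summary. A rerun
#' with the same config and inputs reproduces identical data files (only
#' the log carries timings).
#'
#' @param config `pipeline_config` from [validate_config()] (or a path /
#'   list, validated on the fly).
#' @param outdir output directory.
#' @return (invisibly) a list with the principal in-memory results and
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$analysis
  set.seed(config$seed)
  log_lines <- character(0)
  t_start <- proc.time()[["elapsed"]]
  stage_records <- list()
  current_stage <- "load_inputs"
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%7.2fs] %s",
                                       proc.time()[["elapsed"]] - t_start,
                                       sprintf(...)))
  }
  record <- function(stage, ...) {
    stage_records[[stage]] <<- list(...)
  }
  run <- function(expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("FAILED at stage:", current_stage),
                   conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      writeLines(log_lines, file.path(outdir, "run.log"))
      stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- load inputs -----------------------------------------------------
  res <- run({
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    pfm_files <- sort(list.files(config$motif_dir, pattern = "\\.pfm$",
                                 full.names = TRUE))
    if (length(pfm_files) == 0) stop("no .pfm files in ", config$motif_dir)
    pwms <- lapply(pfm_files, read_pfm)
    names(pwms) <- vapply(pwms, `[[`, character(1), "id")
    genes <- read_gene_model(config$genes)
    expr <- read_expression(config$expression, config$samples)
    libs <- utils::read.table(config$library_sizes, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    lib_of <- stats::setNames(libs$total_reads, libs$track)
    blacklist <- if (!is.null(config$blacklist))
      read_blacklist(config$blacklist) else GenomicRanges::GRanges()
    cells <- list()
    for (side in c("A", "B")) {
      cc <- config$cells[[side]]
      peaks <- lapply(cc$peaks, read_peaks, format = "narrowPeak")
      tracks <- list()
      for (tf in names(cc$tracks)) {
        key <- paste(cc$name, tf, sep = "_")
        if (!key %in% names(lib_of))
          stop("library size missing for track ", key)
        tracks[[tf]] <- read_bedgraph(cc$tracks[[tf]], lib_of[[key]])
      }
      cells[[side]] <- list(name = cc$name, timepoint = cc$timepoint,
                            peaks = peaks, tracks = tracks)
    }
    list(genome = genome, pwms = pwms, genes = genes, expr = expr,
         blacklist = blacklist, cells = cells)
  })
  note("loaded inputs: %d motifs, %d genes, %d+%d peak sets",
       length(res$pwms), nrow(res$genes),
       length(res$cells$A$peaks), length(res$cells$B$peaks))
  record("load_inputs", n_motifs = length(res$pwms),
         n_genes = nrow(res$genes))

  master <- config$master_tf

  # ---- blacklist filter ------------------------------------------------
  current_stage <- "filter_blacklist"
  res <- run({
    for (side in c("A", "B")) {
      res$cells[[side]]$peaks <- lapply(res$cells[[side]]$peaks,
                                        filter_blacklist, res$blacklist)
    }
    res
  })
  record("filter_blacklist", n_blacklist = length(res$blacklist))

  # ---- SE calling per cell line ---------------------------------------
  current_stage <- "call_superenhancers"
  se_calls <- run({
    out <- list()
    for (side in c("A", "B")) {
      cell <- res$cells[[side]]
      cand <- stitch_peaks(cell$peaks[[master]], cfg$stitch_gap_bp)
      curve <- rank_candidates(cand, cell$tracks[[master]],
                               mode = cfg$read_count_mode)
      call <- call_superenhancers(curve)
      tab <- se_call_table(call)
      write_tsv_file(tab, file.path(outdir,
                                    sprintf("se_calls_%s.tsv", cell$name)))
      supers <- se_regions(call)
      bed <- sprintf("%s\t%d\t%d\tSE_%s_%03d",
                     as.character(GenomicRanges::seqnames(supers)),
                     GenomicRanges::start(supers) - 1L,
                     GenomicRanges::end(supers),
                     cell$name, seq_along(supers))
      writeLines(bed, file.path(outdir,
                                sprintf("superenhancers_%s.bed", cell$name)))
      const_idx <- unlist(supers$constituents)
      const_parent <- rep(seq_along(supers), lengths(supers$constituents))
      consts <- cell$peaks[[master]][const_idx]
      cbed <- sprintf("%s\t%d\t%d\t%s\t%s\tSE_%s_%03d",
                      as.character(GenomicRanges::seqnames(consts)),
                      GenomicRanges::start(consts) - 1L,
                      GenomicRanges::end(consts), consts$name,
                      num_fmt(consts$score), cell$name, const_parent)
      writeLines(cbed, file.path(outdir,
                                 sprintf("constituents_%s.bed", cell$name)))
      out[[side]] <- list(call = call, supers = supers,
                          constituents = consts)
      note("%s: %d candidates, %d super-enhancers, %d SE constituents",
           cell$name, length(call$candidates), length(supers),
           length(consts))
    }
    out
  })
  record("call_superenhancers",
         n_SE_A = length(se_calls$A$supers),
         n_SE_B = length(se_calls$B$supers))

  # ---- constituent classification -------------------------------------
  current_stage <- "classify_constituents"
  constituents <- run({
    cl <- classify_constituents(se_calls$A$constituents,
                                se_calls$B$constituents,
                                res$cells$A$tracks[[master]],
                                res$cells$B$tracks[[master]], cfg)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(cl)),
                     start = GenomicRanges::start(cl) - 1L,
                     end = GenomicRanges::end(cl),
                     summit = cl$summit, label = cl$label,
                     rpkm_A = cl$rpkm_A, rpkm_B = cl$rpkm_B,
                     sort_key = cl$sort_key, stringsAsFactors = FALSE)
    write_tsv_file(df, file.path(outdir, "constituent_labels.tsv"))
    cl
  })
  counts <- table(factor(constituents$label,
                         c("A_SPECIFIC", "SHARED", "B_SPECIFIC")))
  ratios <- cluster_abundance_ratios(counts[["A_SPECIFIC"]],
                                     counts[["SHARED"]],
                                     counts[["B_SPECIFIC"]])
  write_tsv_file(data.frame(quantity = c(names(counts),
                                         "A_to_shared_ratio",
                                         "B_to_shared_ratio"),
                            value = c(as.numeric(counts), ratios)),
                 file.path(outdir, "cluster_summary.tsv"))
  note("constituent clusters: A=%d shared=%d B=%d",
       counts[[1]], counts[[2]], counts[[3]])
  record("classify_constituents", n_A_specific = counts[["A_SPECIFIC"]],
         n_shared = counts[["SHARED"]],
         n_B_specific = counts[["B_SPECIFIC"]])

  # ---- motif landscape -------------------------------------------------
  current_stage <- "motif_analysis"
  motif_res <- run({
    scores <- top_motif_scores(res$genome, constituents, res$pwms,
                               cfg$motif_halfwidth_bp)
    thresholds <- list()
    for (pid in names(res$pwms)) {
      manual <- if (is.null(config$thresholds)) NULL
                else config$thresholds[[pid]]
      thresholds[[pid]] <- select_score_threshold(scores[, pid],
                                                  manual = manual)
    }
    thr <- vapply(thresholds, `[[`, numeric(1), "threshold")
    write_tsv_file(data.frame(pwm = names(thr), threshold = unname(thr),
                              provenance = vapply(thresholds, `[[`,
                                                  character(1), "provenance")),
                   file.path(outdir, "motif_thresholds.tsv"))
    presence <- motif_presence(scores, thr)
    bg_regions <- sample_background_regions(res$genome,
                                            config$n_background_regions,
                                            cfg$motif_halfwidth_bp)
    bg_scores <- top_motif_scores(res$genome, bg_regions, res$pwms,
                                  cfg$motif_halfwidth_bp)
    enr <- list()
    for (lab in c("A_SPECIFIC", "SHARED", "B_SPECIFIC")) {
      sel <- constituents$label == lab
      if (!any(sel)) next
      for (pid in names(res$pwms)) {
        e <- enrichment_test(scores[sel, pid], bg_scores[, pid], thr[[pid]])
        enr[[length(enr) + 1L]] <- data.frame(
          label = lab, pwm = pid, target_fraction = e$target_fraction,
          background_fraction = e$background_fraction, p_value = e$p_value,
          n_target = e$n_target, stringsAsFactors = FALSE)
      }
    }
    enr <- do.call(rbind, enr)
    write_tsv_file(enr, file.path(outdir, "motif_enrichment.tsv"))
    hits <- motif_hits(res$genome, constituents, res$pwms,
                       cfg$motif_frame_bp, thr)
    dist <- motif_distribution(hits, length(constituents), res$pwms,
                               cfg$motif_frame_bp, cfg$motif_window_bp)
    # per-label bin profiles, one block per motif
    prof <- list()
    for (pid in names(res$pwms)) {
      for (lab in c("A_SPECIFIC", "SHARED", "B_SPECIFIC")) {
        sel <- constituents$label == lab
        if (!any(sel)) next
        prof[[length(prof) + 1L]] <- data.frame(
          pwm = pid, label = lab,
          t(colSums(dist[sel, , pid, drop = FALSE])),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    write_tsv_file(do.call(rbind, prof),
                   file.path(outdir, "motif_distribution.tsv"))
    subset <- config$motif_subset
    if (is.null(subset))
      subset <- intersect(c("ERE", "FOX", "AP2", "TEAD", "TCF"),
                          colnames(presence))
    sub <- cluster_by_motif_presence(presence, subset)
    write_tsv_file(data.frame(index = seq_along(constituents),
                              label = constituents$label,
                              pattern = sub$label),
                   file.path(outdir, "motif_subclusters.tsv"))
    list(scores = scores, thresholds = thr, presence = presence,
         enrichment = enr, distribution = dist, subclusters = sub,
         background_scores = bg_scores)
  })
  record("motif_analysis", n_motifs = ncol(motif_res$scores),
         n_background_regions = config$n_background_regions)

  # ---- TF density, correlation, co-binding ----------------------------
  current_stage <- "cooccupancy"
  cooc <- run({
    all_tracks <- list()
    for (side in c("A", "B")) {
      cell <- res$cells[[side]]
      for (tf in names(cell$tracks))
        all_tracks[[paste(cell$name, tf, sep = "_")]] <- cell$tracks[[tf]]
    }
    dm <- build_density_matrix(constituents, all_tracks,
                               halfwidth = cfg$rpkm_halfwidth_bp,
                               mode = cfg$read_count_mode)
    rownames(dm) <- sprintf("const_%04d", seq_along(constituents))
    write_matrix_tsv(dm, file.path(outdir, "density_matrix.tsv"))
    gm <- density_group_means(dm, motif_res$subclusters$label)
    write_matrix_tsv(gm, file.path(outdir, "density_subcluster_means.tsv"),
                     rowname_header = "pattern")
    cors <- list()
    for (side in c("A", "B")) {
      cell <- res$cells[[side]]
      cols <- grep(paste0("^", cell$name, "_"), colnames(dm), value = TRUE)
      cm <- correlation_matrix(dm[, cols, drop = FALSE],
                               scale = cfg$correlation_scale,
                               eps = cfg$fpkm_pseudocount)
      write_matrix_tsv(cm, file.path(outdir,
                                     sprintf("correlation_%s.tsv", cell$name)),
                       rowname_header = "track")
      cors[[side]] <- cm
    }
    list(density = dm, group_means = gm, correlations = cors)
  })
  record("cooccupancy", n_tracks = ncol(cooc$density))

  # ---- shared SEs: overlap, breakdown, co-binding, composition --------
  current_stage <- "shared_se_analysis"
  shared <- run({
    ov <- overlap_se_regions(se_calls$A$supers, se_calls$B$supers)
    hull_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(ov$hulls)),
      start = GenomicRanges::start(ov$hulls) - 1L,
      end = GenomicRanges::end(ov$hulls),
      n_A_regions = ov$hulls$n_A, n_B_regions = ov$hulls$n_B,
      stringsAsFactors = FALSE)
    write_tsv_file(hull_df, file.path(outdir, "shared_ses.tsv"))
    bd <- shared_se_constituent_breakdown(ov$hulls, constituents)
    write_tsv_file(bd$per_hull, file.path(outdir, "shared_se_breakdown.tsv"))
    summ <- GenomicRanges::GRanges(GenomicRanges::seqnames(constituents),
                                   IRanges::IRanges(constituents$summit + 1L,
                                                    width = 1L))
    in_hull <- IRanges::overlapsAny(summ, ov$hulls)
    cb <- list()
    for (side in c("A", "B")) {
      lab <- if (side == "A") "A_SPECIFIC" else "B_SPECIFIC"
      cell <- res$cells[[side]]
      collab_peaks <- cell$peaks[setdiff(names(cell$peaks), master)]
      sel <- in_hull & constituents$label == lab
      r <- count_cobound(constituents[sel], collab_peaks,
                         halfwidth = cfg$motif_halfwidth_bp,
                         min_tfs = cfg$min_cobind_tfs)
      cb[[side]] <- data.frame(
        cell_line = cell$name, constituent_label = lab,
        n_constituents = sum(sel),
        fraction_cobound = r$fraction_cobound,
        fraction_low = r$fraction_low, stringsAsFactors = FALSE)
    }
    cb <- do.call(rbind, cb)
    write_tsv_file(cb, file.path(outdir, "cobinding.tsv"))
    comp <- motif_composition(
      motif_res$presence[in_hull, , drop = FALSE],
      constituents$label[in_hull])
    write_tsv_file(comp$table, file.path(outdir, "motif_composition.tsv"))
    if (!is.null(comp$combinations))
      write_tsv_file(comp$combinations,
                     file.path(outdir, "motif_combinations.tsv"))
    list(overlap = ov, breakdown = bd, cobinding = cb, composition = comp)
  })
  note("shared SEs: %d hulls, %s shared constituents inside",
       length(shared$overlap$hulls), shared$breakdown$totals[["SHARED"]])
  record("shared_se_analysis", n_hulls = length(shared$overlap$hulls),
         n_shared_constituents = shared$breakdown$totals[["SHARED"]])

  # ---- annotation and expression --------------------------------------
  current_stage <- "annotation_expression"
  expr_res <- run({
    sets <- list(
      A_specific = list(
        regions = se_calls$A$supers[
          !IRanges::overlapsAny(se_calls$A$supers, se_calls$B$supers)],
        side = "A"),
      shared = list(regions = shared$overlap$hulls, side = "A"),
      B_specific = list(
        regions = se_calls$B$supers[
          !IRanges::overlapsAny(se_calls$B$supers, se_calls$A$supers)],
        side = "B"))
    ann_all <- list(); cls_all <- list()
    for (lb in names(sets)) {
      regions <- sets[[lb]]$regions
      if (length(regions) == 0) next
      cell <- res$cells[[sets[[lb]]$side]]
      ann <- annotate_se(regions, res$genes, res$expr, cell$name,
                         cell$timepoint, cfg)
      ann$se_label <- lb
      ann$chrom <- as.character(GenomicRanges::seqnames(regions))[ann$se_index]
      ann$start <- GenomicRanges::start(regions)[ann$se_index] - 1L
      ann$end <- GenomicRanges::end(regions)[ann$se_index]
      ann_all[[lb]] <- ann
      ok <- !is.na(ann$gene_id)
      if (any(ok)) {
        cls <- classify_expression(
          res$expr, unique(ann$gene_id[ok]),
          c(res$cells$A$name, res$cells$B$name),
          c(res$cells$A$timepoint, res$cells$B$timepoint), cfg)
        cls$se_label <- lb
        cls_all[[lb]] <- cls
      }
    }
    ann_all <- do.call(rbind, ann_all)
    cls_all <- do.call(rbind, cls_all)
    write_tsv_file(ann_all[, c("se_label", "chrom", "start", "end",
                               "gene_id", "rule", "mean_fpkm",
                               "distance_bp")],
                   file.path(outdir, "annotations.tsv"))
    write_tsv_file(cls_all, file.path(outdir, "expression_classes.tsv"))
    summary <- expression_summary(cls_all)
    write_tsv_file(summary, file.path(outdir, "expression_summary.tsv"))
    list(annotations = ann_all, classes = cls_all, summary = summary)
  })
  record("annotation_expression",
         n_annotated = sum(!is.na(expr_res$annotations$gene_id)),
         n_classified = nrow(expr_res$classes))

  # ---- run summary -----------------------------------------------------
  current_stage <- "summary"
  run({
    cfg_json <- file.path(outdir, "config_used.json")
    jsonlite::write_json(
      list(analysis = unclass(cfg), seed = config$seed,
           master_tf = master,
           cells = list(A = config$cells$A$name, B = config$cells$B$name)),
      cfg_json, auto_unbox = TRUE, digits = NA)
    summary <- list(stages = stage_records,
                    config_hash = unname(tools::md5sum(cfg_json)))
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("pipeline complete")
    writeLines(log_lines, file.path(outdir, "run.log"))
  })

  invisible(list(outdir = outdir, se_calls = se_calls,
                 constituents = constituents, motifs = motif_res,
                 cooccupancy = cooc, shared = shared,
                 expression = expr_res))
}
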