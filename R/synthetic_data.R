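#' Built-in motif set of the two-cell-line scenario
#'
#' Consensus-derived PWMs for the motif families that drive the scenario:
#' the palindromic estrogen response element (ERE) and the generic nuclear
#' receptor half-site (NRHALF) shared by both cell lines, the Fox/AP2
#' motifs used by cell line A, the TEAD/TCF/SIX motifs used by cell line B,
#' and a CEBP motif that is never planted and serves as a negative control
#' in enrichment tests.
#'
#' @param strength consensus base probability.
#' @return named list of [pwm] objects.
#' @export
builtin_motifs <- function(strength = 0.88) {
  cons <- c(ERE = "GGTCANNNTGACC",
            FOX = "TGTTTAC",
            AP2 = "GCCTGAGGC",
            TEAD = "ACATTCCA",
            TCF = "ACAGCTGT",
            SIX = "TGATACCA",
            NRHALF = "AGGTCA",
            CEBP = "TTGCGCAA")
  stats::setNames(lapply(names(cons), function(id)
    consensus_pwm(id, cons[[id]], strength)), names(cons))
}

#' Scenario parameters for the synthetic two-cell-line dataset
#'
#' Defines the study conditions the generator emulates: two cell lines
#' sharing a subset of ERE-nucleated super-enhancers, cell-line-specific
#' constituents carrying cell-line-specific motifs, read coverage as
#' Poisson background plus enrichment at planted peaks, and an FPKM table
#' in which shared-SE genes are expressed similarly in both lines while
#' specific-SE genes are skewed towards their own line.
#'
#' @param seed integer seed fixing all randomness.
#' @param genome_n_chrom,chrom_length_bp genome shape (default 2 x 2 Mb).
#' @param n_shared_SEs,n_A_specific_SEs,n_B_specific_SEs planted SE counts.
#' @param constituents_per_SE length-2 integer range.
#' @param peak_enrichment length-2 range of reads per SE constituent peak.
#' @param background_peak_reads length-2 range of reads per non-SE
#'   (typical) enhancer peak.
#' @param background_rate Poisson background, reads per bp.
#' @param n_background_peaks typical enhancers per cell line.
#' @param n_extra_genes distractor protein-coding genes with low
#'   expression.
#' @param fpkm_meanlog,fpkm_sdlog lognormal base-expression parameters of
#'   SE-target genes.
#' @param replicate_sdlog multiplicative replicate noise (lognormal sdlog);
#'   the default keeps the chance that an equal-mean gene exceeds the
#'   2-fold band well below 5 percent.
#' @param specific_SE_fold_effect expression multiplier of specific-SE
#'   genes in their own cell line.
#' @param n_replicates replicates per cell line.
#' @param read_length_bp synthetic read length (bookkeeping only; coverage
#'   stores read 5'-end counts).
#' @param peak_halfwidth_bp half-width of planted peak intervals.
#' @param bin_bp bedGraph bin width.
#' @param cell_names names of the two cell lines (A, B).
#' @param timepoints_min ligand-treatment timepoints of the expression
#'   samples, one per cell line.
#' @return list of class `scenario_params`.
#' @export
scenario_params <- function(seed = 1L,
                            genome_n_chrom = 2L,
                            chrom_length_bp = 2000000L,
                            n_shared_SEs = 10L,
                            n_A_specific_SEs = 10L,
                            n_B_specific_SEs = 10L,
                            constituents_per_SE = c(4L, 6L),
                            peak_enrichment = c(300L, 500L),
                            background_peak_reads = c(10L, 30L),
                            background_rate = 0.002,
                            n_background_peaks = 60L,
                            n_extra_genes = 30L,
                            fpkm_meanlog = 3.0,
                            fpkm_sdlog = 0.6,
                            replicate_sdlog = 0.15,
                            specific_SE_fold_effect = 4,
                            n_replicates = 2L,
                            read_length_bp = 50L,
                            peak_halfwidth_bp = 200L,
                            bin_bp = 50L,
                            cell_names = c("cellA", "cellB"),
                            timepoints_min = c(320L, 240L)) {
  p <- as.list(environment())
  if (any(unlist(p[c("n_shared_SEs", "n_A_specific_SEs", "n_B_specific_SEs",
                     "n_background_peaks", "n_extra_genes")]) < 0))
    stop("counts must be >= 0")
  if (p$n_replicates < 2) stop("need >= 2 replicates per cell line")
  if (diff(constituents_per_SE) < 0 || constituents_per_SE[1] < 1)
    stop("invalid constituents_per_SE range")
  structure(p, class = "scenario_params")
}

# deterministic integer draw in [lo, hi]
rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Embed a motif consensus into a DNA sequence
#'
#' Writes the consensus bases of the PWM (reverse-complemented for the
#' minus strand) at the given 0-based position; the rest of the sequence is
#' unchanged.
#'
#' @param sequence DNA string.
#' @param x `pwm`.
#' @param position 0-based offset of the motif start.
#' @param strand `"+"` or `"-"`.
#' @return modified DNA string.
#' @export
embed_motif <- function(sequence, x, position, strand = "+") {
  L <- pwm_length(x)
  n <- nchar(sequence)
  if (position < 0 || position + L > n)
    stop("motif does not fit at position ", position)
  cons <- pwm_consensus(x)
  if (strand == "-") cons <- revcomp(cons)
  paste0(substr(sequence, 1, position),
         cons,
         substr(sequence, position + L + 1, n))
}

# SE layout constants (bp within a 120-kb slot); chosen so that planted
# items can never stitch across each other and so that each SE's +/-100 kb
# annotation window contains its own target gene but never a neighbouring
# slot's: SE constituents live in [20k, ~52k), the target gene TSS at
# ~45k, background peaks at 84/100k (cell A) and 92/108k (cell B),
# distractor genes at ~110k.
SLOT_BP <- 120000L
SE_OFFSET <- 20000L
GENE_OFFSET <- 45000L
BG_OFFSETS_A <- c(84000L, 100000L)
BG_OFFSETS_B <- c(92000L, 108000L)
EXTRA_GENE_OFFSET <- 110000L

# role/motif program of one SE's constituents
constituent_program <- function(label, n_c) {
  role <- character(n_c); motifs <- vector("list", n_c)
  if (label == "shared") {
    mother <- ceiling(n_c / 2)
    a_next <- TRUE
    amot <- list("FOX", c("FOX", "AP2"), "AP2")
    bmot <- list("TEAD", c("TEAD", "TCF"), "TCF")
    ai <- 1L; bi <- 1L
    for (j in seq_len(n_c)) {
      if (j == mother) {
        role[j] <- "shared"; motifs[[j]] <- "ERE"
      } else if (j == 1 && n_c >= 5) {
        role[j] <- "shared"; motifs[[j]] <- "NRHALF"
      } else if (a_next) {
        role[j] <- "A_only"; motifs[[j]] <- amot[[(ai - 1) %% 3 + 1]]
        ai <- ai + 1
        a_next <- FALSE
      } else {
        role[j] <- "B_only"; motifs[[j]] <- bmot[[(bi - 1) %% 3 + 1]]
        bi <- bi + 1
        a_next <- TRUE
      }
    }
  } else if (label == "A_specific") {
    prog <- list("ERE", "FOX", "AP2", character(0), c("ERE", "FOX"), "FOX")
    for (j in seq_len(n_c)) {
      role[j] <- "A_only"
      motifs[[j]] <- prog[[(j - 1) %% 6 + 1]]
    }
  } else {
    prog <- list(c("NRHALF", "TEAD"), "TEAD", "TCF", character(0),
                 c("TEAD", "TCF"), "SIX")
    for (j in seq_len(n_c)) {
      role[j] <- "B_only"
      motifs[[j]] <- prog[[(j - 1) %% 6 + 1]]
    }
  }
  list(role = role, motifs = motifs)
}

# Poisson background + planted-peak reads, binned 5'-end counts per chrom.
# peaks: data.frame(chrom, summit0, reads). Returns coverage_track.
simulate_track <- function(peaks, chrom_lengths, rate, bin, read_sd = 60) {
  chrom_v <- character(0); start_v <- integer(0); end_v <- integer(0)
  score_v <- numeric(0); total <- 0
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    nbins <- ceiling(len / bin)
    counts <- stats::rpois(nbins, rate * bin)
    sel <- which(peaks$chrom == chrom)
    for (i in sel) {
      nr <- peaks$reads[i]
      if (nr <= 0) next
      starts <- round(stats::rnorm(nr, peaks$summit0[i], read_sd))
      starts <- pmin(pmax(starts, 0), len - 1)
      counts <- counts + tabulate(starts %/% bin + 1L, nbins)
    }
    total <- total + sum(counts)
    nz <- which(counts > 0)
    if (length(nz) > 0) {
      chrom_v <- c(chrom_v, rep(chrom, length(nz)))
      start_v <- c(start_v, (nz - 1L) * bin + 1L)
      end_v <- c(end_v, pmin(nz * bin, len))
      score_v <- c(score_v, counts[nz])
    }
  }
  gr <- GenomicRanges::GRanges(chrom_v, IRanges::IRanges(start_v, end_v),
                               score = score_v)
  coverage_track(gr, max(total, 1))
}

#' Generate the complete two-cell-line synthetic dataset
#'
#' Lays planted super-enhancers, typical enhancers, genes and expression on
#' a random genome, then emits every file the pipeline consumes: a FASTA
#' genome with embedded motif consensi, per-cell-line per-TF narrowPeak
#' files and bedGraph coverage tracks (with a library-size table), a gene
#' model, an FPKM table with sample metadata, JASPAR PFM files, a ready
#' pipeline config (YAML) and the ground-truth tables. Deterministic given
#' the seed: reruns produce byte-identical files.
#'
#' @param params `scenario_params`.
#' @param dir output directory (created).
#' @return list with `dir`, `paths` (named file paths), `truth` (list of
#'   data.frames `ses`, `constituents`, `genes`), and `params`.
#' @export
generate_scenario <- function(params = scenario_params(), dir = tempfile("scenario_")) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "tracks", "motifs", "truth"))
    dir.create(file.path(dir, d), showWarnings = FALSE)

  chroms <- paste0("chr", seq_len(params$genome_n_chrom))
  chrom_lengths <- stats::setNames(rep(as.integer(params$chrom_length_bp),
                                       length(chroms)), chroms)
  slots_per_chrom <- params$chrom_length_bp %/% SLOT_BP
  n_slots <- slots_per_chrom * length(chroms)
  n_se <- params$n_shared_SEs + params$n_A_specific_SEs + params$n_B_specific_SEs
  if (n_se > n_slots)
    stop("cannot place ", n_se, " SEs in ", n_slots,
         " slots; enlarge the genome (chrom_length_bp or genome_n_chrom)")
  if (params$n_background_peaks > 2L * n_slots)
    stop("too many background peaks for this genome; enlarge the genome")

  slot_chrom <- rep(chroms, each = slots_per_chrom)
  slot_base <- rep((seq_len(slots_per_chrom) - 1L) * SLOT_BP, length(chroms))

  se_labels <- c(rep("shared", params$n_shared_SEs),
                 rep("A_specific", params$n_A_specific_SEs),
                 rep("B_specific", params$n_B_specific_SEs))
  se_slots <- sort(sample.int(n_slots, n_se))
  se_labels <- sample(se_labels)
  hw <- params$peak_halfwidth_bp
  motifs <- builtin_motifs()

  # ---- plant SEs and constituents -------------------------------------
  const <- list(); ses <- list()
  for (i in seq_len(n_se)) {
    slot <- se_slots[i]
    chrom <- slot_chrom[slot]; base <- slot_base[slot]
    n_c <- rint(1, params$constituents_per_SE[1], params$constituents_per_SE[2])
    prog <- constituent_program(se_labels[i], n_c)
    pos <- base + SE_OFFSET + rint(1, 0, 2000)
    summits <- integer(n_c)
    for (j in seq_len(n_c)) {
      summits[j] <- pos
      pos <- pos + rint(1, 1500, 3000)
    }
    reads <- rint(n_c, params$peak_enrichment[1], params$peak_enrichment[2])
    const[[i]] <- data.frame(
      const_id = sprintf("SE%02d_c%d", i, seq_len(n_c)),
      se_id = sprintf("SE%02d", i), chrom = chrom,
      start = summits - hw, end = summits + hw, summit = summits,
      role = prog$role,
      motifs = vapply(prog$motifs, paste, character(1), collapse = ","),
      reads = reads, stringsAsFactors = FALSE)
    cc <- const[[i]]
    in_A <- cc$role %in% c("shared", "A_only")
    in_B <- cc$role %in% c("shared", "B_only")
    ses[[i]] <- data.frame(
      se_id = sprintf("SE%02d", i), chrom = chrom, label = se_labels[i],
      start = min(cc$start), end = max(cc$end),
      hull_A_start = if (any(in_A)) min(cc$start[in_A]) else NA_integer_,
      hull_A_end = if (any(in_A)) max(cc$end[in_A]) else NA_integer_,
      hull_B_start = if (any(in_B)) min(cc$start[in_B]) else NA_integer_,
      hull_B_end = if (any(in_B)) max(cc$end[in_B]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  const <- do.call(rbind, const)
  ses <- do.call(rbind, ses)
  const$label <- c(shared = "SHARED", A_only = "A_SPECIFIC",
                   B_only = "B_SPECIFIC")[const$role]

  # ---- background (typical) enhancers ---------------------------------
  bg_peak_df <- function(offsets, prefix) {
    k <- params$n_background_peaks
    if (k == 0)
      return(data.frame(name = character(0), chrom = character(0),
                        summit = integer(0), reads = integer(0)))
    slot <- rep(seq_len(n_slots), each = length(offsets))[seq_len(k)]
    off <- rep(offsets, times = n_slots)[seq_len(k)]
    summit <- slot_base[slot] + off + rint(k, 0, 500)
    data.frame(name = sprintf("%s_bg%03d", prefix, seq_len(k)),
               chrom = slot_chrom[slot], summit = summit,
               reads = rint(k, params$background_peak_reads[1],
                            params$background_peak_reads[2]),
               stringsAsFactors = FALSE)
  }
  bg_A <- bg_peak_df(BG_OFFSETS_A, "A")
  bg_B <- bg_peak_df(BG_OFFSETS_B, "B")

  # ---- genes and expression -------------------------------------------
  genes <- list(); fpkm_mean <- list()
  for (i in seq_len(n_se)) {
    slot <- se_slots[i]
    tss <- slot_base[slot] + GENE_OFFSET + rint(1, 0, 500)
    strand <- if (i %% 2 == 0) "-" else "+"
    gid <- sprintf("G%03d", i)
    body <- if (strand == "+") c(tss, tss + 20000L)
            else c(tss - 19999L, tss + 1L)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, chrom = slot_chrom[slot], strand = strand, tss = tss,
      start = body[1], end = body[2], biotype = "protein_coding",
      se_id = ses$se_id[i], se_label = ses$label[i], stringsAsFactors = FALSE)
    base_expr <- stats::rlnorm(1, params$fpkm_meanlog, params$fpkm_sdlog)
    fe <- params$specific_SE_fold_effect
    mean_A <- if (ses$label[i] == "A_specific") base_expr * fe else base_expr
    mean_B <- if (ses$label[i] == "B_specific") base_expr * fe else base_expr
    fpkm_mean[[gid]] <- c(A = mean_A, B = mean_B)
    if (i %% 3 == 0) {  # non-coding decoy near the SE, highly expressed
      dtss <- slot_base[slot] + SE_OFFSET + 15000L + rint(1, 0, 500)
      did <- sprintf("NC%03d", i)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = did, chrom = slot_chrom[slot], strand = "+", tss = dtss,
        start = dtss, end = dtss + 5000L, biotype = "lincRNA",
        se_id = NA_character_, se_label = NA_character_,
        stringsAsFactors = FALSE)
      fpkm_mean[[did]] <- c(A = 80, B = 80)
    }
  }
  extra_slots <- rep(seq_len(n_slots), length.out = params$n_extra_genes)
  for (k in seq_len(params$n_extra_genes)) {
    slot <- extra_slots[k]
    tss <- slot_base[slot] + EXTRA_GENE_OFFSET + rint(1, 0, 500)
    gid <- sprintf("X%03d", k)
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, chrom = slot_chrom[slot], strand = "+", tss = tss,
      start = tss, end = tss + 8000L, biotype = "protein_coding",
      se_id = NA_character_, se_label = NA_character_,
      stringsAsFactors = FALSE)
    base_expr <- stats::rlnorm(1, 0, 0.7)
    fpkm_mean[[gid]] <- c(A = base_expr, B = base_expr)
  }
  genes <- do.call(rbind, genes)

  cells <- params$cell_names
  samples <- expand.grid(replicate = seq_len(params$n_replicates),
                         cell = c("A", "B"), stringsAsFactors = FALSE)
  samples$cell_line <- cells[match(samples$cell, c("A", "B"))]
  samples$timepoint <- params$timepoints_min[match(samples$cell, c("A", "B"))]
  samples$sample <- sprintf("%s_t%d_r%d", samples$cell_line,
                            samples$timepoint, samples$replicate)
  fpkm <- matrix(0, nrow = nrow(genes), ncol = nrow(samples),
                 dimnames = list(genes$gene_id, samples$sample))
  for (g in genes$gene_id) {
    mu <- fpkm_mean[[g]]
    for (s in seq_len(nrow(samples))) {
      fpkm[g, s] <- mu[[samples$cell[s]]] *
        stats::rlnorm(1, 0, params$replicate_sdlog)
    }
  }

  # ---- genome with embedded motifs ------------------------------------
  genome_chars <- lapply(chrom_lengths, function(len)
    sample(c("A", "C", "G", "T"), len, replace = TRUE))
  for (i in seq_len(nrow(const))) {
    mids <- strsplit(const$motifs[i], ",", fixed = TRUE)[[1]]
    mids <- mids[nzchar(mids)]
    if (length(mids) == 0) next
    centers <- if (length(mids) == 1) const$summit[i]
               else const$summit[i] + c(-20L, 20L)
    for (k in seq_along(mids)) {
      m <- motifs[[mids[k]]]
      L <- pwm_length(m)
      cons <- pwm_consensus(m)
      if (stats::runif(1) < 0.5) cons <- revcomp(cons)
      start0 <- centers[k] - L %/% 2L
      genome_chars[[const$chrom[i]]][(start0 + 1):(start0 + L)] <-
        strsplit(cons, "")[[1]]
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chroms

  # ---- peaks and coverage per cell line / TF --------------------------
  collab <- list(A = c("FOXA1", "AP2G"), B = c("TEAD4", "TCF12"))
  collab_motif <- c(FOXA1 = "FOX", AP2G = "AP2", TEAD4 = "TEAD", TCF12 = "TCF")
  peak_paths <- list(); track_paths <- list(); lib_sizes <- list()
  master_const <- list(A = const[const$role %in% c("shared", "A_only"), ],
                       B = const[const$role %in% c("shared", "B_only"), ])
  bg <- list(A = bg_A, B = bg_B)
  for (side in c("A", "B")) {
    cell <- cells[match(side, c("A", "B"))]
    mc <- master_const[[side]]
    master_df <- data.frame(
      name = c(mc$const_id, bg[[side]]$name),
      chrom = c(mc$chrom, bg[[side]]$chrom),
      summit0 = c(mc$summit, bg[[side]]$summit),
      reads = c(mc$reads, bg[[side]]$reads), stringsAsFactors = FALSE)
    tf_defs <- list(ER = master_df)
    for (tf in collab[[side]]) {
      sel <- grepl(paste0("(^|,)", collab_motif[[tf]], "(,|$)"), mc$motifs)
      cc <- mc[sel, , drop = FALSE]
      # collaborators are enriched at roughly half the master's level
      clo <- params$peak_enrichment[1] %/% 2L
      chi <- max(params$peak_enrichment[2] %/% 2L, clo)
      tf_defs[[tf]] <- data.frame(
        name = paste0(tf, "_", cc$const_id), chrom = cc$chrom,
        summit0 = cc$summit, reads = rint(nrow(cc), clo, chi),
        stringsAsFactors = FALSE)
    }
    for (tf in names(tf_defs)) {
      df <- tf_defs[[tf]]
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$summit0 - hw + 1L,
                                                    df$summit0 + hw))
      gr$name <- df$name
      gr$score <- as.numeric(df$reads)
      gr$summit <- as.integer(df$summit0)
      gr$signalValue <- as.numeric(df$reads)
      gr$pValue <- -1
      gr$qValue <- -1
      gr$peak_offset <- hw
      pp <- file.path(dir, "peaks", sprintf("%s_%s.narrowPeak", cell, tf))
      write_peaks(GenomicRanges::sort(gr), pp, format = "narrowPeak")
      peak_paths[[paste(cell, tf, sep = "_")]] <- pp
      track <- simulate_track(
        data.frame(chrom = df$chrom, summit0 = df$summit0, reads = df$reads),
        chrom_lengths, params$background_rate, params$bin_bp)
      tp <- file.path(dir, "tracks", sprintf("%s_%s.bedGraph", cell, tf))
      write_bedgraph(track, tp)
      track_paths[[paste(cell, tf, sep = "_")]] <- tp
      lib_sizes[[paste(cell, tf, sep = "_")]] <- track$total_mapped_reads
    }
  }
  libs <- data.frame(track = names(lib_sizes),
                     total_reads = unlist(lib_sizes),
                     stringsAsFactors = FALSE)
  write_tsv_file(libs, file.path(dir, "tracks", "library_sizes.tsv"))

  # ---- remaining files -------------------------------------------------
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  for (id in names(motifs))
    write_pfm(motifs[[id]], file.path(dir, "motifs", paste0(id, ".pfm")))
  gene_file <- genes[, c("gene_id", "chrom", "strand", "tss", "start",
                         "end", "biotype")]
  write_tsv_file(gene_file, file.path(dir, "genes.tsv"))
  expr_df <- data.frame(gene_id = rownames(fpkm),
                        apply(fpkm, 2, function(x) sprintf("%.4f", x)),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(expr_df, file.path(dir, "expression.tsv"))
  write_tsv_file(samples[, c("sample", "cell_line", "timepoint", "replicate")],
                 file.path(dir, "samples.tsv"))

  truth_genes <- genes[!is.na(genes$se_id),
                       c("gene_id", "se_id", "se_label")]
  truth_genes$expected_class <- c(shared = "SIMILAR",
                                  A_specific = "A_SPECIFIC",
                                  B_specific = "B_SPECIFIC")[truth_genes$se_label]
  write_tsv_file(ses, file.path(dir, "truth", "ses.tsv"))
  write_tsv_file(const, file.path(dir, "truth", "constituents.tsv"))
  write_tsv_file(truth_genes, file.path(dir, "truth", "genes.tsv"))
  jsonlite::write_json(
    list(seed = params$seed, replicate_sdlog = params$replicate_sdlog,
         specific_SE_fold_effect = params$specific_SE_fold_effect,
         n_se = n_se, cells = cells),
    file.path(dir, "truth", "params.json"), auto_unbox = TRUE, digits = NA)

  cfg <- list(
    genome = "genome.fa",
    motif_dir = "motifs",
    genes = "genes.tsv",
    expression = "expression.tsv",
    samples = "samples.tsv",
    library_sizes = "tracks/library_sizes.tsv",
    master_tf = "ER",
    cells = list(
      A = list(name = cells[1], timepoint = params$timepoints_min[1],
               peaks = stats::setNames(
                 as.list(sprintf("peaks/%s_%s.narrowPeak", cells[1],
                                 c("ER", collab$A))), c("ER", collab$A)),
               tracks = stats::setNames(
                 as.list(sprintf("tracks/%s_%s.bedGraph", cells[1],
                                 c("ER", collab$A))), c("ER", collab$A))),
      B = list(name = cells[2], timepoint = params$timepoints_min[2],
               peaks = stats::setNames(
                 as.list(sprintf("peaks/%s_%s.narrowPeak", cells[2],
                                 c("ER", collab$B))), c("ER", collab$B)),
               tracks = stats::setNames(
                 as.list(sprintf("tracks/%s_%s.bedGraph", cells[2],
                                 c("ER", collab$B))), c("ER", collab$B)))),
    seed = params$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  list(dir = dir,
       paths = c(list(genome = file.path(dir, "genome.fa"),
                      genes = file.path(dir, "genes.tsv"),
                      expression = file.path(dir, "expression.tsv"),
                      samples = file.path(dir, "samples.tsv"),
                      config = file.path(dir, "config.yaml"),
                      library_sizes = file.path(dir, "tracks",
                                                "library_sizes.tsv")),
                 peaks = peak_paths, tracks = track_paths),
       truth = list(ses = ses, constituents = const, genes = truth_genes),
       params = params)
}
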