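test_that("scenario generation is deterministic and honours zero counts", {
  p <- scenario_params(seed = 99, n_shared_SEs = 2, n_A_specific_SEs = 2,
                       n_B_specific_SEs = 0, n_background_peaks = 6,
                       n_extra_genes = 4, chrom_length_bp = 600000L)
  d1 <- file.path(tempdir(), "sc_det1"); unlink(d1, recursive = TRUE)
  d2 <- file.path(tempdir(), "sc_det2"); unlink(d2, recursive = TRUE)
  s1 <- generate_scenario(p, d1)
  s2 <- generate_scenario(p, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 15)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  # no B-specific labels when none were requested
  expect_false("B_specific" %in% s1$truth$ses$label)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero background and enrichment yield empty coverage", {
  p <- scenario_params(seed = 5, n_shared_SEs = 2, n_A_specific_SEs = 1,
                       n_B_specific_SEs = 1, n_background_peaks = 2,
                       n_extra_genes = 2, chrom_length_bp = 600000L,
                       background_rate = 0, peak_enrichment = c(0L, 0L),
                       background_peak_reads = c(0L, 0L))
  d <- file.path(tempdir(), "sc_zero"); unlink(d, recursive = TRUE)
  s <- generate_scenario(p, d)
  for (tp in unlist(s$paths[grepl("^tracks", names(s$paths))]))
    expect_equal(length(readLines(tp)), 0)
  unlink(d, recursive = TRUE)
})

test_that("generation fails with a helpful error when the genome is too small", {
  p <- scenario_params(seed = 1, chrom_length_bp = 300000L)
  expect_error(generate_scenario(p, tempfile()), "enlarge the genome")
})

test_that("truth labels partition the planted constituents", {
  sc <- default_scenario()
  const <- sc$truth$constituents
  expect_false(any(duplicated(const$const_id)))
  expect_true(all(const$label %in% c("A_SPECIFIC", "SHARED", "B_SPECIFIC")))
  # every constituent lies inside exactly one planted SE hull
  ses <- sc$truth$ses
  n_in <- vapply(seq_len(nrow(const)), function(i) {
    sum(ses$chrom == const$chrom[i] & ses$start <= const$start[i] &
          const$end[i] <= ses$end)
  }, integer(1))
  expect_true(all(n_in == 1))
  # labels consistent with which cell lines received master peaks
  pkA <- read_peaks(sc$paths$peaks.cellA_ER)
  pkB <- read_peaks(sc$paths$peaks.cellB_ER)
  expect_true(all(const$summit[const$label != "B_SPECIFIC"] %in% pkA$summit))
  expect_false(any(const$summit[const$label == "B_SPECIFIC"] %in% pkA$summit))
  expect_true(all(const$summit[const$label != "A_SPECIFIC"] %in% pkB$summit))
})

test_that("planted summits stand far above background coverage", {
  sc <- default_scenario()
  libs <- read.delim(sc$paths$library_sizes)
  tr <- read_bedgraph(sc$paths$tracks.cellA_ER,
                      libs$total_reads[libs$track == "cellA_ER"])
  const <- sc$truth$constituents
  inA <- const[const$label != "B_SPECIFIC", ]
  pk <- genomic_interval(inA$chrom, inA$start, inA$end)
  pk$summit <- inA$summit
  peak_rpkm <- compute_rpkm(tr, pk, halfwidth = 50)
  # background windows: fixed offsets far from any planted feature
  bg_pos <- seq(60000, 1900000, by = 120000)
  bg <- genomic_interval(rep(c("chr1", "chr2"), each = length(bg_pos)),
                         rep(bg_pos - 200, 2), rep(bg_pos + 200, 2))
  bg$summit <- rep(bg_pos, 2)
  bg_rpkm <- compute_rpkm(tr, bg, halfwidth = 50)
  expect_true(all(peak_rpkm > quantile(bg_rpkm, 0.95)))
})

test_that("scanning an embedded consensus recovers the maximum score", {
  sc <- default_scenario()
  genome <- Biostrings::readDNAStringSet(sc$paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  motifs <- builtin_motifs()
  const <- sc$truth$constituents
  with_m <- const[const$motifs != "", ][1:10, ]
  for (i in seq_len(nrow(with_m))) {
    first <- strsplit(with_m$motifs[i], ",")[[1]][1]
    sc_top <- top_motif_score(genome, with_m$chrom[i], with_m$summit[i],
                              motifs[[first]], 100)
    expect_equal(sc_top, pwm_max_score(motifs[[first]]), tolerance = 1e-9)
  }
})
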