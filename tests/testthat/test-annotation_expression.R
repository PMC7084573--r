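# in-memory expression fixture: 2 cell lines x 2 replicates
mk_expr <- function(genes, a1, a2, b1, b2) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  m <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  df <- data.frame(gene_id = genes, A_r1 = a1, A_r2 = a2,
                   B_r1 = b1, B_r2 = b2)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = c("A_r1", "A_r2", "B_r1", "B_r2"),
                     cell_line = c("A", "A", "B", "B"),
                     timepoint = c(320, 320, 240, 240),
                     replicate = c(1, 2, 1, 2))
  write.table(meta, m, sep = "\t", quote = FALSE, row.names = FALSE)
  read_expression(f, m)
}

mk_genes <- function(...) {
  g <- data.frame(...)
  g$is_protein_coding <- g$biotype == "protein_coding"
  g
}

test_that("SE annotation prefers the highest-expressed promoter in window", {
  genes <- mk_genes(
    gene_id = c("G1", "G2", "NC1", "FAR"),
    chrom = "chr1", strand = "+",
    tss = c(150000, 180000, 160000, 900000),
    start = c(150000, 180000, 160000, 900000),
    end = c(170000, 200000, 165000, 920000),
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "protein_coding"))
  expr <- mk_expr(c("G1", "G2", "NC1", "FAR"),
                  c(5, 50, 100, 3), c(5, 50, 100, 3),
                  c(5, 50, 100, 3), c(5, 50, 100, 3))
  se <- genomic_interval("chr1", 99000, 101000)  # centre 100000
  ann <- annotate_se(se, genes, expr, "A", 320)
  # both promoters in the +/-100 kb window; G2 has the higher FPKM, and the
  # non-coding NC1 (FPKM 100) is ignored
  expect_equal(ann$gene_id, "G2")
  expect_equal(ann$rule, "promoter_overlap")
})

test_that("annotation falls back to the nearest sufficiently expressed gene", {
  genes <- mk_genes(
    gene_id = c("NEAR", "NEXT"),
    chrom = "chr1", strand = "+",
    tss = c(300000, 350000), start = c(300000, 350000),
    end = c(310000, 360000), biotype = "protein_coding")
  expr <- mk_expr(c("NEAR", "NEXT"), c(0.5, 3), c(0.5, 3),
                  c(0.5, 3), c(0.5, 3))
  se <- genomic_interval("chr1", 99000, 101000)
  ann <- annotate_se(se, genes, expr, "A", 320)
  # NEAR is closer but below 1 FPKM -> NEXT is assigned
  expect_equal(ann$gene_id, "NEXT")
  expect_equal(ann$rule, "nearest_fallback")
  # no eligible gene anywhere -> none
  expr0 <- mk_expr(c("NEAR", "NEXT"), c(0.5, 0.2), c(0.5, 0.2),
                   c(0.5, 0.2), c(0.5, 0.2))
  ann0 <- annotate_se(se, genes, expr0, "A", 320)
  expect_equal(ann0$rule, "none")
  expect_true(is.na(ann0$gene_id))
  expect_error(annotate_se(se, genes[0, ], expr, "A", 320), "empty")
})

test_that("annotation is invariant under gene-list permutation", {
  set.seed(51)
  genes <- mk_genes(
    gene_id = sprintf("G%02d", 1:12), chrom = "chr1", strand = "+",
    tss = seq(50000, 160000, by = 10000),
    start = seq(50000, 160000, by = 10000),
    end = seq(50000, 160000, by = 10000) + 5000,
    biotype = "protein_coding")
  fp <- rexp(12, 1 / 20)
  expr <- mk_expr(genes$gene_id, fp, fp, fp, fp)
  se <- genomic_interval("chr1", 99000, 101000)
  base <- annotate_se(se, genes, expr, "A", 320)
  for (i in 1:5) {
    perm <- sample(nrow(genes))
    expect_equal(annotate_se(se, genes[perm, ], expr, "A", 320)$gene_id,
                 base$gene_id)
  }
})

test_that("2-fold classification applies the all-pairs rule strictly", {
  expr <- mk_expr(c("sim", "aspec", "border"),
                  a1 = c(10, 50, 20), a2 = c(12, 60, 20),
                  b1 = c(10, 5, 10), b2 = c(11, 6, 10))
  cls <- classify_expression(expr, c("sim", "aspec", "border"),
                             c("A", "B"), c(320, 240))
  expect_equal(cls$class, c("SIMILAR", "A_SPECIFIC", "SIMILAR"))
  # hand-checked extremes for the A-specific case (pseudocount 0.1)
  expect_equal(cls$min_fold[2], 50.1 / 6.1, tolerance = 1e-12)
  expect_equal(cls$max_fold[2], 60.1 / 5.1, tolerance = 1e-12)
  # the borderline gene: 20.1/10.1 < 2, strict > not met
  expect_lt(cls$min_fold[3], 2)
  # antisymmetry under cell-line swap
  swapped <- classify_expression(expr, c("sim", "aspec", "border"),
                                 c("B", "A"), c(240, 320))
  expect_equal(swapped$class, c("SIMILAR", "B_SPECIFIC", "SIMILAR"))
  expect_error(classify_expression(expr, "sim", c("A", "C"), c(320, 240)),
               "replicates")
})

test_that("expression summary conserves counts and handles empty labels", {
  cls <- data.frame(
    se_label = c("shared", "shared", "A_specific"),
    gene_id = c("g1", "g2", "g3"),
    class = c("SIMILAR", "SIMILAR", "A_SPECIFIC"))
  s <- expression_summary(cls)
  sh <- s[s$se_label == "shared", ]
  expect_equal(sh$n_genes, 2)
  expect_equal(sh$pct_similar, 100)
  expect_equal(sh$n_similar + sh$n_a_specific + sh$n_b_specific, sh$n_genes)
  # empty label set -> zero row without division errors
  s0 <- expression_summary(cls[0, ])
  expect_equal(nrow(s0), 0)
})
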