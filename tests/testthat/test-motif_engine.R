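test_that("PFM reading regularises and validates", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">TEST test",
               "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  p <- read_pfm(f)
  expect_equal(p$id, "TEST")
  expect_equal(pwm_consensus(p), "AC")
  expect_true(all(p$mat > 0))              # no zeros after pseudocount
  expect_equal(rowSums(p$mat), c(1, 1))
  # probability input is preserved up to the pseudocount
  writeLines(c("A [ 0.7 ]", "C [ 0.1 ]", "G [ 0.1 ]", "T [ 0.1 ]"), f)
  p2 <- read_pfm(f, id = "P")
  expect_equal(unname(p2$mat[1, "A"]), 0.7, tolerance = 0.01)
  # wrong row count
  writeLines(c("A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(read_pfm(f), "4 matrix rows")
  # unequal rows
  writeLines(c("A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f)
  expect_error(read_pfm(f), "unequal")
  # pfm files round-trip through write_pfm (up to re-regularisation)
  f2 <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(p, f2)
  expect_equal(read_pfm(f2)$mat, p$mat, tolerance = 0.01)
})

test_that("scan scores match hand-computed log-odds and oracle", {
  # uniform PWM scores 0 everywhere
  uni <- pwm("uni", matrix(0.25, nrow = 3, ncol = 4), pseudocount = 0)
  sc <- scan_pwm("ACGTAC", uni)
  expect_true(all(abs(sc$score) < 1e-12))
  # rows (0.85, 0.05 x3) twice on "AA": 2*log2(0.85/0.25)
  m <- matrix(rep(c(0.85, 0.05, 0.05, 0.05), 2), nrow = 2, byrow = TRUE)
  aa <- pwm("aa", m, pseudocount = 0)
  sc2 <- scan_pwm("AA", aa)
  plus <- sc2$score[sc2$strand == "+"]
  expect_equal(plus, 2 * log2(0.85 / 0.25), tolerance = 1e-9)
  # "TT" on the minus strand scores the same (reverse complement symmetry)
  sc3 <- scan_pwm("TT", aa)
  expect_equal(sc3$score[sc3$strand == "-"], 2 * log2(0.85 / 0.25),
               tolerance = 1e-9)
  # windows containing N are skipped
  scN <- scan_pwm("ANA", pwm("d", matrix(0.25, 2, 4), pseudocount = 0))
  expect_equal(nrow(scN), 0)
  # random cases against the naive oracle
  set.seed(21)
  for (i in 1:40) {
    L <- sample(2:12, 1)
    n <- sample(L:60, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    mat <- matrix(rexp(L * 4) + 0.01, nrow = L)
    mat <- mat / rowSums(mat)
    p <- pwm(paste0("r", i), mat, pseudocount = 0)
    got <- scan_pwm(seq, p)
    want <- oracle_scan(seq, p$mat)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      gp <- got[got$strand == "+", ]
      gm <- got[got$strand == "-", ]
      expect_equal(gp$offset, want$offset)
      expect_equal(gp$score, want$plus, tolerance = 1e-9)
      expect_equal(gm$score, want$minus, tolerance = 1e-9)
    }
  }
})

test_that("reverse-complementing the sequence preserves the score multiset", {
  set.seed(22)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
    mat <- matrix(rexp(5 * 4) + 0.01, nrow = 5); mat <- mat / rowSums(mat)
    p <- pwm("r", mat, pseudocount = 0)
    s1 <- sort(scan_pwm(seq, p)$score)
    s2 <- sort(scan_pwm(revcomp(seq), p)$score)
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("top motif score recovers embedded consensi and handles edge cases", {
  p <- consensus_pwm("M", "TGTTTAC")
  seq <- strrep("C", 400)
  seq <- embed_motif(seq, p, 200, "+")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  expect_equal(top_motif_score(genome, "chr1", 203, p, 100),
               pwm_max_score(p), tolerance = 1e-9)
  # minus-strand embedding scores identically
  seq2 <- embed_motif(strrep("C", 400), p, 200, "-")
  genome2 <- Biostrings::DNAStringSet(c(chr1 = seq2))
  expect_equal(top_motif_score(genome2, "chr1", 203, p, 100),
               pwm_max_score(p), tolerance = 1e-9)
  # all-N window -> sentinel
  genomeN <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 300)))
  expect_identical(top_motif_score(genomeN, "chr1", 150, p, 50), -Inf)
  # max over both strands >= max over plus alone
  sc <- scan_pwm(substr(seq, 104, 303), p)
  expect_gte(max(sc$score), max(sc$score[sc$strand == "+"]))
})

test_that("embed_motif writes the consensus and errors out of range", {
  p <- consensus_pwm("AA", "AA", strength = 0.9)
  expect_equal(embed_motif("CCCC", p, 0, "+"), "AACC")
  expect_equal(embed_motif("CCCC", p, 0, "-"), "TTCC")
  expect_equal(embed_motif("CCCC", p, 2, "+"), "CCAA")
  expect_error(embed_motif("CCCC", p, 3, "+"), "fit")
})

test_that("motif distribution bins hits by centre within the frame", {
  p <- list(M = consensus_pwm("M", strrep("A", 10)))
  # hit centred at the summit: offset 750 - 5 -> centre 750 -> bin 25
  hits <- data.frame(region = 1L, pwm = "M", offset = 745L, strand = "+",
                     score = 10)
  arr <- motif_distribution(hits, 1, p, frame = 1500, window = 30)
  expect_equal(dim(arr), c(1, 50, 1))
  expect_equal(unname(arr[1, 26, 1]), 1L)  # bin 25, 0-based
  expect_equal(sum(arr), 1L)
  # centre at summit + 40 -> floor(790/30) = bin 26
  hits2 <- data.frame(region = 1L, pwm = "M", offset = 785L, strand = "+",
                      score = 10)
  arr2 <- motif_distribution(hits2, 1, p, frame = 1500, window = 30)
  expect_equal(unname(arr2[1, 27, 1]), 1L)
  # no hits -> all zeros
  arr0 <- motif_distribution(hits[0, ], 2, p, 1500, 30)
  expect_equal(sum(arr0), 0L)
  # hits outside the frame are dropped
  hits3 <- data.frame(region = 1L, pwm = "M", offset = 1496L, strand = "+",
                      score = 10)
  expect_equal(sum(motif_distribution(hits3, 1, p, 1500, 30)), 0L)
})

test_that("presence patterns label and order sub-clusters deterministically", {
  pres <- rbind(c(TRUE, FALSE), c(FALSE, FALSE), c(TRUE, FALSE))
  colnames(pres) <- c("ERE", "TEAD")
  cl <- cluster_by_motif_presence(pres, c("ERE", "TEAD"))
  expect_equal(cl$label, c("10", "00", "10"))
  expect_equal(cl$label[cl$order], sort(cl$label, decreasing = TRUE))
  expect_error(cluster_by_motif_presence(pres, c("ERE", "XX")), "unknown")
})

test_that("enrichment p-values match closed-form binomial tails", {
  # target fraction = background fraction = 0.5, n = 10 -> tail from k = 5
  e1 <- enrichment_test(c(rep(1, 5), rep(-1, 5)),
                        c(rep(1, 50), rep(-1, 50)), 0)
  expect_equal(e1$p_value, sum(dbinom(5:10, 10, 0.5)), tolerance = 1e-12)
  # 8/10 targets at background rate 0.2
  e2 <- enrichment_test(c(rep(1, 8), rep(-1, 2)),
                        c(rep(1, 20), rep(-1, 80)), 0)
  expect_equal(e2$p_value, sum(dbinom(8:10, 10, 0.2)), tolerance = 1e-12)
  expect_equal(e2$p_value, 7.79e-5, tolerance = 1e-3)
  # zero target hits -> p = 1
  e3 <- enrichment_test(rep(-1, 5), rep(1, 5), 0)
  expect_equal(e3$p_value, 1)
  # zero background rate replaced by 1/(n_bg + 1)
  e4 <- enrichment_test(rep(1, 4), rep(-1, 9), 0)
  expect_equal(e4$p_value, stats::pbinom(3, 4, 0.1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(enrichment_test(numeric(0), rep(1, 5), 0), "target")
})

test_that("score threshold heuristic finds the last markedly high mode", {
  set.seed(31)
  scores <- c(rnorm(300, 2, 0.4), rnorm(60, 10, 0.2))
  thr <- select_score_threshold(scores, bin_width = 0.5)
  expect_equal(thr$provenance, "heuristic")
  expect_gte(thr$threshold, 9)
  expect_lte(thr$threshold, 10)
  # unimodal: threshold at the single mode's left edge
  uni <- rnorm(200, 5, 0.3)
  thr2 <- select_score_threshold(uni, bin_width = 0.5)
  expect_gte(thr2$threshold, 4)
  expect_lte(thr2$threshold, 5.5)
  # manual override wins regardless of data
  thr3 <- select_score_threshold(scores, manual = 8)
  expect_equal(thr3$threshold, 8)
  expect_equal(thr3$provenance, "manual")
  expect_error(select_score_threshold(rnorm(10)), "20")
})
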