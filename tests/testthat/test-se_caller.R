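# independent brute-force oracle for the slope-1 cutoff: scale, enumerate
# every index, take the minimiser of y - x (last on ties), flag the rest
oracle_cutoff <- function(dens) {
  n <- length(dens)
  ord <- order(dens)
  y <- dens[ord] / max(dens)
  x <- (seq_len(n) - 1) / (n - 1)
  d <- y - x
  max(which(d <= min(d) + 1e-12))
}

test_that("stitching merges below the gap and splits at it", {
  pk <- mk_peaks("chr1", c(1000, 13000, 26000), c(1200, 13200, 26200))
  cand <- stitch_peaks(pk, 12500)
  expect_length(cand, 2)
  # gaps: 11800 (< 12500, merged) and 12800 (>= 12500, split)
  expect_equal(GenomicRanges::start(cand) - 1L, c(1000L, 26000L))
  expect_equal(GenomicRanges::end(cand), c(13200L, 26200L))
  expect_equal(as.list(cand$constituents), list(c(1L, 2L), 3L))
  # single peak -> itself
  one <- stitch_peaks(pk[1], 12500)
  expect_equal(GenomicRanges::ranges(one), GenomicRanges::ranges(pk[1]))
  # idempotence: stitching the stitched regions changes nothing
  cand2 <- stitch_peaks(cand, 12500)
  expect_equal(GenomicRanges::ranges(cand2), GenomicRanges::ranges(cand))
  # chromosomes never merge
  two <- mk_peaks(c("chr1", "chr2"), c(0, 0), c(100, 100))
  expect_length(stitch_peaks(two, 12500), 2)
})

test_that("ranking sorts ascending with deterministic ties and scaled axes", {
  pk <- mk_peaks("chr1", seq(0, 80000, by = 20000),
                 seq(0, 80000, by = 20000) + 100)
  cand <- stitch_peaks(pk, 1000)
  counts <- c(4, 2, 100, 1, 3)
  tr <- mk_track("chr1", GenomicRanges::start(cand) - 1L,
                 GenomicRanges::end(cand), counts, 1e6)
  curve <- rank_candidates(cand, tr)
  # density = reads / width(100 bp) / (1e6/1e6) -> counts/100, ascending
  expect_equal(curve$density, sort(counts) / 100)
  expect_equal(curve$x, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(curve$y[5], 1)
  # equal densities tie-break by start coordinate
  tr2 <- mk_track("chr1", GenomicRanges::start(cand) - 1L,
                  GenomicRanges::end(cand), rep(5, 5), 1e6)
  curve2 <- rank_candidates(cand, tr2)
  expect_equal(GenomicRanges::start(curve2$candidates),
               sort(GenomicRanges::start(cand)))
  expect_error(rank_candidates(cand, mk_track("chr1", 0, 10, 0, 1e6)),
               "no signal")
  expect_error(rank_candidates(cand[1], tr), "at least 2")
})

test_that("slope-1 cutoff reproduces hand-evaluated examples", {
  mk_curve <- function(dens) {
    n <- length(dens)
    pk <- mk_peaks("chr1", seq_len(n) * 20000, seq_len(n) * 20000 + 100)
    cand <- stitch_peaks(pk, 1000)
    tr <- mk_track("chr1", GenomicRanges::start(cand) - 1L,
                   GenomicRanges::end(cand), dens, 1e6)
    rank_candidates(cand, tr)
  }
  # densities (1,2,3,4,100): argmin(y-x) at the 4 -> one SE (the 100)
  call <- call_superenhancers(mk_curve(c(1, 2, 3, 4, 100)))
  expect_equal(call$cutoff_index, 4)
  expect_equal(sum(call$candidates$is_super), 1)
  expect_equal(max(call$candidates$tag_density[call$candidates$is_super]),
               max(call$candidates$tag_density))
  # all equal: minimum of y-x at the last index -> zero SEs
  call_eq <- call_superenhancers(mk_curve(rep(3, 6)))
  expect_equal(sum(call_eq$candidates$is_super), 0)
  # densities (1,1,1,2,2,3,10,50): cutoff at the 10 -> one SE (the 50)
  call3 <- call_superenhancers(mk_curve(c(1, 1, 1, 2, 2, 3, 10, 50)))
  expect_equal(call3$cutoff_index, 7)
  expect_equal(sum(call3$candidates$is_super), 1)
})

test_that("cutoff equals the brute-force oracle on random curves", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(3:20, 1)
    dens <- round(rexp(n, 1 / 50)) + 1
    pk <- mk_peaks("chr1", seq_len(n) * 20000, seq_len(n) * 20000 + 100)
    cand <- stitch_peaks(pk, 1000)
    tr <- mk_track("chr1", GenomicRanges::start(cand) - 1L,
                   GenomicRanges::end(cand), dens, 1e6)
    call <- call_superenhancers(rank_candidates(cand, tr))
    expect_equal(call$cutoff_index, oracle_cutoff(dens))
  }
})

test_that("the SE set is invariant under positive scaling of densities", {
  set.seed(12)
  n <- 15
  dens <- round(rexp(n, 1 / 50)) + 1
  pk <- mk_peaks("chr1", seq_len(n) * 20000, seq_len(n) * 20000 + 100)
  cand <- stitch_peaks(pk, 1000)
  base <- NULL
  for (k in c(1, 2, 10, 0.5)) {
    tr <- mk_track("chr1", GenomicRanges::start(cand) - 1L,
                   GenomicRanges::end(cand), dens * k, 1e6)
    call <- call_superenhancers(rank_candidates(cand, tr))
    flags <- call$candidates$is_super[order(call$candidates$rank)]
    if (is.null(base)) base <- flags else expect_equal(flags, base)
  }
})
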