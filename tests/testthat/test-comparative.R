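test_that("constituent classification follows the overlap rule", {
  a <- mk_peaks("chr1", c(100, 1000), c(300, 1200), summit = c(200, 1100),
                score = c(10, 5))
  b <- mk_peaks("chr1", c(250, 5000), c(400, 5200), summit = c(300, 5100),
                score = c(3, 8))
  cl <- classify_constituents(a, b)
  expect_equal(sort(cl$label), c("A_SPECIFIC", "B_SPECIFIC", "SHARED"))
  sh <- cl[cl$label == "SHARED"]
  # merged region is the hull, summit comes from the stronger member
  expect_equal(GenomicRanges::start(sh) - 1L, 100)
  expect_equal(GenomicRanges::end(sh), 400)
  expect_equal(sh$summit, 200L)
  # half-open boundary: touching peaks do not merge
  b2 <- mk_peaks("chr1", 300, 500)
  cl2 <- classify_constituents(a[1], b2)
  expect_equal(sort(cl2$label), c("A_SPECIFIC", "B_SPECIFIC"))
})

test_that("swapping the cell lines swaps the specific labels exactly", {
  set.seed(41)
  starts_a <- sort(sample(seq(0, 1e5, by = 500), 30))
  starts_b <- sort(sample(seq(0, 1e5, by = 700), 25))
  a <- mk_peaks("chr1", starts_a, starts_a + 300, score = rpois(30, 20))
  b <- mk_peaks("chr1", starts_b, starts_b + 300, score = rpois(25, 20))
  ab <- classify_constituents(a, b)
  ba <- classify_constituents(b, a)
  expect_equal(sum(ab$label == "A_SPECIFIC"), sum(ba$label == "B_SPECIFIC"))
  expect_equal(sum(ab$label == "B_SPECIFIC"), sum(ba$label == "A_SPECIFIC"))
  expect_equal(sum(ab$label == "SHARED"), sum(ba$label == "SHARED"))
  # label counts invariant under input permutation
  perm <- sample(length(a))
  ab2 <- classify_constituents(a[perm], b)
  expect_equal(table(ab$label), table(ab2$label))
})

test_that("SE overlap reports pairs and merges chains into hulls", {
  a <- genomic_interval("chr1", c(0, 50000), c(10000, 60000))
  b <- genomic_interval("chr1", c(9000, 30000), c(20000, 40000))
  ov <- overlap_se_regions(a, b)
  expect_equal(nrow(ov$pairs), 1)
  expect_length(ov$hulls, 1)
  expect_equal(GenomicRanges::start(ov$hulls) - 1L, 0)
  expect_equal(GenomicRanges::end(ov$hulls), 20000)
  # identical lists -> every region pairs; disjoint lists -> empty
  same <- overlap_se_regions(a, a)
  expect_equal(nrow(same$pairs), 2)
  none <- overlap_se_regions(a, genomic_interval("chr2", 0, 100))
  expect_equal(nrow(none$pairs), 0)
  expect_length(none$hulls, 0)
})

test_that("hull constituent breakdown counts summits half-open", {
  hulls <- genomic_interval("chr1", 0, 10000)
  const <- mk_peaks("chr1", c(100, 2000, 4000, 9900, 20000),
                    c(500, 2400, 4400, 10300, 20400),
                    summit = c(300, 2200, 4200, 10000, 20200))
  const$label <- c("A_SPECIFIC", "A_SPECIFIC", "SHARED", "A_SPECIFIC",
                   "B_SPECIFIC")
  bd <- shared_se_constituent_breakdown(hulls, const)
  # summit 10000 sits exactly at the exclusive hull end -> not counted
  expect_equal(unname(bd$totals), c(2, 1, 0))
  expect_equal(sum(bd$per_hull[, c("A_SPECIFIC", "SHARED", "B_SPECIFIC")]),
               sum(bd$totals))
})

test_that("density matrix columns mirror their tracks", {
  const <- mk_peaks("chr1", c(100, 5000), c(300, 5200))
  t1 <- mk_track("chr1", c(150, 5050), c(250, 5150), c(10, 40), 1e6)
  t0 <- mk_track("chr1", 0, 50, 0, 1e6)
  dm <- build_density_matrix(const, list(x = t1, y = t1, zero = t0))
  expect_equal(dm[, "x"], dm[, "y"])          # duplicated track
  expect_equal(unname(dm[, "zero"]), c(0, 0)) # all-zero track
  gm <- density_group_means(dm, c("g1", "g1"))
  expect_equal(unname(gm["g1", ]), unname(colMeans(dm)))
  expect_error(build_density_matrix(const, list(x = t1, y = NULL)),
               "missing coverage track")
})

test_that("correlation matrix is symmetric with sentinel for flat columns", {
  set.seed(43)
  base <- rexp(20, 1 / 50)
  m <- cbind(a = base, b = base * 2, c = rev(base), flat = rep(1, 20))
  cm <- correlation_matrix(m)
  # identical up to scale; the log2(+0.1) transform is only near-affine
  expect_equal(cm["a", "b"], 1, tolerance = 1e-3)
  expect_equal(correlation_matrix(m, scale = "raw")["a", "b"], 1)
  expect_lt(cm["a", "c"], 0.5)
  expect_equal(cm, t(cm))
  expect_true(is.na(cm["a", "flat"]))
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(m)))
  expect_error(correlation_matrix(m[1:2, ]), "3 rows")
})

test_that("co-binding fractions partition the constituents", {
  const <- mk_peaks("chr1", c(0, 10000, 20000), c(400, 10400, 20400))
  tf1 <- genomic_interval("chr1", c(100, 10100), c(300, 10300))
  tf2 <- genomic_interval("chr1", 150, 250)
  r <- count_cobound(const, list(tf1 = tf1, tf2 = tf2), halfwidth = 100,
                     min_tfs = 2)
  expect_equal(r$counts, c(2, 1, 0))
  expect_equal(r$fraction_cobound, 1 / 3)
  expect_equal(r$fraction_low, 2 / 3)
  expect_equal(r$fraction_cobound + r$fraction_low, 1)
})

test_that("motif composition assigns one category and sums to 100", {
  pres <- rbind(c(TRUE, FALSE, FALSE),   # ERE only
                c(TRUE, TRUE, FALSE),    # multiple
                c(FALSE, FALSE, FALSE),  # none
                c(FALSE, TRUE, FALSE))   # TEAD only
  colnames(pres) <- c("ERE", "TEAD", "TCF")
  labels <- c("SHARED", "SHARED", "SHARED", "B_SPECIFIC")
  comp <- motif_composition(pres, labels)
  expect_equal(comp$category, c("ERE", "multiple", "none", "TEAD"))
  expect_equal(comp$combinations$combination, "ERE+TEAD")
  for (lb in unique(labels)) {
    expect_equal(sum(comp$table$percent[comp$table$label == lb]), 100,
                 tolerance = 0.1)
  }
  # swapping labels transposes the panels
  comp2 <- motif_composition(pres, c("B_SPECIFIC", "B_SPECIFIC",
                                     "B_SPECIFIC", "SHARED"))
  t1 <- comp$table[comp$table$label == "SHARED", "count"]
  t2 <- comp2$table[comp2$table$label == "B_SPECIFIC", "count"]
  expect_equal(t1, t2)
})

test_that("cluster abundance ratios reproduce simple arithmetic", {
  r <- cluster_abundance_ratios(20, 10, 5)
  expect_equal(unname(r), c(2, 0.5))
  expect_error(cluster_abundance_ratios(1, 0, 1), "positive")
})
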