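test_that("point probability: boundary tables and hand values", {
  expect_equal(roi_point_probability(2, 0, 0, 0), 1)
  expect_equal(roi_point_probability(1, 0, 0, 1), 0.5)
  expect_equal(roi_tail_probability(1, 0, 0, 1), 0.5)
  expect_error(roi_point_probability(-1, 0, 0, 1), "non-negative")
  expect_error(roi_tail_probability(0, 0, 0, 0), "at least one")
})

test_that("point and tail probabilities match brute-force enumeration", {
  # exhaustive over all tables with n <= 8 (the acceptance suite goes to 12)
  for (n in 1:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      oracle <- enumerate_table_probs(a, b, c, d)
      expect_equal(roi_point_probability(a, b, c, d), oracle$point,
                   tolerance = 1e-12,
                   label = sprintf("point(%d,%d,%d,%d)", a, b, c, d))
      expect_equal(roi_tail_probability(a, b, c, d), oracle$tail,
                   tolerance = 1e-12,
                   label = sprintf("tail(%d,%d,%d,%d)", a, b, c, d))
    }
  }
})

test_that("point probabilities over fixed margins sum to one", {
  margins <- list(c(5, 4), c(8, 3), c(10, 10), c(40, 12))
  for (mg in margins) {
    row1 <- mg[1]; col1 <- mg[2]; n <- row1 + 20
    a_vals <- max(0, col1 - (n - row1)):min(row1, col1)
    total <- sum(vapply(a_vals, function(a)
      roi_point_probability(a, row1 - a, col1 - a, n - row1 - col1 + a),
      numeric(1)))
    expect_lt(abs(total - 1), 1e-9)
  }
})

test_that("tail probability dominates the point value and is monotone in a", {
  set.seed(5)
  for (i in 1:50) {
    cts <- as.integer(rmultinom(1, 30, c(0.1, 0.2, 0.3, 0.4)))
    pp <- roi_point_probability(cts[1], cts[2], cts[3], cts[4])
    pt_ <- roi_tail_probability(cts[1], cts[2], cts[3], cts[4])
    expect_gte(pt_ + 1e-12, pp)
    if (cts[2] > 0 && cts[3] > 0) {
      # shift one window from outside-significant to inside, margins fixed
      pt_up <- roi_tail_probability(cts[1] + 1, cts[2] - 1,
                                    cts[3] - 1, cts[4] + 1)
      expect_lte(pt_up, pt_ + 1e-12)
    }
  }
})

test_that("windows map to ROIs by overlap with nearest-TSS tie-breaking", {
  rois <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 451), end = c(500, 900)),
    strand = c("+", "+"), gene_id = c("gA", "gB"))
  S4Vectors::mcols(rois)$tss <- c(1, 900)
  win <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(101, 460, 461, 101), width = 100))
  got <- assign_windows(win, rois)
  expect_equal(got[1], "gA")              # unique overlap
  expect_equal(got[2], "gB")              # overlaps both; midpoint nearer gB's TSS
  expect_equal(got[3], "gB")
  expect_equal(got[4], NA_character_)     # chromosome without ROIs
})

test_that("fully mismatched chromosome names raise a hard error", {
  rois <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 500),
                                 gene_id = "gA")
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_error(assign_windows(win, rois), "chromosome names")
})

test_that("a fully planted ROI tops the ranking and is called a DMROI", {
  cfg <- simulation_config(n_regions = 400, n_true_dmrs = 8,
                           dmr_placement = "clustered", seed = 23)
  co <- simulate_array_cohort(cfg)
  des <- make_design24()
  dmr <- call_dmrs(co$methylation, des)
  roi <- call_dmrois(dmr, cohort_rois(co), co$regions, co$methylation, des)
  planted_gene <- unique(
    S4Vectors::mcols(co$regions)$roi[co$true_dmr_mask])
  expect_length(planted_gene, 1)
  expect_equal(roi$gene_id[1], planted_gene)
  expect_true(roi$is_dmroi[1])
  expect_gte(roi$n_dmrs_in_roi[1], 1)
  # table margins close
  expect_equal(roi$n, roi$a + roi$b + roi$c + roi$d)
  expect_true(all(roi$p_tail >= roi$p_point - 1e-12))
})

test_that("significant windows without a composite DMR are not a DMROI", {
  cfg <- simulation_config(n_regions = 200, n_true_dmrs = 6,
                           dmr_placement = "clustered", seed = 29)
  co <- simulate_array_cohort(cfg)
  des <- make_design24()
  # impossible abs-diff bar: windows stay significant but no DMR is called
  dmr <- call_dmrs(co$methylation, des,
                   thresholds = dmr_thresholds(abs_diff = 0.95))
  expect_equal(sum(dmr$is_dmr), 0)
  roi <- call_dmrois(dmr, cohort_rois(co), co$regions, co$methylation, des)
  expect_true(any(roi$p_tail <= 0.01))   # enrichment alone would pass
  expect_false(any(roi$is_dmroi))
})

test_that("a null cohort yields (almost) no DMROI calls", {
  cfg <- simulation_config(n_regions = 400, n_true_dmrs = 0, seed = 31)
  co <- simulate_array_cohort(cfg)
  des <- make_design24()
  dmr <- call_dmrs(co$methylation, des)
  roi <- call_dmrois(dmr, cohort_rois(co), co$regions, co$methylation, des)
  expect_lte(mean(roi$is_dmroi), 0.01)
})

test_that("gene-set enrichment matches an independent tail-sum oracle", {
  # degenerate margins: total overlap forced, p = 1
  genes <- sprintf("g%03d", 1:10)
  res <- geneset_enrichment(genes, list(s = genes), genes)
  expect_equal(res$p_hyper, 1)
  # no overlap: upper tail including 0 is 1
  res0 <- geneset_enrichment("g001", list(s = c("g005", "g006")),
                             sprintf("g%03d", 1:100))
  expect_equal(res0$k_hit, 0)
  expect_equal(res0$p_hyper, 1)
  # array-background scale: independent tail sum via dhyper
  bg <- sprintf("g%05d", 1:25000)
  set_genes <- bg[1:71]
  hits <- c(bg[1:4], bg[100:136])        # 41 draws, 4 in the set
  res2 <- geneset_enrichment(hits, list(dev = set_genes), bg)
  oracle <- sum(stats::dhyper(4:41, 71, 25000 - 71, 41))
  expect_equal(res2$p_hyper, oracle, tolerance = 1e-10)
  expect_error(geneset_enrichment("x", list(s = "x"), character(0)),
               "background")
  expect_error(geneset_enrichment("zzz", list(s = "g001"), bg), "subset")
})
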