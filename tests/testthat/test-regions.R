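# Threshold computation, region calling, consensus, interval arithmetic.

test_that("compute_threshold uses linear interpolation between order statistics", {
  expect_equal(compute_threshold(1:1000, 0.999)$cutoff, 999.001)
  expect_equal(compute_threshold(rep(3.2, 50), 0.5)$cutoff, 3.2)
  expect_equal(compute_threshold(c(5, 1, 9, 2), 1)$cutoff, 9)
  # absolute mode for signed tracks
  expect_equal(compute_threshold(c(-10, 1, 2), 1, absolute = TRUE)$cutoff, 10)
  expect_error(compute_threshold(numeric(0)), "empty")
})

test_that("call_regions honours the minimum-site rule at the 9/10 boundary", {
  mk <- function(n_above) {
    data.frame(chrom = "chr1",
               pos = seq(1e6, by = 1e4, length.out = n_above + 4),
               v = c(0, 0, rep(5, n_above), 0, 0))
  }
  st9 <- mk(9); st10 <- mk(10)
  expect_equal(nrow(call_regions(st9, "v", 1, min_sites = 10)), 0)
  r <- call_regions(st10, "v", 1, min_sites = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_sites_above, 10)
  expect_equal(c(r$start, r$end), c(st10$pos[3], st10$pos[12]))
})

test_that("merge_gap joins runs split by short sub-threshold territory", {
  pos <- c(seq(1e6, by = 1000, length.out = 10),
           2e6,                                  # below-threshold spacer
           seq(3e6, by = 1000, length.out = 10))
  v <- c(rep(5, 10), 0, rep(5, 10))
  st <- data.frame(chrom = "chr1", pos = pos, v = v)
  two <- call_regions(st, "v", 1, min_sites = 10, merge_gap = 0)
  expect_equal(nrow(two), 2)
  one <- call_regions(st, "v", 1, min_sites = 10, merge_gap = 3e6)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_sites_above, 20)
})

test_that("call_regions equals the brute-force run-length oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(200:2000, 1)
    st <- data.frame(chrom = "chr1", pos = sort(sample.int(5e7, n)),
                     v = rnorm(n))
    cutoff <- quantile(st$v, runif(1, 0.5, 0.95))
    ms <- sample(c(1, 3, 10), 1)
    gap <- sample(c(0, 1e5, 1e6), 1)
    got <- call_regions(st, "v", cutoff, min_sites = ms, merge_gap = gap)
    want <- regions_oracle(st$pos, st$v, cutoff, ms, gap)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$start), ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_sites_above, want$n_sites_above)
    }
  }
})

test_that("raising the quantile never increases the number of regions", {
  set.seed(33)
  st <- data.frame(chrom = "chr1", pos = sort(sample.int(1e7, 800)),
                   v = rnorm(800)^2)
  counts <- vapply(c(0.8, 0.9, 0.95, 0.99, 0.999), function(q) {
    th <- compute_threshold(st$v, q)
    nrow(call_regions(st, "v", th, min_sites = 3))
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus annotates support without inventing or losing regions", {
  a <- data.frame(chrom = "chr1", start = c(100, 5000), end = c(400, 6000))
  b <- data.frame(chrom = "chr1", start = 200, end = 300)    # nested in a1
  c_ <- data.frame(chrom = "chr2", start = 100, end = 400)   # other chrom
  cons <- consensus_regions(list(A = a, B = b, C = c_))
  expect_equal(nrow(cons), 4)  # permutation of the union
  nested <- cons[cons$method == "B", ]
  expect_equal(nested$n_methods, 2)
  # reciprocal overlap of nested pair: |B| / |A1|
  expect_equal(nested$reciprocal_overlap, 101 / 301, tolerance = 1e-12)
  expect_equal(cons[cons$method == "C", ]$n_methods, 1)
  # disjoint lists stay single-method
  cons2 <- consensus_regions(list(
    A = data.frame(chrom = "chr1", start = 1, end = 10),
    B = data.frame(chrom = "chr1", start = 100, end = 110)))
  expect_true(all(cons2$n_methods == 1))
  # ordering: multi-method first
  expect_true(all(diff(cons$n_methods) <= 0))
})

test_that("interval_span is exact, translation-invariant and additive", {
  expect_equal(interval_span(1, 10, "bp"), 10)
  expect_equal(interval_span(101, 110, "bp"), 10)
  # additivity over adjacent closed intervals: [a,b] + [b+1,c] = [a,c]
  expect_equal(interval_span(1, 500, "bp") + interval_span(501, 900, "bp"),
               interval_span(1, 900, "bp"))
  expect_equal(interval_span(1, 64656, "kb"), 64.66)  # half-up at 3rd decimal
  expect_error(interval_span(10, 1), "start")
})

test_that("summarize_region counts variants and overlapping genes", {
  rows <- list(
    toy_variant_row(pos = 100L), toy_variant_row(pos = 200L),
    toy_variant_row(pos = 300L, impact = "HIGH"),
    toy_variant_row(pos = 400L), toy_variant_row(pos = 500L),
    toy_variant_row(pos = 250L, variant_class = "InDel", impact = "MODERATE"),
    toy_variant_row(pos = 450L, variant_class = "InDel"),
    toy_variant_row(pos = 9000L),                       # outside
    toy_variant_row(chrom = "chr2", pos = 300L))        # other chromosome
  tab <- toy_variant_table(rows)
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(90, 600, 100), end = c(120, 800, 500),
                      gene_id = c("g1", "g2", "g3"))
  s <- summarize_region(list(chrom = "chr1", start = 100, end = 500),
                        tab, genes)
  expect_equal(s$total_snps, 5)
  expect_equal(s$total_indels, 2)
  expect_equal(s$effective_snps, 1)
  expect_equal(s$effective_indels, 1)
  expect_equal(s$annotated_genes, 1)
  # closed-interval convention: gene starting exactly at region end counts
  genes2 <- data.frame(chrom = "chr1", start = 500, end = 900, gene_id = "g")
  expect_equal(summarize_region(list(chrom = "chr1", start = 100, end = 500),
                                tab, genes2)$annotated_genes, 1)
  # empty slice
  s0 <- summarize_region(list(chrom = "chr9", start = 1, end = 2), tab, genes)
  expect_equal(unlist(s0), c(total_snps = 0, total_indels = 0,
                             effective_snps = 0, effective_indels = 0,
                             annotated_genes = 0))
})
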