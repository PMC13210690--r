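# Filtering, polarization, and the variant I/O round trip.

test_that("apply_filters attributes removals to the first failing rule", {
  rows <- list(
    toy_variant_row(pos = 100L),                          # pass
    toy_variant_row(pos = 200L, qual = 10),               # fail qual
    toy_variant_row(pos = 300L, qual = 29.9),             # fail qual
    toy_variant_row(pos = 400L, qual = 5, mq = 10),       # qual first
    toy_variant_row(pos = 500L, pd = c(4L, 0L)),          # parent depth
    toy_variant_row(pos = 600L, pt = c(0L, 9L)),          # parent depth
    toy_variant_row(pos = 700L, pd = c(12L, 0L), pt = c(11L, 1L)),  # same hom
    toy_variant_row(pos = 800L),                          # pass
    toy_variant_row(pos = 900L),                          # pass
    toy_variant_row(pos = 1000L))                         # pass
  out <- apply_filters(toy_variant_table(rows))
  expect_equal(nrow(out), 4)
  rep <- attr(out, "removal_report")
  expect_equal(rep$qual, 3L)
  expect_equal(rep$parent_depth, 2L)
  expect_equal(rep$not_opposite, 1L)
  expect_equal(sum(unlist(rep)), 10 - nrow(out))
})

test_that("each filter rule triggers and thresholds of zero retain everything", {
  rows <- list(
    toy_variant_row(pos = 1L, biallelic = FALSE),
    toy_variant_row(pos = 2L, mq = 20),
    toy_variant_row(pos = 3L, bd = c(5L, 5L)),            # bulk depth 10 < 15
    toy_variant_row(pos = 4L, bt = c(7L, 7L)),
    toy_variant_row(pos = 5L, pd = c(NA_integer_, 0L)))   # missing
  out <- apply_filters(toy_variant_table(rows))
  rep <- attr(out, "removal_report")
  expect_equal(nrow(out), 0)
  expect_equal(unlist(rep[c("biallelic", "mq", "bulk_depth", "missing")]),
               c(biallelic = 1L, mq = 1L, bulk_depth = 2L, missing = 1L))
  # zeroed thresholds: identity on opposite-homozygote rows
  rows2 <- list(toy_variant_row(pos = 10L, qual = 1, mq = 1,
                                pd = c(2L, 0L), pt = c(0L, 2L),
                                bd = c(1L, 0L), bt = c(0L, 1L)))
  out2 <- apply_filters(toy_variant_table(rows2), qual_min = 0, mq_min = 0,
                        parent_depth_min = 0, bulk_depth_min = 0)
  expect_equal(nrow(out2), 1)
})

test_that("filtering is idempotent and retained rows satisfy all invariants", {
  cfg <- small_sim_config(seed = 2)
  tab <- sample_reads(select_bulks(simulate_f2(cfg)))
  once <- apply_filters(tab)
  twice <- apply_filters(once)
  strip <- function(x) { attr(x, "removal_report") <- NULL; as.data.frame(x) }
  expect_equal(strip(once), strip(twice))
  expect_equal(sum(unlist(attr(twice, "removal_report"))), 0)
  with(once, {
    expect_true(all(qual >= 30 & mq >= 30))
    expect_true(all(pd_ref + pd_alt >= 10 & pt_ref + pt_alt >= 10))
    expect_true(all(bd_ref + bd_alt >= 15 & bt_ref + bt_alt >= 15))
  })
  expect_true(!is.unsorted(once$pos[once$chrom == "chr1"]))
})

test_that("polarize records the tall-parent allele and drives antisymmetry", {
  rows <- list(
    toy_variant_row(pos = 100L, pd = c(12L, 0L), pt = c(0L, 14L)),  # tall=alt
    toy_variant_row(pos = 200L, pd = c(0L, 12L), pt = c(14L, 0L)))  # tall=ref
  tab <- polarize(apply_filters(toy_variant_table(rows),
                                bulk_depth_min = 0))
  expect_equal(tab$tall_allele, c("alt", "ref"))

  # swapping the parent roles negates the delta SNP-index site-wise
  cfg <- small_sim_config(seed = 4)
  tab2 <- apply_filters(sample_reads(select_bulks(simulate_f2(cfg))))
  swapped <- tab2
  swapped[, c("pd_ref", "pd_alt", "pt_ref", "pt_alt")] <-
    tab2[, c("pt_ref", "pt_alt", "pd_ref", "pd_alt")]
  d1 <- compute_bsa_stats(polarize(tab2))$delta
  d2 <- compute_bsa_stats(polarize(swapped))$delta
  expect_equal(d2, -d1, tolerance = 1e-12)
})

test_that("polarize rejects unfiltered ambiguous parents", {
  rows <- list(toy_variant_row(pd = c(6L, 6L)))
  expect_error(polarize(toy_variant_table(rows)), "ambiguous")
})

test_that("TSV and VCF round trips preserve the table", {
  cfg <- small_sim_config(seed = 6, n_sites = 60L)
  tab <- sample_reads(select_bulks(simulate_f2(cfg)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(tab, tsv)
  back <- read_variants(tsv, "tsv")
  expect_equal(as.data.frame(back), as.data.frame(tab))

  skip_if_not_installed("VariantAnnotation")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(tab, vcf)
  vback <- read_variants(vcf, "vcf")
  expect_equal(vback$pos, tab$pos)
  expect_equal(vback$ref, tab$ref)
  expect_equal(vback$alt, tab$alt)
  expect_equal(vback$qual, tab$qual, tolerance = 1e-6)
  expect_equal(vback$mq, tab$mq)
  for (cl in c("pd_ref", "pd_alt", "pt_ref", "pt_alt",
               "bd_ref", "bd_alt", "bt_ref", "bt_alt"))
    expect_equal(vback[[cl]], tab[[cl]], info = cl)
  # and the depths feed identical downstream statistics
  expect_equal(compute_bsa_stats(polarize(apply_filters(vback)))$delta,
               compute_bsa_stats(polarize(apply_filters(tab)))$delta)
})

test_that("multi-allelic records are flagged; empty files warn", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "PD", "PT", "BD", "BT"), collapse = "\t"),
    paste("chr1", 10, ".", "A", "G", 99, ".", "MQ=60", "GT:AD",
          "0/0:12,0", "1/1:0,14", "./.:9,8", "./.:7,11", sep = "\t"),
    paste("chr1", 20, ".", "C", "T,G", 99, ".", "MQ=60", "GT:AD",
          "0/0:10,0,1", "1/1:0,9,2", "./.:5,5,1", "./.:4,6,0", sep = "\t")),
    vcf)
  tab <- read_variants(vcf, "vcf")
  expect_equal(tab$biallelic, c(TRUE, FALSE))
  out <- apply_filters(tab, bulk_depth_min = 10)
  expect_equal(attr(out, "removal_report")$biallelic, 1L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(e <- read_variants(empty, "tsv"), "empty")
  expect_equal(nrow(e), 0)
})

test_that("unknown sample roles in a VCF are a hard error", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  cfg <- small_sim_config(seed = 8, n_sites = 10L)
  write_variant_vcf(sample_reads(select_bulks(simulate_f2(cfg))), vcf)
  expect_error(read_variants(vcf, "vcf",
                             roles = c(parent_dwarf = "NOPE",
                                       parent_tall = "PT",
                                       bulk_dwarf = "BD", bulk_tall = "BT")),
               "NOPE")
})
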