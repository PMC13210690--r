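# Haplotype grouping, Duncan's multiple range test, single-marker tests,
# frequency tables, and the 2^-ddCt contrast.

test_that("define_haplotypes partitions accessions into labelled groups", {
  panel <- make_panel_fixture(seed = 50)
  hg <- define_haplotypes(panel)
  expect_equal(nrow(hg$groups), 6)
  expect_setequal(hg$groups$n, c(39L, 6L, 8L, 21L, 21L, 53L))
  expect_equal(sum(hg$groups$n), 148)
  # partition: assignment covers every accession exactly once
  expect_equal(as.integer(table(hg$panel$haplotype)[hg$groups$haplotype]),
               hg$groups$n)
  # labels ordered by descending overall mean
  expect_true(all(diff(hg$groups$overall_mean) <= 0))
  expect_equal(hg$groups$haplotype, paste0("Hap", 1:6))

  # single haplotype and combinatorial bound
  one <- define_haplotypes(make_panel_fixture(
    seed = 51, group_sizes = 10L, group_means = 100))
  expect_equal(nrow(one$groups), 1)
  # incomplete allele strings are excluded with a message
  p <- make_panel_fixture(seed = 52)
  p$s1[3] <- NA
  expect_message(hg2 <- define_haplotypes(p), "excluded")
  expect_equal(nrow(hg2$panel), 147)
})

test_that("Duncan two-group case coincides with Fisher's LSD", {
  set.seed(60)
  for (rep in 1:12) {
    n <- sample(5:15, 1)
    shift <- runif(1, 0, 3)
    y <- c(rnorm(n), rnorm(n, shift))
    g <- rep(c("A", "B"), each = n)
    dres <- anova_duncan(y, g)
    distinct <- !grepl(dres$means$letters[1], dres$means$letters[2],
                       fixed = TRUE)
    # direct LSD on the pooled MS_error (p = 2 reduction)
    mse <- dres$anova$ms_error
    lsd <- qt(0.975, 2 * n - 2) * sqrt(mse * (2 / n))
    expect_equal(distinct, abs(mean(y[g == "A"]) - mean(y[g == "B"])) > lsd)
  }
})

test_that("Duncan letters: identical means share, separated groups differ", {
  set.seed(61)
  y <- rnorm(30, 100, 5)
  g <- rep(c("a", "b", "c"), each = 10)
  same <- anova_duncan(y - ave(y, g) + 100, g)  # identical group means
  expect_equal(unique(same$means$letters), "a")

  # power: two groups 6 sd apart, n = 6, distinct letters in >= 95% of reps
  hits <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    yy <- c(rnorm(6, 0, 1), rnorm(6, 6, 1))
    gg <- rep(c("lo", "hi"), each = 6)
    r <- anova_duncan(yy, gg)
    !grepl(r$means$letters[1], r$means$letters[2], fixed = TRUE)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Duncan letter display is transitively consistent", {
  # constructed case: ordered means, adjacent overlaps
  set.seed(62)
  y <- c(rnorm(8, 100), rnorm(8, 102), rnorm(8, 104), rnorm(8, 115))
  g <- rep(c("g1", "g2", "g3", "g4"), each = 8)
  r <- anova_duncan(y, g)
  m <- r$means
  share <- function(i, j) any(strsplit(m$letters[i], "")[[1]] %in%
                                strsplit(m$letters[j], "")[[1]])
  # if i and j share a letter, any group with mean between them must share
  # a letter with both
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (!share(i, j)) next
    for (k in seq_len(nrow(m))) {
      if (m$mean[k] <= m$mean[i] && m$mean[k] >= m$mean[j]) {
        expect_true(share(i, k) && share(k, j))
      }
    }
  }
  # groups of size 1 are excluded and reported
  y2 <- c(y, 50); g2 <- c(g, "solo")
  r2 <- anova_duncan(y2, g2)
  expect_equal(r2$excluded, "solo")
  expect_false("solo" %in% r2$means$group)
})

test_that("single-marker t-test: calibration, power, and degeneracy", {
  # type-I rate over 500 null replicates approximately alpha = 0.05
  rej <- vapply(1:500, function(i) {
    set.seed(2000 + i)
    panel <- data.frame(s1 = rep(c("C", "T"), each = 74),
                        height_y = rnorm(148, 180, 20))
    single_marker_test(panel, "s1", "height_y")$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)

  # power: +20 cm shift, sd 10, n = 30/group -> p < 0.001 in >= 95%
  hit <- vapply(1:60, function(i) {
    set.seed(3000 + i)
    panel <- data.frame(s1 = rep(c("C", "T"), each = 30),
                        height_y = c(rnorm(30, 160, 10), rnorm(30, 180, 10)))
    single_marker_test(panel, "s1", "height_y")$p_value < 0.001
  }, TRUE)
  expect_gte(mean(hit), 0.95)

  # monomorphic site and constant data
  mono <- data.frame(s1 = rep("C", 10), height_y = rnorm(10))
  expect_false(single_marker_test(mono, "s1", "height_y")$testable)
  const <- data.frame(s1 = rep(c("C", "T"), each = 5),
                      height_y = rep(7, 10))
  r <- single_marker_test(const, "s1", "height_y")
  expect_true(r$testable)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
})

test_that("frequency_breakdown rounds to one decimal summing to 100", {
  panel <- data.frame(
    haplotype = c(rep("Hap2", 6), rep("Hap6", 37), rep("Hap1", 24),
                  rep("Hap4", 7), rep("Hap5", 15), rep("Hap3", 3)),
    market_class = "confection")
  f <- frequency_breakdown(panel, "market_class")
  expect_equal(f$pct[f$haplotype == "Hap2"], 6.5)  # 6/92
  expect_equal(sum(f$pct), 100)
  # invariance to row order
  f2 <- frequency_breakdown(panel[sample(nrow(panel)), , drop = FALSE],
                            "market_class")
  expect_equal(f, f2)
  # single accession stratum
  one <- data.frame(haplotype = "HapX", market_class = "oilseed")
  expect_equal(frequency_breakdown(one, "market_class")$pct, 100)
})

test_that("ddct computes relative expression anchored at the reference group", {
  # three replicates with dCt {5,6,7} against a reference group mean of 6
  samples <- data.frame(
    group = rep(c("ref", "alt"), each = 3),
    bio_rep = rep(1:3, 2), tech_rep = 1L,
    ct_target = c(26, 27, 28, 25, 26, 27),
    ct_reference = c(21, 21, 21, 20, 20, 20))
  r <- ddct(samples, "ref")
  alt <- r$per_rep[r$per_rep$group == "alt", ]
  expect_equal(sort(alt$rel_expr), c(0.5, 1, 2))
  expect_equal(exp(mean(log(alt$rel_expr))), 1)  # geometric mean
  # the reference group's own mean dCt maps to exactly 1.0
  expect_equal(r$group_summary$fold_change[r$group_summary$group == "ref"], 1)

  # technical replicates are averaged before the contrast
  tech <- data.frame(group = "ref", bio_rep = 1L, tech_rep = 1:3,
                     ct_target = c(24, 25, 26), ct_reference = c(20, 20, 20))
  r2 <- ddct(rbind(tech, within(tech, {bio_rep <- 2L})), "ref")
  expect_equal(nrow(r2$per_rep), 2)
  expect_equal(unique(r2$per_rep$dct), 5)

  # missing reference Ct rows are excluded with a message
  bad <- samples; bad$ct_reference[1] <- NA
  expect_message(ddct(bad, "ref"), "excluded")
})
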