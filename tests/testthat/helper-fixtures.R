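# Shared fixture builders.  Everything is generated in code; no stored data.

# A small, fast simulation world for unit tests (not the default analysis
# world): 2 chromosomes, strong QTL, modest site count.
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_individuals = 200L, bulk_size = 20L,
               n_sites = 400L, n_chrom = 2L, chrom_length = 5e7,
               qtl_chrom = "chr1", qtl_position = 2.5e7)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# Hand-built unfiltered variant table: every row passes unless perturbed.
toy_variant_row <- function(chrom = "chr1", pos = 100L, qual = 100, mq = 60,
                            biallelic = TRUE,
                            pd = c(12L, 0L), pt = c(0L, 14L),
                            bd = c(10L, 10L), bt = c(8L, 12L),
                            variant_class = "SNP", impact = "MODIFIER") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G", qual = qual,
             mq = mq, variant_class = variant_class, impact = impact,
             biallelic = biallelic,
             pd_ref = pd[1], pd_alt = pd[2], pt_ref = pt[1], pt_alt = pt[2],
             bd_ref = bd[1], bd_alt = bd[2], bt_ref = bt[1], bt_alt = bt[2],
             stringsAsFactors = FALSE)
}

toy_variant_table <- function(rows) {
  tab <- do.call(rbind, rows)
  class(tab) <- c("bulk_variant_table", "data.frame")
  tab
}

# Independent oracle for the G statistic: twice the log-likelihood ratio of
# the product-binomial model (free per-bulk frequencies) against the pooled
# model.  Deliberately different algebra from the cell-count form.
g_oracle_binom <- function(dwarf_tall, dwarf_other, tall_tall, tall_other) {
  n1 <- dwarf_tall + dwarf_other
  n2 <- tall_tall + tall_other
  p1 <- dwarf_tall / n1
  p2 <- tall_tall / n2
  p0 <- (dwarf_tall + tall_tall) / (n1 + n2)
  ll <- function(k, n, p) {
    if (p <= 0 || p >= 1) {
      out <- 0
      if (k > 0) out <- out + k * log(p)
      if (n - k > 0) out <- out + (n - k) * log(1 - p)
      return(out)
    }
    k * log(p) + (n - k) * log(1 - p)
  }
  2 * (ll(dwarf_tall, n1, p1) + ll(tall_tall, n2, p2) -
         ll(dwarf_tall, n1, p0) - ll(tall_tall, n2, p0))
}

# Brute-force double-loop tricube smoother.
smooth_oracle <- function(pos, v, h) {
  vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    j <- which(d <= h)
    w <- (1 - (d[j] / h)^3)^3
    sum(w * v[j]) / sum(w)
  }, 1)
}

# Brute-force run-length region caller (no merging support beyond gap rule).
regions_oracle <- function(pos, v, cutoff, min_sites, merge_gap) {
  above <- which(!is.na(v) & v >= cutoff)
  if (!length(above)) return(NULL)
  # split above-indices into runs of consecutive sites, then merge by bp gap
  runs <- split(above, cumsum(c(1L, diff(above) != 1L)))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gap <- pos[r[1]] - pos[last[length(last)]] - 1
    if (gap <= merge_gap) merged[[length(merged)]] <- c(last, r)
    else merged[[length(merged) + 1L]] <- r
  }
  keep <- Filter(function(r) length(r) >= min_sites, merged)
  if (!length(keep)) return(NULL)
  do.call(rbind, lapply(keep, function(r)
    data.frame(start = pos[min(r)], end = pos[max(r)],
               n_sites_above = length(r))))
}
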