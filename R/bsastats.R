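# Per-site BSA statistics and tricube kernel smoothing.
#
# Three complementary statistics are computed from the polarized bulk
# depths at each site:
#   * delta SNP-index: difference in tall-allele read frequency between the
#     tall and dwarf bulks, in [-1, 1];
#   * G: the 2x2 allele-count log-likelihood-ratio statistic
#     G = 2 * sum n_i * ln(n_i / nhat_i), smoothed into G';
#   * ED: Euclidean distance between the bulk allele-frequency vectors,
#     sqrt(2) * |delta f| for a biallelic site, raised to the fourth power
#     before smoothing to sharpen peaks.
# Smoothing uses a tricube kernel over a fixed bp window evaluated at every
# variant site, per chromosome, truncated at chromosome ends.

#' Per-bulk SNP-index and their difference
#'
#' The SNP-index of a bulk is the fraction of its reads carrying the
#' tall-parent allele; `delta = index_tall - index_dwarf`.
#'
#' @param dwarf_tall,dwarf_other tall-allele and other-allele read counts in
#'   the dwarf bulk (vectorized).
#' @param tall_tall,tall_other the same for the tall bulk.
#' @return data frame with `index_dwarf`, `index_tall`, `delta`.
#' @export
snp_index <- function(dwarf_tall, dwarf_other, tall_tall, tall_other) {
  dd <- dwarf_tall + dwarf_other
  dt <- tall_tall + tall_other
  idx_d <- ifelse(dd > 0, dwarf_tall / dd, NA_real_)
  idx_t <- ifelse(dt > 0, tall_tall / dt, NA_real_)
  data.frame(index_dwarf = idx_d, index_tall = idx_t,
             delta = idx_t - idx_d)
}

#' G statistic of a 2x2 allele-count table
#'
#' `G = 2 * sum n * ln(n / nhat)` over the four cells (tall/other allele x
#' dwarf/tall bulk), with expected counts `nhat = row total * column total /
#' grand total` and the convention `0 * ln(0) = 0`.  Equivalent to twice
#' the log-likelihood ratio of independent versus pooled binomials.
#'
#' @param dwarf_tall,dwarf_other,tall_tall,tall_other cell counts
#'   (vectorized).
#' @return numeric vector of G values (`NA` where the grand total is 0).
#' @export
g_statistic <- function(dwarf_tall, dwarf_other, tall_tall, tall_other) {
  n11 <- dwarf_tall; n12 <- dwarf_other
  n21 <- tall_tall;  n22 <- tall_other
  total <- n11 + n12 + n21 + n22
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  term <- function(n, e) ifelse(n > 0, n * log(n / e), 0)
  g <- 2 * (term(n11, r1 * c1 / total) + term(n12, r1 * c2 / total) +
            term(n21, r2 * c1 / total) + term(n22, r2 * c2 / total))
  g[total == 0] <- NA_real_
  pmax(g, 0)  # clamp tiny negative rounding residue
}

#' Euclidean distance between bulk allele-frequency vectors
#'
#' `ED = sqrt((f_t - f_d)^2 + ((1 - f_t) - (1 - f_d))^2)`, which equals
#' `sqrt(2) * |f_t - f_d|` at a biallelic site; `ed4 = ED^4`.
#'
#' @param freq_dwarf,freq_tall tall-allele frequencies per bulk
#'   (vectorized).
#' @return data frame with `ed` and `ed4`.
#' @export
euclidean_distance <- function(freq_dwarf, freq_tall) {
  d <- freq_tall - freq_dwarf
  ed <- sqrt(d^2 + d^2)
  data.frame(ed = ed, ed4 = ed^4)
}

#' Tricube kernel smoothing along a chromosome
#'
#' Smoothed value at focal site i is `sum(w_j v_j) / sum(w_j)` over sites j
#' with `|pos_j - pos_i| <= h`, using tricube weights
#' `w_j = (1 - (|pos_j - pos_i| / h)^3)^3`.  A convex combination, so the
#' result always lies within the range of the contributing raw values.
#' Windows truncate at the ends of the position vector.
#'
#' @param pos sorted positions (one chromosome).
#' @param values numeric vector or matrix (one column per track) of raw
#'   values aligned with `pos`.
#' @param h kernel half-width in bp (`h > 0`).
#' @return object shaped like `values` with smoothed values.
#' @export
tricube_smooth <- function(pos, values, h) {
  stopifnot(h > 0, !is.unsorted(pos))
  vm <- as.matrix(values)
  n <- length(pos)
  if (n == 0L) return(values)
  if (nrow(vm) != n) stop("values and pos lengths differ")
  lo <- findInterval(pos - h, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + h, pos)
  out <- vm
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    w <- (1 - (abs(pos[j] - pos[i]) / h)^3)^3
    sw <- sum(w)
    out[i, ] <- (w %*% vm[j, , drop = FALSE]) / sw
  }
  if (is.matrix(values)) out else drop(out)
}

#' Compute all three BSA statistics with smoothed tracks
#'
#' Runs [snp_index()], [g_statistic()] and [euclidean_distance()] at every
#' site of a polarized table, then tricube-smooths the signed delta
#' SNP-index, G (into G') and ED^4 per chromosome with a shared window.
#' ED is raised to the fourth power *before* smoothing.
#'
#' @param table a filtered, polarized `bulk_variant_table`.
#' @param window_kb total smoothing window span in kb (default 1000, i.e.
#'   a 1-Mb window; the kernel half-width is `window_kb / 2`).
#' @return a `bsa_stats` data frame: chrom, pos, index_dwarf, index_tall,
#'   delta, G, Gprime, ED, ED4, ED4_smoothed, delta_smoothed.
#' @export
compute_bsa_stats <- function(table, window_kb = 1000) {
  stopifnot(is.data.frame(table))
  if (is.null(table$tall_allele))
    stop("table is not polarized; call polarize() first")
  h <- window_kb * 1000 / 2
  tall_is_alt <- table$tall_allele == "alt"
  bd_tall <- ifelse(tall_is_alt, table$bd_alt, table$bd_ref)
  bd_other <- ifelse(tall_is_alt, table$bd_ref, table$bd_alt)
  bt_tall <- ifelse(tall_is_alt, table$bt_alt, table$bt_ref)
  bt_other <- ifelse(tall_is_alt, table$bt_ref, table$bt_alt)

  idx <- snp_index(bd_tall, bd_other, bt_tall, bt_other)
  g <- g_statistic(bd_tall, bd_other, bt_tall, bt_other)
  edd <- euclidean_distance(idx$index_dwarf, idx$index_tall)

  stats <- data.frame(chrom = table$chrom, pos = table$pos,
                      index_dwarf = idx$index_dwarf,
                      index_tall = idx$index_tall,
                      delta = idx$delta, G = g,
                      Gprime = NA_real_, ED = edd$ed, ED4 = edd$ed4,
                      ED4_smoothed = NA_real_, delta_smoothed = NA_real_,
                      stringsAsFactors = FALSE)
  drop_idx <- which(is.na(stats$delta) | is.na(stats$G))
  if (length(drop_idx)) {
    message(length(drop_idx), " site(s) with zero bulk depth excluded")
    stats <- stats[-drop_idx, , drop = FALSE]
  }
  for (chrom in unique(stats$chrom)) {
    sel <- stats$chrom == chrom
    sm <- tricube_smooth(stats$pos[sel],
                         cbind(delta = stats$delta[sel],
                               G = stats$G[sel],
                               ED4 = stats$ED4[sel]), h)
    stats$delta_smoothed[sel] <- sm[, "delta"]
    stats$Gprime[sel] <- sm[, "G"]
    stats$ED4_smoothed[sel] <- sm[, "ED4"]
  }
  rownames(stats) <- NULL
  class(stats) <- c("bsa_stats", "data.frame")
  stats
}
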