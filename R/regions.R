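# Candidate-region calling from smoothed tracks: empirical quantile
# thresholds, maximal above-threshold runs with the >= 10-variant support
# rule, cross-method consensus by closed-interval overlap, and the interval
# arithmetic used in reporting.  All coordinates are 1-based, fully closed.

#' Empirical quantile threshold for a smoothed track
#'
#' The cutoff is the empirical quantile (linear interpolation between order
#' statistics, R type 7) of all smoothed values in the track.  For signed
#' tracks (delta SNP-index) set `absolute = TRUE` so the quantile is taken
#' on `|values|`.
#'
#' @param values genome-wide smoothed values.
#' @param q quantile level in (0, 1]; default 0.999.
#' @param statistic label carried into the result.
#' @param absolute take the quantile of absolute values.
#' @return list of class `bsa_threshold` with `statistic`, `q`, `cutoff`,
#'   `absolute`.
#' @export
compute_threshold <- function(values, q = 0.999, statistic = "stat",
                              absolute = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot compute a threshold from an empty track")
  stopifnot(q > 0, q <= 1)
  if (absolute) values <- abs(values)
  structure(list(statistic = statistic, q = q,
                 cutoff = quantile(values, q, type = 7, names = FALSE),
                 absolute = absolute),
            class = "bsa_threshold")
}

#' Call candidate regions from a smoothed track
#'
#' Forms maximal runs of consecutive sites whose smoothed value is at or
#' above the cutoff (absolute value for signed tracks), merges runs whose
#' intervening sub-threshold territory spans at most `merge_gap` bp, and
#' keeps runs supported by at least `min_sites` above-threshold sites.
#' Region bounds are the positions of the first and last above-threshold
#' sites of the run.
#'
#' @param stats a `bsa_stats` data frame (or any frame with `chrom`, `pos`
#'   and the value column).
#' @param value_col name of the smoothed-value column to threshold.
#' @param threshold a `bsa_threshold` from [compute_threshold()], or a bare
#'   numeric cutoff.
#' @param min_sites minimum above-threshold sites per region (default 10).
#' @param merge_gap maximum bp of sub-threshold territory bridged when
#'   merging adjacent runs (default 0: no merging).
#' @param method method label stored in the output.
#' @return data frame of class `candidate_regions`: chrom, start, end,
#'   method, n_sites_above, peak_pos, peak_value, ordered by peak_value
#'   descending (so the first row is the top-ranked region).
#' @export
call_regions <- function(stats, value_col, threshold, min_sites = 10,
                         merge_gap = 0, method = value_col) {
  cutoff <- if (inherits(threshold, "bsa_threshold")) threshold$cutoff
            else as.numeric(threshold)
  absolute <- if (inherits(threshold, "bsa_threshold")) threshold$absolute
              else FALSE
  v <- stats[[value_col]]
  if (absolute) v <- abs(v)
  out <- list()
  for (chrom in unique(stats$chrom)) {
    sel <- which(stats$chrom == chrom)
    pos <- stats$pos[sel]
    above <- !is.na(v[sel]) & v[sel] >= cutoff
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(i = starts[r$values], j = ends[r$values])
    # merge runs separated by <= merge_gap bp of sub-threshold territory
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) {
      for (k in 2L:nrow(runs)) {
        gap <- pos[runs$i[k]] - pos[merged$j[nrow(merged)]] - 1L
        if (gap <= merge_gap) {
          merged$j[nrow(merged)] <- runs$j[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
    }
    for (k in seq_len(nrow(merged))) {
      jj <- merged$i[k]:merged$j[k]
      n_above <- sum(above[jj])
      if (n_above < min_sites) next
      above_jj <- jj[above[jj]]
      pk <- above_jj[which.max(v[sel][above_jj])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = pos[min(above_jj)], end = pos[max(above_jj)],
        method = method, n_sites_above = n_above,
        peak_pos = pos[pk], peak_value = v[sel][pk],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               method = character(), n_sites_above = integer(),
               peak_pos = numeric(), peak_value = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(-res$peak_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_regions", "data.frame")
  res
}

#' Cross-method consensus of candidate regions
#'
#' Two regions support each other when their closed intervals overlap by at
#' least one bp on the same chromosome.  Every input region is returned
#' (none invented, none lost), annotated with the set of supporting
#' methods, their count, and the best reciprocal-overlap fraction
#' `min(intersection/len_a, intersection/len_b)` over its cross-method
#' partners.  Output is ordered by supporting-method count (descending),
#' then start position.
#'
#' @param regions_by_method named list of `candidate_regions` data frames,
#'   one per method; names override any `method` column.
#' @return data frame with chrom, start, end, method, n_sites_above,
#'   methods (comma-joined supporting set), n_methods,
#'   reciprocal_overlap (NA when single-method).
#' @export
consensus_regions <- function(regions_by_method) {
  stopifnot(is.list(regions_by_method), !is.null(names(regions_by_method)))
  all <- do.call(rbind, lapply(names(regions_by_method), function(m) {
    r <- as.data.frame(regions_by_method[[m]])
    if (nrow(r) == 0L) return(NULL)
    r$method <- m
    if (is.null(r$n_sites_above)) r$n_sites_above <- NA_integer_
    r[, c("chrom", "start", "end", "method", "n_sites_above")]
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), method = character(),
                      methods = character(), n_methods = integer(),
                      reciprocal_overlap = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(all)
  methods <- vector("list", n)
  recip <- rep(NA_real_, n)
  for (i in seq_len(n)) methods[[i]] <- all$method[i]
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (all$chrom[i] != all$chrom[j]) next
    ov <- min(all$end[i], all$end[j]) - max(all$start[i], all$start[j]) + 1
    if (ov < 1) next
    li <- all$end[i] - all$start[i] + 1
    lj <- all$end[j] - all$start[j] + 1
    if (all$method[j] != all$method[i]) {
      methods[[i]] <- union(methods[[i]], all$method[j])
      methods[[j]] <- union(methods[[j]], all$method[i])
      rec <- min(ov / li, ov / lj)
      recip[i] <- max(recip[i], rec, na.rm = TRUE)
      recip[j] <- max(recip[j], rec, na.rm = TRUE)
    }
  }
  all$methods <- vapply(methods, function(m) paste(sort(m), collapse = ","), "")
  all$n_methods <- lengths(methods)
  all$reciprocal_overlap <- recip
  all <- all[order(-all$n_methods, all$start), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Length of a 1-based closed genomic interval
#'
#' `(end - start + 1)` scaled to the requested unit; kb and Mb values are
#' rounded half-up to two decimals, matching conventional interval
#' reporting.
#'
#' @param start,end 1-based inclusive endpoints, `start <= end`.
#' @param unit `"bp"`, `"kb"` or `"Mb"`.
#' @return numeric span.
#' @export
interval_span <- function(start, end, unit = c("bp", "kb", "Mb")) {
  unit <- match.arg(unit)
  if (any(start > end)) stop("start must not exceed end")
  len <- end - start + 1
  scale <- switch(unit, bp = 1, kb = 1e3, Mb = 1e6)
  x <- len / scale
  if (unit == "bp") return(x)
  floor(x * 100 + 0.5 + 1e-9) / 100   # round half-up, 2 decimals
}

#' Fill variant and gene counts for a candidate region
#'
#' Counts SNP and InDel sites of the variant table inside the closed
#' interval, the "effective" subset whose impact tag is in
#' `effective_impacts`, and genes whose `[start, end]` overlaps the region
#' by at least 1 bp.
#'
#' @param region one-row data frame (or list) with chrom, start, end.
#' @param table a `bulk_variant_table` (any filtering level).
#' @param genes data frame of gene records (chrom, start, end, gene_id),
#'   e.g. from [read_gff_genes()]; may be `NULL`.
#' @param effective_impacts impact tags counted as effective/functional
#'   (default HIGH and MODERATE).
#' @return list with total_snps, total_indels, effective_snps,
#'   effective_indels, annotated_genes.
#' @export
summarize_region <- function(region, table, genes = NULL,
                             effective_impacts = c("HIGH", "MODERATE")) {
  sel <- table$chrom == region$chrom &
    table$pos >= region$start & table$pos <= region$end
  slice <- table[sel, , drop = FALSE]
  eff <- slice$impact %in% effective_impacts
  snp <- slice$variant_class == "SNP"
  ngenes <- if (is.null(genes)) 0L else
    sum(genes$chrom == region$chrom & genes$start <= region$end &
          genes$end >= region$start)
  list(total_snps = sum(snp), total_indels = sum(!snp),
       effective_snps = sum(snp & eff), effective_indels = sum(!snp & eff),
       annotated_genes = as.integer(ngenes))
}
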