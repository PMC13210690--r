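# Germplasm haplotype association: haplotype definition from a small SNP
# panel, one-way ANOVA with Duncan's multiple range test and compact
# letters, per-site two-group tests, frequency breakdowns, and the
# 2^-ddCt relative-expression contrast.

#' Group panel accessions into haplotypes
#'
#' One group per distinct joint allele string over the panel sites.
#' Accessions with an incomplete allele string are excluded (logged).
#' Labels `Hap1..HapK` are assigned by descending overall mean height
#' (mean of the per-accession year means), ties broken by allele string;
#' the ordering rule is a reporting convention, overridable via
#' `label_map`.
#'
#' @param panel data frame with one column per site plus height columns.
#' @param site_cols names of the allele-site columns (default: columns
#'   matching `^s[0-9]+$`).
#' @param height_cols names of the per-year height columns (default:
#'   columns starting with `height_`).
#' @param label_map optional named character vector mapping allele strings
#'   to labels, overriding the mean-height ordering.
#' @return list of class `haplotype_groups`: `groups` (data frame with
#'   haplotype, allele_string, n, one mean column per height column,
#'   overall_mean), `panel` (complete rows with a `haplotype` column),
#'   `excluded` (number of incomplete accessions).
#' @export
define_haplotypes <- function(panel,
                              site_cols = grep("^s[0-9]+$", names(panel),
                                               value = TRUE),
                              height_cols = grep("^height_", names(panel),
                                                 value = TRUE),
                              label_map = NULL) {
  stopifnot(is.data.frame(panel), length(site_cols) >= 1L)
  if (nrow(panel) == 0L) stop("empty accession panel")
  alle <- panel[, site_cols, drop = FALSE]
  complete <- rowSums(is.na(alle) | alle == "") == 0L
  if (any(!complete))
    message(sum(!complete), " accession(s) with incomplete allele strings excluded")
  panel <- panel[complete, , drop = FALSE]
  if (nrow(panel) == 0L) stop("no accession has a complete allele string")
  string <- do.call(paste0, panel[, site_cols, drop = FALSE])

  ustr <- unique(string)
  per_acc_mean <- rowMeans(panel[, height_cols, drop = FALSE])
  overall <- vapply(ustr, function(s) mean(per_acc_mean[string == s]), 1)
  ord <- order(-overall, ustr)
  ustr <- ustr[ord]
  labels <- if (!is.null(label_map)) {
    if (!all(ustr %in% names(label_map)))
      stop("label_map does not cover every observed allele string")
    unname(label_map[ustr])
  } else sprintf("Hap%d", seq_along(ustr))

  groups <- data.frame(haplotype = labels, allele_string = ustr,
                       n = vapply(ustr, function(s) sum(string == s), 1L),
                       stringsAsFactors = FALSE, row.names = NULL)
  for (hc in height_cols)
    groups[[paste0("mean_", sub("^height_", "", hc))]] <-
      vapply(ustr, function(s) mean(panel[[hc]][string == s]), 1)
  groups$overall_mean <- overall[ord]
  panel$haplotype <- labels[match(string, ustr)]
  structure(list(groups = groups, panel = panel,
                 excluded = sum(!complete)),
            class = "haplotype_groups")
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(sprintf("<haplotype_groups> %d group(s), %d accession(s)\n",
              nrow(x$groups), nrow(x$panel)))
  print(x$groups, ...)
  invisible(x)
}

# Duncan critical range for means p ranks apart: the studentized-range
# quantile at protection level alpha_p = 1 - (1 - alpha)^(p - 1), scaled by
# sqrt(MS_error / n_h) with n_h the harmonic mean group size.
.duncan_range <- function(p, df_error, ms_error, n_h, alpha) {
  qtukey((1 - alpha)^(p - 1), p, df_error) * sqrt(ms_error / n_h)
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way ANOVA of `values ~ groups`, then runs Duncan's stepwise
#' procedure on the group means: means `p` ranks apart are compared against
#' the critical range `R_p = q(alpha_p, p, df) * sqrt(MS_error / n_h)` with
#' protection level `alpha_p = 1 - (1 - alpha)^(p - 1)` and `n_h` the
#' harmonic mean group size; a range found non-significant protects all its
#' sub-ranges.  Compact letters are assigned so that groups sharing a
#' letter are not significantly different.  Groups with fewer than two
#' observations are excluded from the comparison and reported.
#'
#' @param values numeric response (e.g. height in cm).
#' @param groups group labels, same length.
#' @param alpha significance level (default 0.05).
#' @return list of class `duncan_result`: `anova` (data frame with F,
#'   df1, df2, p_value, ms_error), `means` (data frame with group, n,
#'   mean, letters, ordered by mean descending), `alpha`, `excluded`
#'   (labels of dropped groups).
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2L]
  keep <- !(groups %in% excluded)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2L)
    stop("need at least two groups with >= 2 members")

  fit <- aov(values ~ factor(groups))
  an <- summary(fit)[[1L]]
  ms_error <- an["Residuals", "Mean Sq"]
  df_error <- an["Residuals", "Df"]
  anova_tab <- data.frame(F = an[1L, "F value"], df1 = an[1L, "Df"],
                          df2 = df_error, p_value = an[1L, "Pr(>F)"],
                          ms_error = ms_error, row.names = NULL)

  mns <- tapply(values, groups, mean)
  ns <- table(groups)[names(mns)]
  ord <- order(-mns)
  mns <- mns[ord]; ns <- ns[ord]
  k <- length(mns)
  n_h <- k / sum(1 / as.numeric(ns))

  if (ms_error <= 0) {
    # degenerate zero-variance data: any difference is significant,
    # identical means share a letter
    nonsig <- outer(seq_len(k), seq_len(k),
                    function(i, j) mns[i] == mns[j])
  } else {
    # step-down: span (i, j) over the means sorted descending is
    # non-significant if its range <= R_p or any containing span was
    nonsig <- diag(TRUE, k)
    for (span in rev(seq.int(2L, k))) {     # longest spans first
      for (i in seq_len(k - span + 1L)) {
        j <- i + span - 1L
        parent_ns <- (i > 1L && nonsig[i - 1L, j]) ||
                     (j < k && nonsig[i, j + 1L]) ||
                     (span == k && FALSE)
        r_p <- .duncan_range(span, df_error, ms_error, n_h, alpha)
        if (parent_ns || (mns[i] - mns[j]) <= r_p) {
          nonsig[i, j] <- nonsig[j, i] <- TRUE
          for (a in i:j) for (b in i:j) nonsig[a, b] <- TRUE
        }
      }
    }
  }

  letters_out <- .compact_letters(nonsig)
  means <- data.frame(group = names(mns), n = as.integer(ns),
                      mean = as.numeric(mns), letters = letters_out,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(anova = anova_tab, means = means, alpha = alpha,
                 excluded = excluded),
            class = "duncan_result")
}

# Compact letter display from a symmetric non-significance matrix whose
# groups are sorted by mean: maximal contiguous non-significant spans each
# get one letter.
.compact_letters <- function(nonsig) {
  k <- nrow(nonsig)
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    spans[[i]] <- c(i, j)
  }
  # keep maximal spans only
  maximal <- Filter(function(s) {
    !any(vapply(spans, function(t) (t[1] <= s[1] && s[2] <= t[2] &&
                                      !(t[1] == s[1] && t[2] == s[2])),
                TRUE))
  }, unique(spans))
  lab <- character(k)
  for (si in seq_along(maximal)) {
    s <- maximal[[si]]
    for (g in s[1]:s[2]) lab[g] <- paste0(lab[g], letters[si])
  }
  lab
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("<duncan_result> F(%d, %d) = %.3f, p = %.4g (alpha = %g)\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value, x$alpha))
  print(x$means, ...)
  if (length(x$excluded))
    cat("excluded (n < 2):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Single-marker allele-group comparison
#'
#' Splits accessions by the allele carried at one panel site and compares
#' heights with a two-sample Student's t-test (equal variance by default;
#' set `var_equal = FALSE` for Welch).
#'
#' @param panel accession data frame.
#' @param site_col allele column to split on.
#' @param height_col phenotype column to test.
#' @param var_equal pool the variances (classic Student's t)?
#' @return list with `testable`; when testable: `alleles`, `n`, `means`,
#'   `t`, `df`, `p_value`, `degenerate` (TRUE when the data are constant
#'   and no statistic exists).
#' @export
single_marker_test <- function(panel, site_col, height_col,
                               var_equal = TRUE) {
  a <- as.character(panel[[site_col]])
  y <- panel[[height_col]]
  ok <- !is.na(a) & a != "" & !is.na(y)
  a <- a[ok]; y <- y[ok]
  lev <- sort(unique(a))
  if (length(lev) < 2L)
    return(list(testable = FALSE, reason = "monomorphic site",
                alleles = lev))
  if (length(lev) > 2L)
    return(list(testable = FALSE, reason = "site is not biallelic",
                alleles = lev))
  g1 <- y[a == lev[1L]]; g2 <- y[a == lev[2L]]
  means <- c(mean(g1), mean(g2)); names(means) <- lev
  tt <- tryCatch(t.test(g1, g2, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(testable = TRUE, degenerate = TRUE, alleles = lev,
                n = c(length(g1), length(g2)), means = means,
                t = NA_real_, df = NA_real_, p_value = NA_real_))
  list(testable = TRUE, degenerate = FALSE, alleles = lev,
       n = c(length(g1), length(g2)), means = means,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Haplotype frequency breakdown by stratum
#'
#' Per-stratum haplotype percentages.  Percentages are rounded to one
#' decimal; any rounding remainder is absorbed by the largest cell so each
#' stratum sums to exactly 100.0.  Empty strata are excluded with a
#' warning.  Invariant to input row order.
#'
#' @param panel data frame with a `haplotype` column (e.g. the `panel`
#'   element of [define_haplotypes()]).
#' @param by stratifying column, e.g. `"market_class"` or `"region"`.
#' @return data frame: stratum, haplotype, n, pct.
#' @export
frequency_breakdown <- function(panel, by) {
  stopifnot(by %in% names(panel), "haplotype" %in% names(panel))
  strata <- sort(unique(as.character(panel[[by]])))
  haps <- sort(unique(as.character(panel$haplotype)))
  out <- list()
  for (s in strata) {
    sel <- panel[[by]] == s
    if (!sum(sel)) { warning("empty stratum: ", s); next }
    n <- vapply(haps, function(h) sum(panel$haplotype[sel] == h), 1L)
    pct <- round(100 * n / sum(n), 1)
    # put the rounding remainder on the largest cell
    imax <- which.max(n)
    pct[imax] <- round(pct[imax] + (100 - sum(pct)), 1)
    out[[s]] <- data.frame(stratum = s, haplotype = haps, n = n, pct = pct,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate
#' before any contrast.  Per biological replicate,
#' `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean(dCt)` of the
#' reference sample group, and relative expression is `2^-ddCt` (exactly
#' 1.0 at the reference-group mean).  Groups are compared by Student's
#' t-test on the dCt values.  Samples missing the reference-gene Ct are
#' excluded with a message.
#'
#' @param samples data frame with columns `group` (sample/line label),
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_reference` (an optional
#'   `gene` column is analysed per level).
#' @param reference_group group whose mean dCt anchors the contrast.
#' @return list of class `ddct_result`: `per_rep` (group, gene, bio_rep,
#'   dct, ddct, rel_expr), `group_summary` (mean dCt, fold change
#'   `2^-(mean dCt - reference mean dCt)`), `t_test` (per gene, when
#'   exactly two groups).
#' @export
ddct <- function(samples, reference_group) {
  need <- c("group", "bio_rep", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(samples)))
  if (!"gene" %in% names(samples)) samples$gene <- "target"
  drop <- is.na(samples$ct_reference) | is.na(samples$ct_target)
  if (any(drop)) {
    message(sum(drop), " sample row(s) without both Ct values excluded")
    samples <- samples[!drop, , drop = FALSE]
  }
  if (!reference_group %in% samples$group)
    stop("reference_group not present in 'group'")
  agg <- stats::aggregate(
    samples[, c("ct_target", "ct_reference")],
    by = samples[, c("group", "gene", "bio_rep")], FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference

  per_rep <- list(); summ <- list(); tt <- list()
  for (g in unique(agg$gene)) {
    a <- agg[agg$gene == g, , drop = FALSE]
    ref_mean <- mean(a$dct[a$group == reference_group])
    a$ddct <- a$dct - ref_mean
    a$rel_expr <- 2^(-a$ddct)
    per_rep[[g]] <- a
    gs <- stats::aggregate(a$dct, by = list(group = a$group), FUN = mean)
    names(gs)[2L] <- "mean_dct"
    gs$gene <- g
    gs$fold_change <- 2^(-(gs$mean_dct - ref_mean))
    summ[[g]] <- gs
    grps <- unique(a$group)
    if (length(grps) == 2L) {
      other <- setdiff(grps, reference_group)
      tt[[g]] <- t.test(a$dct[a$group == other],
                        a$dct[a$group == reference_group],
                        var.equal = TRUE)
    }
  }
  structure(list(per_rep = do.call(rbind, per_rep),
                 group_summary = do.call(rbind, summ),
                 t_test = tt, reference_group = reference_group),
            class = "ddct_result")
}
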