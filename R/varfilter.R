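# Variant filtering and parental polarization.
#
# The analysis substrate is a "bulk variant table": biallelic sites with
# per-sample ref/alt read depths for the two parents and the two bulks.
# Filtering retains sites with QUAL >= 30, MQ >= 30, depth >= 10 in each
# parent and >= 15 in each bulk, no missing sample, and opposite-homozygous
# parents; polarization then records which allele came from the tall parent
# so every downstream frequency is a tall-allele frequency.

#' Read a multi-sample variant table
#'
#' Accepts either the flat TSV dialect written by [write_variant_tsv()] or
#' a VCF 4.2 with per-sample `AD` fields (read via the VariantAnnotation
#' package).  Multi-allelic records are carried through flagged
#' `biallelic = FALSE` for removal by [apply_filters()].
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param roles named character vector mapping sample roles to VCF sample
#'   names, with names `parent_dwarf`, `parent_tall`, `bulk_dwarf`,
#'   `bulk_tall`.  Defaults to the samples written by
#'   [write_variant_vcf()]: `PD`, `PT`, `BD`, `BT`.
#' @return an unfiltered `bulk_variant_table` data frame.
#' @export
read_variants <- function(path, format = c("tsv", "vcf"),
                          roles = c(parent_dwarf = "PD", parent_tall = "PT",
                                    bulk_dwarf = "BD", bulk_tall = "BT")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (file.size(path) == 0L) {
      warning("empty variant file: ", path)
      return(.empty_variant_table())
    }
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
      warning("no variant records in ", path)
      return(.empty_variant_table())
    }
    need <- c("chrom", "pos", "ref", "alt", "qual", "mq", .depth_cols)
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("variant TSV is missing columns: ", paste(miss, collapse = ", "))
    if (is.null(tab$biallelic)) tab$biallelic <- TRUE
    if (is.null(tab$variant_class))
      tab$variant_class <- ifelse(nchar(tab$ref) == 1L & nchar(tab$alt) == 1L,
                                  "SNP", "InDel")
    if (is.null(tab$impact)) tab$impact <- "MODIFIER"
  } else {
    tab <- .read_variants_vcf(path, roles)
    if (is.null(tab)) return(.empty_variant_table())
  }
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("bulk_variant_table", "data.frame")
  tab
}

.empty_variant_table <- function() {
  tab <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), qual = numeric(), mq = numeric(),
                    variant_class = character(), impact = character(),
                    biallelic = logical(), stringsAsFactors = FALSE)
  for (cl in .depth_cols) tab[[cl]] <- integer()
  class(tab) <- c("bulk_variant_table", "data.frame")
  tab
}

.read_variants_vcf <- function(path, roles) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the 'VariantAnnotation' package")
  stopifnot(all(.role_order %in% names(roles)))
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0L) {
    warning("no variant records in ", path)
    return(NULL)
  }
  hdr_samples <- colnames(vcf)
  bad_role <- setdiff(unname(roles[.role_order]), hdr_samples)
  if (length(bad_role))
    stop("unknown sample name(s) in roles: ", paste(bad_role, collapse = ", "))
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno))
    stop("VCF has no AD FORMAT field for samples ",
         paste(roles[.role_order], collapse = ", "))
  ad <- geno$AD
  rr <- SummarizedExperiment::rowRanges(vcf)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  alt1 <- vapply(seq_len(nrow(vcf)), function(i)
    as.character(VariantAnnotation::alt(vcf)[[i]][1L]), "")
  mq <- VariantAnnotation::info(vcf)$MQ
  if (is.null(mq)) mq <- rep(NA_real_, nrow(vcf))
  tab <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt1,
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    mq = as.numeric(unlist(mq)),
    variant_class = NA_character_,
    impact = "MODIFIER",
    biallelic = nalt == 1L,
    stringsAsFactors = FALSE)
  tab$variant_class <- ifelse(nchar(tab$ref) == 1L & nchar(tab$alt) == 1L,
                              "SNP", "InDel")
  prefix <- c(parent_dwarf = "pd", parent_tall = "pt",
              bulk_dwarf = "bd", bulk_tall = "bt")
  for (role in .role_order) {
    s <- unname(roles[[role]])
    adr <- ad[, s]
    get_k <- function(k) vapply(adr, function(v) {
      if (length(v) >= k && !is.na(v[k])) as.integer(v[k]) else NA_integer_
    }, 1L)
    tab[[paste0(prefix[[role]], "_ref")]] <- get_k(1L)
    tab[[paste0(prefix[[role]], "_alt")]] <- get_k(2L)
  }
  tab
}

#' Filter a bulk variant table
#'
#' Retains exactly the sites that are biallelic, have `qual >= qual_min`
#' and `mq >= mq_min`, depth at least `parent_depth_min` in each parent and
#' `bulk_depth_min` in each bulk, no missing sample depths, and parents
#' that are opposite homozygotes (each parent's minor-allele read fraction
#' at most `hom_tol`, with the two parental major alleles different).
#'
#' Each removed site is attributed to the *first* failing rule in the fixed
#' order biallelic, qual, mq, parent_depth, bulk_depth, missing,
#' not_opposite; the per-rule counts are attached as
#' `attr(result, "removal_report")`, and always sum to
#' `nrow(input) - nrow(output)`.
#'
#' @param table an unfiltered `bulk_variant_table`.
#' @param qual_min,mq_min phred-scaled quality floors (default 30/30).
#' @param parent_depth_min,bulk_depth_min per-sample depth floors
#'   (default 10/15).
#' @param hom_tol maximum minor-allele read fraction for a parent to be
#'   called homozygous (default 0.1).
#' @return the filtered table, with a `removal_report` attribute.
#' @export
apply_filters <- function(table, qual_min = 30, mq_min = 30,
                          parent_depth_min = 10, bulk_depth_min = 15,
                          hom_tol = 0.1) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  if (n == 0L) {
    attr(table, "removal_report") <- .empty_report()
    return(table)
  }
  dp <- function(a, b) table[[a]] + table[[b]]
  na0 <- function(x) ifelse(is.na(x), FALSE, x)

  pd_dp <- dp("pd_ref", "pd_alt"); pt_dp <- dp("pt_ref", "pt_alt")
  bd_dp <- dp("bd_ref", "bd_alt"); bt_dp <- dp("bt_ref", "bt_alt")
  any_missing <- Reduce(`|`, lapply(.depth_cols,
                                    function(cl) is.na(table[[cl]])))

  hom <- function(ref_n, alt_n) {
    tot <- ref_n + alt_n
    minor <- pmin(ref_n, alt_n)
    ok <- tot > 0 & minor / tot <= hom_tol
    major_alt <- alt_n > ref_n
    list(ok = na0(ok), major_alt = major_alt)
  }
  pdh <- hom(table$pd_ref, table$pd_alt)
  pth <- hom(table$pt_ref, table$pt_alt)
  opposite <- pdh$ok & pth$ok & (pdh$major_alt != pth$major_alt)

  fails <- list(
    biallelic    = !na0(table$biallelic),
    qual         = na0(table$qual < qual_min),
    mq           = na0(table$mq < mq_min),
    parent_depth = na0(pd_dp < parent_depth_min) |
                   na0(pt_dp < parent_depth_min),
    bulk_depth   = na0(bd_dp < bulk_depth_min) |
                   na0(bt_dp < bulk_depth_min),
    missing      = any_missing,
    not_opposite = !na0(opposite))

  reason <- rep(NA_character_, n)
  for (rule in names(fails)) {
    hit <- is.na(reason) & fails[[rule]]
    reason[hit] <- rule
  }
  keep <- is.na(reason)
  report <- vapply(names(fails), function(r) sum(reason == r, na.rm = TRUE), 1L)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bulk_variant_table", "data.frame")
  attr(out, "removal_report") <- as.list(report)
  out
}

.empty_report <- function() {
  as.list(setNames(integer(7),
                   c("biallelic", "qual", "mq", "parent_depth",
                     "bulk_depth", "missing", "not_opposite")))
}

#' Polarize a filtered table by parental allele origin
#'
#' Records, per site, which allele (`"ref"` or `"alt"`) was carried by the
#' tall parent; all downstream SNP-index values are frequencies of that
#' allele.  Requires the table to have passed [apply_filters()] so parents
#' are opposite homozygotes; an ambiguous parental genotype (equal ref and
#' alt support in a parent) is a hard error because it should be
#' unreachable after filtering.
#'
#' @param table a filtered `bulk_variant_table`.
#' @return the table with a `tall_allele` column added.
#' @export
polarize <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    table$tall_allele <- character(0)
    return(table)
  }
  if (any(table$pt_ref == table$pt_alt) || any(table$pd_ref == table$pd_alt))
    stop("ambiguous parental genotype encountered during polarization; ",
         "run apply_filters() first")
  tall_alt <- table$pt_alt > table$pt_ref
  dwarf_alt <- table$pd_alt > table$pd_ref
  if (any(tall_alt == dwarf_alt))
    stop("parents share a major allele at some site; run apply_filters() first")
  table$tall_allele <- ifelse(tall_alt, "alt", "ref")
  table
}
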