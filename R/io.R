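# Readers and writers for the flat-file interfaces: the allele-depth TSV
# dialect, minimal VCF 4.2 with per-sample AD, marker/profile/panel TSVs,
# and gene records from GFF3.

.depth_cols <- c("pd_ref", "pd_alt", "pt_ref", "pt_alt",
                 "bd_ref", "bd_alt", "bt_ref", "bt_alt")

.role_order <- c("parent_dwarf", "parent_tall", "bulk_dwarf", "bulk_tall")

#' Write a bulk variant table as TSV
#'
#' Flat tab-separated dialect: chrom, pos, ref, alt, qual, mq,
#' variant_class, impact, biallelic, and ref/alt depth per sample role
#' (`pd_*` dwarf parent, `pt_*` tall parent, `bd_*` dwarf bulk, `bt_*` tall
#' bulk), plus `tall_allele` when the table has been polarized.
#'
#' @param table a `bulk_variant_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a bulk variant table as minimal VCF 4.2
#'
#' Emits GT:AD per sample with samples named `PD`, `PT`, `BD`, `BT`
#' (dwarf parent, tall parent, dwarf bulk, tall bulk).  Parent genotypes
#' are called from their major allele; bulks are pooled samples and get
#' `./.` genotypes with AD only.  MQ is written as an INFO field.
#'
#' @param table a `bulk_variant_table`.
#' @param path output file.
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` headers; defaults to the maximum position seen per
#'   chromosome.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(table, path, contig_lengths = NULL) {
  tab <- as.data.frame(table)
  if (is.null(contig_lengths))
    contig_lengths <- tapply(tab$pos, tab$chrom, max)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "PD", "PT", "BD", "BT"), collapse = "\t"))
  gt_parent <- function(ref_n, alt_n) {
    dp <- ref_n + alt_n
    ifelse(dp == 0, "./.", ifelse(alt_n > ref_n, "1/1", "0/0"))
  }
  fmt <- function(gt, ref_n, alt_n) sprintf("%s:%d,%d", gt, ref_n, alt_n)
  body <- paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt,
                format(tab$qual, trim = TRUE), ".",
                sprintf("MQ=%s", format(tab$mq, trim = TRUE)), "GT:AD",
                fmt(gt_parent(tab$pd_ref, tab$pd_alt), tab$pd_ref, tab$pd_alt),
                fmt(gt_parent(tab$pt_ref, tab$pt_alt), tab$pt_ref, tab$pt_alt),
                fmt("./.", tab$bd_ref, tab$bd_alt),
                fmt("./.", tab$bt_ref, tab$bt_alt),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import()` keeping only records of the
#' requested feature type, as the plain data frame consumed by
#' [summarize_region()].
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data frame with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the 'rtracklayer' package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[as.character(gr$type) == feature_type, , drop = FALSE]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%05d", seq_len(nrow(gr)))
  data.frame(chrom = as.character(gr$seqnames), start = gr$start,
             end = gr$end, gene_id = id, stringsAsFactors = FALSE)
}

#' Write a toy GFF3 of gene records
#'
#' @param genes data frame with chrom, start, end, gene_id.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- sprintf("%s\tbsaqtl\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a marker panel TSV (id, chrom, pos)
#' @param path TSV file.
#' @return data frame sorted by position.
#' @export
read_marker_panel <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(m)))
  m[order(m$pos), , drop = FALSE]
}

#' Read recombinant profiles TSV (individual, phenotype, one column per marker)
#' @param path TSV file.
#' @return data frame of profiles.
#' @export
read_profiles <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("individual", "phenotype") %in% names(p)))
  p
}
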