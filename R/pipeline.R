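# End-to-end orchestration: simulate -> filter -> statistics -> regions ->
# fine mapping -> germplasm, with a JSON manifest recording input hashes,
# configuration and per-stage row counts so a rerun with the same config is
# byte-identical.

#' Build and validate a pipeline configuration
#'
#' All defaults mirror the analysis defaults of the individual stages.
#' Configurations round-trip through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param seed integer seed (mandatory).
#' @param out_dir run directory; created if absent.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "varfilter", "bsastats", "regions", "finemap",
#'   "germplasm")`, executed in that canonical order.
#' @param variants_tsv input variant TSV when `simulate` is disabled.
#' @param gff gene annotation GFF3 (optional; region gene counts are
#'   skipped without it).  The simulate stage writes its own toy GFF.
#' @param sim named list of overrides passed to [sim_config()].
#' @param qual_min,mq_min,parent_depth_min,bulk_depth_min,hom_tol filter
#'   thresholds, see [apply_filters()].
#' @param window_kb smoothing window span, see [compute_bsa_stats()].
#' @param q quantile level for [compute_threshold()].
#' @param min_sites,merge_gap region-calling parameters.
#' @param alpha significance level for the germplasm stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            stages = c("simulate", "varfilter", "bsastats",
                                       "regions", "finemap", "germplasm"),
                            variants_tsv = NULL, gff = NULL,
                            sim = list(),
                            qual_min = 30, mq_min = 30,
                            parent_depth_min = 10, bulk_depth_min = 15,
                            hom_tol = 0.1, window_kb = 1000,
                            q = 0.999, min_sites = 10, merge_gap = 0,
                            alpha = 0.05) {
  known <- c("simulate", "varfilter", "bsastats", "regions", "finemap",
             "germplasm")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              stages = known[known %in% stages],
              variants_tsv = variants_tsv, gff = gff, sim = sim,
              qual_min = qual_min, mq_min = mq_min,
              parent_depth_min = parent_depth_min,
              bulk_depth_min = bulk_depth_min, hom_tol = hom_tol,
              window_kb = window_kb, q = q, min_sites = min_sites,
              merge_gap = merge_gap, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$sim <- as.list(cfg$sim)
  do.call(pipeline_config, cfg)
}

.stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the BSA pipeline
#'
#' Executes the enabled stages in canonical order inside
#' `config$out_dir`, writing per-stage TSV/JSON outputs and a
#' `manifest.json` with input hashes, the configuration, and per-stage row
#' counts.  A rerun with an identical configuration reproduces
#' byte-identical stage outputs.  Input files named in the configuration
#' are checked before any stage runs.
#'
#' @param config a [pipeline_config()] or path to its JSON serialization.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # fail fast on missing inputs, before any stage runs
  for (p in c(config$variants_tsv, config$gff))
    if (!is.null(p) && !file.exists(p))
      stop("input file does not exist: ", p)
  if (!"simulate" %in% config$stages && is.null(config$variants_tsv) &&
      any(c("varfilter", "bsastats", "regions") %in% config$stages))
    stop("variants_tsv is required when the simulate stage is disabled")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "bsaqtl",
                   version = as.character(utils::packageVersion("bsaqtl")),
                   config = unclass(config), stages = list())
  note <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
      rows = rows)
  }

  variants_path <- config$variants_tsv
  gff_path <- config$gff

  if ("simulate" %in% config$stages) {
    tryCatch({
      scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      truth <- simulate_f2(scfg)
      truth <- select_bulks(truth)
      tab <- sample_reads(truth)
      variants_path <- out("variants.tsv")
      write_variant_tsv(tab, variants_path)
      write_variant_vcf(tab, out("variants.vcf"),
                        setNames(rep(scfg$chrom_length, scfg$n_chrom),
                                 paste0("chr", seq_len(scfg$n_chrom))))
      genes <- .toy_genes(scfg)
      gff_path <- out("genes.gff3")
      write_gff_genes(genes, gff_path)
      pheno <- data.frame(individual = seq_along(truth$phenotype),
                          height = round(truth$phenotype, 2),
                          bulk = ifelse(seq_along(truth$phenotype) %in%
                                          truth$bulk_dwarf, "dwarf",
                                 ifelse(seq_along(truth$phenotype) %in%
                                          truth$bulk_tall, "tall", "")))
      write.table(pheno, out("phenotypes.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note("simulate", c(variants_path, out("variants.vcf"), gff_path,
                         out("phenotypes.tsv")), nrow(tab))
    }, error = function(e) .stage_error("simulate", e))
  }

  filtered <- NULL
  if ("varfilter" %in% config$stages) {
    tryCatch({
      raw <- read_variants(variants_path, "tsv")
      filtered <- apply_filters(raw, config$qual_min, config$mq_min,
                                config$parent_depth_min,
                                config$bulk_depth_min, config$hom_tol)
      filtered <- polarize(filtered)
      write_variant_tsv(filtered, out("filtered.tsv"))
      jsonlite::write_json(attr(filtered, "removal_report"),
                           out("filter_report.json"), auto_unbox = TRUE)
      note("varfilter", c(out("filtered.tsv"), out("filter_report.json")),
           nrow(filtered))
    }, error = function(e) .stage_error("varfilter", e))
  }

  stats <- NULL
  if ("bsastats" %in% config$stages) {
    tryCatch({
      if (is.null(filtered)) {
        filtered <- read_variants(out("filtered.tsv"), "tsv")
        class(filtered) <- c("bulk_variant_table", "data.frame")
      }
      stats <- compute_bsa_stats(filtered, config$window_kb)
      write.table(stats, out("stats.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note("bsastats", out("stats.tsv"), nrow(stats))
    }, error = function(e) .stage_error("bsastats", e))
  }

  if ("regions" %in% config$stages) {
    tryCatch({
      tracks <- list(
        `Index-slid` = list(col = "delta_smoothed", absolute = TRUE),
        Gprime = list(col = "Gprime", absolute = FALSE),
        ED = list(col = "ED4_smoothed", absolute = FALSE))
      regs <- lapply(names(tracks), function(m) {
        tr <- tracks[[m]]
        th <- compute_threshold(stats[[tr$col]], config$q, m, tr$absolute)
        call_regions(stats, tr$col, th, config$min_sites,
                     config$merge_gap, method = m)
      })
      names(regs) <- names(tracks)
      cons <- consensus_regions(regs)
      if (nrow(cons) && !is.null(gff_path)) {
        genes <- read_gff_genes(gff_path)
        extra <- t(vapply(seq_len(nrow(cons)), function(i)
          unlist(summarize_region(cons[i, ], filtered, genes)),
          numeric(5)))
        cons <- cbind(cons, extra)
      }
      write.table(cons, out("regions.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note("regions", out("regions.tsv"), nrow(cons))
    }, error = function(e) .stage_error("regions", e))
  }

  if ("finemap" %in% config$stages) {
    tryCatch({
      fx <- make_finemap_fixture(config$seed)
      res <- map_interval(fx$profiles, fx$markers)
      jsonlite::write_json(
        list(conflict = res$conflict, chrom = res$chrom,
             left_bp = res$left_bp, right_bp = res$right_bp,
             span_kb = if (!res$conflict)
               interval_span(res$left_bp, res$right_bp, "kb") else NULL,
             markers_in = res$markers_in,
             per_profile = res$per_profile),
        out("finemap.json"), auto_unbox = TRUE, null = "null")
      note("finemap", out("finemap.json"), nrow(fx$profiles))
    }, error = function(e) .stage_error("finemap", e))
  }

  if ("germplasm" %in% config$stages) {
    tryCatch({
      panel <- make_panel_fixture(config$seed)
      hg <- define_haplotypes(panel)
      write.table(hg$groups, out("haplotypes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      hc <- grep("^height_", names(hg$panel), value = TRUE)[1L]
      dres <- anova_duncan(hg$panel[[hc]], hg$panel$haplotype, config$alpha)
      jsonlite::write_json(list(anova = dres$anova, means = dres$means,
                                alpha = dres$alpha),
                           out("duncan.json"), auto_unbox = TRUE,
                           dataframe = "rows", digits = NA)
      freq <- rbind(frequency_breakdown(hg$panel, "market_class"),
                    frequency_breakdown(hg$panel, "region"))
      write.table(freq, out("frequencies.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      note("germplasm", c(out("haplotypes.tsv"), out("duncan.json"),
                          out("frequencies.tsv")), nrow(hg$groups))
    }, error = function(e) .stage_error("germplasm", e))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# Deterministic toy gene annotation tiling the simulated chromosomes
# (seeded off the sim config so reruns are identical).
.toy_genes <- function(scfg, genes_per_chrom = 400L) {
  set.seed(scfg$seed + 2L)
  out <- list()
  for (ci in seq_len(scfg$n_chrom)) {
    start <- sort(sample.int(scfg$chrom_length - 20000L, genes_per_chrom))
    out[[ci]] <- data.frame(
      chrom = paste0("chr", ci), start = start,
      end = pmin(start + sample(2000:15000, genes_per_chrom, TRUE),
                 scfg$chrom_length),
      gene_id = sprintf("gene_c%d_%04d", ci, seq_len(genes_per_chrom)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
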