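# Synthetic F2 bulk-segregant data generator.
#
# The generator states a fixed "world": an F2 of 715 individuals from two
# fully inbred parents that are opposite homozygotes at every variant site,
# truncation-selected extreme bulks of 30 + 30, pooled short-read sequencing
# at ~27x mean depth, and (optionally) one major QTL on the first simulated
# chromosome.  Defaults mirror that world; everything is seeded.

#' Configuration for the synthetic F2 bulk-segregant experiment
#'
#' Builds and validates the parameter set used by [simulate_f2()],
#' [select_bulks()] and [sample_reads()].  Defaults describe a single
#' major-QTL cross: 715 F2 individuals, bulks of 30 from each phenotypic
#' tail, seventeen unlinked 180-Mb chromosomes carrying 1500 variant sites
#' each, a QTL on chr15 at 107 Mb, ~27x pooled depth, and an additive
#' effect three residual standard deviations wide.  The site density
#' (~8 sites/Mb; far below real resequencing density) is chosen so that a
#' 1-Mb smoothing window spans only a handful of sites: noise excursions of
#' the smoothed tracks then cannot string ten consecutive sites above a
#' genome-wide quantile cutoff, which keeps the minimum-support rule of
#' [call_regions()] effective against false regions, while the 3-Gb genome
#' keeps the above-threshold slice around a real QTL several Mb wide.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_individuals number of F2 plants.
#' @param bulk_size individuals per extreme bulk (`2 * bulk_size <=
#'   n_individuals`).
#' @param n_sites variant sites per chromosome.
#' @param n_chrom number of unlinked chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bp.
#' @param cm_per_mb genetic-map density (cM per Mb); 0 disables crossovers.
#' @param qtl_chrom,qtl_position location of the causal site, or
#'   `qtl_position = NULL` for a null (no-QTL) world.  The nearest simulated
#'   site on `qtl_chrom` is moved to `qtl_position` so the causal
#'   polymorphism is itself observable.
#' @param additive_effect additive effect `a` (cm of height per tall
#'   allele).
#' @param dominance_effect dominance deviation `d` (cm) of the heterozygote.
#' @param residual_sd residual (polygenic + environmental) SD in cm.
#' @param mean_height mid-parent height in cm.
#' @param mean_depth mean pooled sequencing depth per site (Poisson).
#' @param base_error symmetric per-read base error probability.
#' @param indel_fraction fraction of sites simulated as InDels (the rest are
#'   SNPs).
#' @param effective_fraction fraction of sites tagged with a HIGH/MODERATE
#'   functional impact label.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_sites = 200, n_individuals = 50,
#'                   bulk_size = 10)
#' @export
sim_config <- function(seed,
                       n_individuals = 715L,
                       bulk_size = 30L,
                       n_sites = 1500L,
                       n_chrom = 17L,
                       chrom_length = 1.8e8,
                       cm_per_mb = 1,
                       qtl_chrom = "chr15",
                       qtl_position = 1.07e8,
                       additive_effect = 60,
                       dominance_effect = 30,
                       residual_sd = 20,
                       mean_height = 175,
                       mean_depth = 27,
                       base_error = 0.005,
                       indel_fraction = 0.12,
                       effective_fraction = 0.02) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory and must be a single integer")
  cfg <- list(
    seed = as.integer(seed),
    n_individuals = as.integer(n_individuals),
    bulk_size = as.integer(bulk_size),
    n_sites = as.integer(n_sites),
    n_chrom = as.integer(n_chrom),
    chrom_length = as.numeric(chrom_length),
    cm_per_mb = as.numeric(cm_per_mb),
    qtl_chrom = qtl_chrom,
    qtl_position = if (is.null(qtl_position)) NULL else as.numeric(qtl_position),
    additive_effect = as.numeric(additive_effect),
    dominance_effect = as.numeric(dominance_effect),
    residual_sd = as.numeric(residual_sd),
    mean_height = as.numeric(mean_height),
    mean_depth = as.numeric(mean_depth),
    base_error = as.numeric(base_error),
    indel_fraction = as.numeric(indel_fraction),
    effective_fraction = as.numeric(effective_fraction))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (2L * cfg$bulk_size > cfg$n_individuals)
    stop("2 * bulk_size must not exceed n_individuals")
  if (cfg$base_error < 0 || cfg$base_error >= 0.5)
    stop("base_error must lie in [0, 0.5)")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$residual_sd < 0) stop("residual_sd must be non-negative")
  if (cfg$n_sites < 1L || cfg$n_chrom < 1L || cfg$chrom_length < 1)
    stop("n_sites, n_chrom and chrom_length must be positive")
  if (cfg$cm_per_mb < 0) stop("cm_per_mb must be non-negative")
  if (!is.null(cfg$qtl_position)) {
    if (cfg$qtl_position < 1 || cfg$qtl_position > cfg$chrom_length)
      stop("qtl_position must lie within [1, chrom_length]")
    if (!cfg$qtl_chrom %in% paste0("chr", seq_len(cfg$n_chrom)))
      stop("qtl_chrom is not one of the simulated chromosomes")
  }
  invisible(cfg)
}

# One meiotic gamete: crossover count ~ Poisson(map length in Morgans),
# breakpoint positions uniform in bp (uniform genetic map), no interference.
# Returns 0/1 tall-parent origin at each site position.
.sim_gamete <- function(positions, chrom_length, morgans) {
  k <- rpois(1L, morgans)
  start <- sample.int(2L, 1L) - 1L
  if (k == 0L) return(rep.int(start, length(positions)))
  bp <- sort(runif(k, 0, chrom_length))
  (start + findInterval(positions, bp)) %% 2L
}

#' Simulate an F2 population from opposite-homozygous inbred parents
#'
#' Each F2 individual is the union of two F1 gametes per chromosome.
#' Crossovers per gamete are Poisson with mean equal to the chromosome's
#' genetic length in Morgans (`chrom_length * cm_per_mb / 1e6 / 100`),
#' positions uniform, no interference.  Height is
#' `mean_height + a * (g - 1) + d * [g == 1] + N(0, residual_sd^2)` where
#' `g` is the number of tall-parent alleles at the causal site (the QTL term
#' is omitted in a null configuration).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_truth`: a list with `config`, `sites`
#'   (data frame: chrom, pos, ref, alt, tall_is_alt, variant_class, impact),
#'   `genotypes` (list per chromosome of integer matrices, individuals x
#'   sites, counting tall-parent alleles), `phenotype` (cm), and `qtl_site`
#'   (row index into `sites` of the causal site, or `NA`).
#' @seealso [select_bulks()], [sample_reads()]
#' @export
simulate_f2 <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  morgans <- config$chrom_length * config$cm_per_mb / 1e6 / 100

  bases <- c("A", "C", "G", "T")
  sites_list <- vector("list", config$n_chrom)
  geno <- vector("list", config$n_chrom)
  names(geno) <- chroms
  qtl_row <- NA_integer_
  offset <- 0L

  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(config$chrom_length, config$n_sites))
    if (!is.null(config$qtl_position) && chroms[ci] == config$qtl_chrom) {
      j <- which.min(abs(pos - config$qtl_position))
      pos[j] <- as.integer(config$qtl_position)
      pos <- sort(pos)
      qtl_row <- offset + which(pos == as.integer(config$qtl_position))[1L]
    }
    ref <- sample(bases, config$n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    is_indel <- runif(config$n_sites) < config$indel_fraction
    alt[is_indel] <- paste0(alt[is_indel], "A")  # 1-bp insertion stand-in
    impact <- ifelse(runif(config$n_sites) < config$effective_fraction,
                     sample(c("HIGH", "MODERATE"), config$n_sites, replace = TRUE),
                     sample(c("LOW", "MODIFIER"), config$n_sites, replace = TRUE))
    sites_list[[ci]] <- data.frame(
      chrom = chroms[ci], pos = pos, ref = ref, alt = alt,
      tall_is_alt = runif(config$n_sites) < 0.5,
      variant_class = ifelse(is_indel, "InDel", "SNP"),
      impact = impact, stringsAsFactors = FALSE, row.names = NULL)

    g <- matrix(0L, nrow = config$n_individuals, ncol = config$n_sites)
    for (i in seq_len(config$n_individuals)) {
      g[i, ] <- .sim_gamete(pos, config$chrom_length, morgans) +
        .sim_gamete(pos, config$chrom_length, morgans)
    }
    geno[[ci]] <- g
    offset <- offset + config$n_sites
  }
  sites <- do.call(rbind, sites_list)

  pheno <- config$mean_height + rnorm(config$n_individuals, 0, config$residual_sd)
  if (!is.na(qtl_row)) {
    ci <- match(config$qtl_chrom, chroms)
    j <- qtl_row - (ci - 1L) * config$n_sites
    gq <- geno[[ci]][, j]
    pheno <- pheno + config$additive_effect * (gq - 1L) +
      config$dominance_effect * (gq == 1L)
  }

  structure(list(config = config, sites = sites, genotypes = geno,
                 phenotype = pheno, qtl_site = qtl_row,
                 bulk_dwarf = NULL, bulk_tall = NULL,
                 freq_dwarf = NULL, freq_tall = NULL),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d individuals, %d sites on %d chromosome(s)\n",
              x$config$n_individuals, nrow(x$sites), x$config$n_chrom))
  if (!is.na(x$qtl_site))
    cat(sprintf("  QTL at %s:%d\n", x$sites$chrom[x$qtl_site],
                x$sites$pos[x$qtl_site]))
  if (!is.null(x$bulk_dwarf))
    cat(sprintf("  bulks selected: %d dwarf + %d tall\n",
                length(x$bulk_dwarf), length(x$bulk_tall)))
  invisible(x)
}

#' Truncation-select the extreme phenotype bulks
#'
#' Picks the `bulk_size` lowest and `bulk_size` highest individuals by
#' height.  Ties are broken by individual index (stable order), so runs are
#' reproducible.  True tall-allele frequencies per bulk are recomputed as
#' (allele copies in bulk) / (2 * bulk_size).
#'
#' @param truth a `sim_truth` from [simulate_f2()].
#' @param bulk_size individuals per bulk; defaults to the config value.
#' @return `truth` with `bulk_dwarf`, `bulk_tall` (individual indices) and
#'   `freq_dwarf`, `freq_tall` (per-site true frequencies) filled in.
#' @export
select_bulks <- function(truth, bulk_size = truth$config$bulk_size) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- length(truth$phenotype)
  if (2L * bulk_size > n)
    stop("2 * bulk_size exceeds the number of individuals")
  ord <- order(truth$phenotype, seq_len(n))
  truth$bulk_dwarf <- sort(ord[seq_len(bulk_size)])
  truth$bulk_tall <- sort(ord[seq.int(n - bulk_size + 1L, n)])
  truth$freq_dwarf <- unlist(lapply(truth$genotypes, function(g)
    colSums(g[truth$bulk_dwarf, , drop = FALSE]) / (2 * bulk_size)),
    use.names = FALSE)
  truth$freq_tall <- unlist(lapply(truth$genotypes, function(g)
    colSums(g[truth$bulk_tall, , drop = FALSE]) / (2 * bulk_size)),
    use.names = FALSE)
  truth
}

#' Sample pooled sequencing reads for parents and bulks
#'
#' Per site and pool, total depth is Poisson(`mean_depth`) and the number of
#' tall-parent-allele reads is Binomial(depth, `f(1-e) + (1-f)e`) with `f`
#' the pool's true tall-allele frequency and `e` the base error.  Parents
#' are emitted as opposite homozygotes (`f` = 0 for the dwarf parent, 1 for
#' the tall parent).  QUAL and MQ are filled with passing defaults.
#'
#' Uses a seed offset of +1 from `config$seed` so the read stage has its own
#' reproducible stream regardless of what was drawn during simulation.
#'
#' @param truth a `sim_truth` with bulks selected.
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return a `bulk_variant_table` data frame (see [read_variants()]) with
#'   per-sample ref/alt depth columns `pd_*`, `pt_*`, `bd_*`, `bt_*`
#'   (parent dwarf / parent tall / dwarf bulk / tall bulk).
#' @export
sample_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(truth$bulk_dwarf))
    stop("bulks have not been selected; call select_bulks() first")
  set.seed(config$seed + 1L)
  n <- nrow(truth$sites)
  eps <- config$base_error

  draw_pool <- function(f) {
    dp <- rpois(n, config$mean_depth)
    tall <- rbinom(n, dp, f * (1 - eps) + (1 - f) * eps)
    list(tall = tall, other = dp - tall)
  }
  pd <- draw_pool(rep(0, n))          # dwarf parent: no tall alleles
  pt <- draw_pool(rep(1, n))          # tall parent: all tall alleles
  bd <- draw_pool(truth$freq_dwarf)
  bt <- draw_pool(truth$freq_tall)

  tall_is_alt <- truth$sites$tall_is_alt
  as_ref_alt <- function(p) {
    list(ref = ifelse(tall_is_alt, p$other, p$tall),
         alt = ifelse(tall_is_alt, p$tall, p$other))
  }
  pdra <- as_ref_alt(pd); ptra <- as_ref_alt(pt)
  bdra <- as_ref_alt(bd); btra <- as_ref_alt(bt)

  tab <- data.frame(
    chrom = truth$sites$chrom, pos = truth$sites$pos,
    ref = truth$sites$ref, alt = truth$sites$alt,
    qual = round(runif(n, 35, 2000), 2), mq = 60,
    variant_class = truth$sites$variant_class,
    impact = truth$sites$impact,
    biallelic = TRUE,
    pd_ref = pdra$ref, pd_alt = pdra$alt,
    pt_ref = ptra$ref, pt_alt = ptra$alt,
    bd_ref = bdra$ref, bd_alt = bdra$alt,
    bt_ref = btra$ref, bt_alt = btra$alt,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  class(tab) <- c("bulk_variant_table", "data.frame")
  tab
}

#' Generate a substitution-mapping fixture with known answer
#'
#' Produces recombinant F2-style individuals over an ordered marker panel.
#' Each individual is built from two single-crossover-or-fewer gametes, so
#' genotypes are genetically coherent; the phenotype class follows a
#' dominant-tall model at the designated causal marker.  By construction the
#' true QTL marker is consistent with every profile, so [map_interval()]
#' must return an interval containing it.
#'
#' @param seed integer seed.
#' @param n_markers markers in the panel.
#' @param qtl_marker_index 1-based index of the causal marker.
#' @param n_recombinants number of recombinant individuals to generate.
#' @param chrom chromosome label for the panel.
#' @param start,spacing bp position of the first marker and inter-marker
#'   spacing.
#' @return list with `markers` (data frame: id, chrom, pos),
#'   `profiles` (data frame: individual, phenotype, then one column per
#'   marker with calls A/H/B), and `qtl_marker_index`.
#' @export
make_finemap_fixture <- function(seed, n_markers = 9L, qtl_marker_index = 5L,
                                 n_recombinants = 8L, chrom = "chr15",
                                 start = 1.066e8, spacing = 130000) {
  stopifnot(qtl_marker_index >= 1L, qtl_marker_index <= n_markers)
  set.seed(seed)
  pos <- as.integer(start + spacing * (seq_len(n_markers) - 1L))
  markers <- data.frame(id = sprintf("M%02d", seq_len(n_markers)),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  gamete <- function() {
    s <- sample.int(2L, 1L) - 1L
    if (runif(1) < 0.5) return(rep.int(s, n_markers))
    cut <- sample.int(n_markers - 1L, 1L)   # crossover between cut and cut+1
    c(rep.int(s, cut), rep.int(1L - s, n_markers - cut))
  }
  profs <- vector("list", n_recombinants)
  i <- 0L
  guard <- 0L
  while (i < n_recombinants) {
    guard <- guard + 1L
    if (guard > 10000L) stop("could not generate recombinants")
    g <- gamete() + gamete()
    if (length(unique(g)) < 2L) next              # must be a recombinant
    i <- i + 1L
    profs[[i]] <- g
  }
  calls <- do.call(rbind, profs)
  phen <- ifelse(calls[, qtl_marker_index] >= 1L, "tall", "dwarf")
  call_chr <- matrix(c("A", "H", "B")[calls + 1L], nrow = n_recombinants)
  colnames(call_chr) <- markers$id
  profiles <- data.frame(individual = sprintf("R%02d", seq_len(n_recombinants)),
                         phenotype = phen, call_chr,
                         stringsAsFactors = FALSE, check.names = FALSE)
  list(markers = markers, profiles = profiles,
       qtl_marker_index = as.integer(qtl_marker_index))
}

#' Generate a germplasm panel fixture with fixed haplotype-group structure
#'
#' Builds an accession panel over a small set of biallelic haplotype-tagging
#' sites.  Each group gets a distinct allele string; heights for each of two
#' years are Normal(group mean, sd^2); market class and geographic region
#' are assigned round-robin unless given explicitly.
#'
#' Default group sizes and means describe a 148-accession panel with six
#' haplotype groups spanning roughly 137-211 cm.
#'
#' @param seed integer seed.
#' @param group_sizes accessions per haplotype group.
#' @param group_means mean height (cm) per group, same length.
#' @param sd within-group height SD (cm), shared across years.
#' @param n_sites number of haplotype-defining sites (max 4^n_sites groups).
#' @param allele_strings optional explicit allele strings per group (must be
#'   distinct, each of `n_sites` characters).
#' @param classes,regions label pools recycled over accessions.
#' @param years column-name suffixes for the phenotype years.
#' @return data frame with accession, one column per site (`s1`...),
#'   `market_class`, `region`, and one `height_<year>` column per year.
#' @export
make_panel_fixture <- function(seed,
                               group_sizes = c(39L, 6L, 8L, 21L, 21L, 53L),
                               group_means = c(210.97, 155.60, 137.23,
                                               174.18, 191.06, 201.92),
                               sd = 20,
                               n_sites = 4L,
                               allele_strings = NULL,
                               classes = c("oilseed", "confection"),
                               regions = c("Asia", "Europe", "North America",
                                           "South America"),
                               years = c("2024", "2025")) {
  if (length(group_sizes) != length(group_means))
    stop("group_sizes and group_means must have the same length")
  set.seed(seed)
  k <- length(group_sizes)
  if (is.null(allele_strings)) {
    combos <- do.call(expand.grid,
                      c(rep(list(c("A", "C", "G", "T")), n_sites),
                        stringsAsFactors = FALSE))
    if (k > nrow(combos)) stop("too many groups for n_sites")
    pick <- sample.int(nrow(combos), k)
    allele_strings <- apply(combos[pick, , drop = FALSE], 1L, paste0,
                            collapse = "")
  }
  if (anyDuplicated(allele_strings))
    stop("allele strings must be distinct per group")
  if (any(nchar(allele_strings) != n_sites))
    stop("each allele string must have n_sites characters")

  n <- sum(group_sizes)
  grp <- rep(seq_len(k), group_sizes)
  alle <- do.call(rbind, strsplit(allele_strings[grp], ""))
  colnames(alle) <- paste0("s", seq_len(n_sites))
  panel <- data.frame(accession = sprintf("ACC%03d", seq_len(n)),
                      alle,
                      market_class = rep_len(classes, n),
                      region = rep_len(regions, n),
                      stringsAsFactors = FALSE)
  for (y in years)
    panel[[paste0("height_", y)]] <-
      round(rnorm(n, group_means[grp], sd), 2)
  panel
}
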