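# Substitution mapping: narrow a QTL interval by intersecting, across
# recombinant individuals, the marker positions whose genotype is
# consistent with the observed phenotype under a declared inheritance
# model.  Marker calls are coded A (dwarf-parent homozygote), H
# (heterozygote), B (tall-parent homozygote), "-" (missing).

#' Declare the single-locus inheritance model
#'
#' Maps each marker call to its predicted phenotype.  `A` always predicts
#' dwarf and `B` tall; the heterozygote prediction is the model choice
#' (default `"tall"`, i.e. tall is dominant).
#'
#' @param het_phenotype phenotype of the heterozygote: `"tall"` or
#'   `"dwarf"`.
#' @return named character vector of class `inheritance_model` mapping
#'   calls A/H/B to phenotypes.
#' @export
inheritance_model <- function(het_phenotype = c("tall", "dwarf")) {
  het_phenotype <- match.arg(het_phenotype)
  structure(c(A = "dwarf", H = het_phenotype, B = "tall"),
            class = "inheritance_model")
}

#' Marker positions consistent with one recombinant's phenotype
#'
#' Returns the 1-based marker indices at which the model's predicted
#' phenotype for the individual's call equals the observed phenotype —
#' i.e. where the QTL could reside for this individual.  Missing calls
#' (`"-"` or `NA`) are uninformative and treated as consistent.
#'
#' @param calls character vector of marker calls (A/H/B/-), in map order.
#' @param phenotype observed class, `"dwarf"` or `"tall"`.
#' @param model an [inheritance_model()].
#' @return integer vector of consistent marker indices.
#' @export
consistent_span <- function(calls, phenotype, model = inheritance_model()) {
  if (!length(calls)) stop("profile has an empty marker list")
  stopifnot(phenotype %in% c("dwarf", "tall"))
  missing <- is.na(calls) | calls == "-"
  bad <- !missing & !calls %in% names(model)
  if (any(bad))
    stop("unknown marker call(s): ", paste(unique(calls[bad]), collapse = ", "))
  pred <- unname(model[calls])
  which(missing | pred == phenotype)
}

#' Substitution-map a QTL interval from recombinant profiles
#'
#' Intersects [consistent_span()] over all profiles.  The mapped interval
#' spans the leftmost to the rightmost marker in the intersection;
#' `flank_mode = "inner"` (default) bounds it by those consistent markers,
#' `"flanking"` extends each side to the nearest excluded marker, when one
#' exists.  With zero profiles the full marker span is returned.  An empty
#' intersection yields a structured conflict result, not an error.
#'
#' @param profiles data frame with columns `individual`, `phenotype`, and
#'   one column per marker id in `markers$id` order (calls A/H/B/-).
#' @param markers data frame with `id`, `chrom`, `pos`, positions strictly
#'   increasing.
#' @param model an [inheritance_model()].
#' @param flank_mode `"inner"` or `"flanking"`.
#' @return list of class `finemap_result`: `conflict` (logical), `chrom`,
#'   `left_bp`, `right_bp`, `markers_in` (indices of the intersection),
#'   `per_profile` (named list of consistent index sets), `flank_mode`.
#' @export
map_interval <- function(profiles, markers, model = inheritance_model(),
                         flank_mode = c("inner", "flanking")) {
  flank_mode <- match.arg(flank_mode)
  if (is.unsorted(markers$pos, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  m <- nrow(markers)
  per_profile <- list()
  keep <- seq_len(m)
  if (!is.null(profiles) && nrow(profiles) > 0L) {
    miss <- setdiff(markers$id, names(profiles))
    if (length(miss))
      stop("profiles lack marker column(s): ", paste(miss, collapse = ", "))
    for (r in seq_len(nrow(profiles))) {
      calls <- as.character(unlist(profiles[r, markers$id]))
      cs <- consistent_span(calls, profiles$phenotype[r], model)
      per_profile[[profiles$individual[r]]] <- cs
      keep <- intersect(keep, cs)
    }
  }
  if (!length(keep)) {
    return(structure(list(conflict = TRUE, chrom = markers$chrom[1L],
                          left_bp = NA_real_, right_bp = NA_real_,
                          markers_in = integer(0),
                          per_profile = per_profile,
                          flank_mode = flank_mode),
                     class = "finemap_result"))
  }
  lo <- min(keep); hi <- max(keep)
  if (flank_mode == "flanking") {
    if (lo > 1L) lo <- lo - 1L
    if (hi < m) hi <- hi + 1L
  }
  structure(list(conflict = FALSE, chrom = markers$chrom[1L],
                 left_bp = markers$pos[lo], right_bp = markers$pos[hi],
                 markers_in = sort(keep), per_profile = per_profile,
                 flank_mode = flank_mode),
            class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  if (x$conflict) {
    cat("<finemap_result> no consistent placement (conflicting profiles)\n")
  } else {
    cat(sprintf("<finemap_result> %s:%s-%s (%s markers consistent, %s bounds)\n",
                x$chrom, format(x$left_bp, big.mark = ","),
                format(x$right_bp, big.mark = ","),
                length(x$markers_in), x$flank_mode))
  }
  invisible(x)
}
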