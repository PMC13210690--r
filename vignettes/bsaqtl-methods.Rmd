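---
title: "Methods: bulked segregant mapping with bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked segregant mapping with bsaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The problem

Bulked segregant analysis with whole-genome resequencing (BSA-seq /
QTL-seq) localizes major quantitative trait loci by comparing allele
frequencies between two pooled DNA samples drawn from the phenotypic
extremes of a segregating population.  `bsaqtl` implements the full desk
side of such an experiment for a biparental F2 design — here motivated by
plant height in sunflower, where a dwarf and a tall inbred are crossed,
the F2 is truncation-selected into a dwarf and a tall bulk, and both
bulks plus both parents are sequenced:

1. variant filtering and parental polarization (`apply_filters()`,
   `polarize()`);
2. three per-site association statistics and their kernel-smoothed
   tracks (`compute_bsa_stats()`);
3. quantile thresholds, candidate-region calling with a minimum-support
   rule, and cross-method consensus (`compute_threshold()`,
   `call_regions()`, `consensus_regions()`);
4. recombinant substitution mapping to narrow the locus
   (`consistent_span()`, `map_interval()`);
5. haplotype–phenotype association in a germplasm panel with Duncan's
   multiple range test, single-marker t-tests, frequency breakdowns, and
   qPCR contrasts (`define_haplotypes()`, `anova_duncan()`,
   `single_marker_test()`, `frequency_breakdown()`, `ddct()`);
6. a fully seeded synthetic data generator (`sim_config()`,
   `simulate_f2()`, `select_bulks()`, `sample_reads()`) so that every
   stage above is testable without any external data.

## The statistics

Let a site be polarized so that frequencies refer to the allele carried
by the tall parent, and let $f_L$, $f_H$ be the tall-allele read
frequencies in the dwarf (low) and tall (high) bulk.

* **ΔSNP-index.**  The SNP-index of a bulk is the fraction of its reads
  carrying the tall-parent allele; the statistic is
  $\Delta = f_H - f_L \in [-1, 1]$.  The sign depends only on which bulk
  is labelled "tall", so significance uses $|\Delta|$ after smoothing
  while the track itself stays signed.
* **G statistic.**  From the 2×2 table of (tall allele, other allele) ×
  (dwarf bulk, tall bulk) read counts,
  $G = 2\sum_i n_i \ln(n_i/\hat n_i)$ with expected counts from the
  margins and $0\ln 0 \equiv 0$.  This equals twice the log-likelihood
  ratio of independent versus pooled binomial bulk frequencies (a test in
  the suite verifies the identity against an independently coded
  binomial oracle).  Its smoothed track is written G′.
* **Euclidean distance.**  $ED = \sqrt{(f_H-f_L)^2 + ((1-f_H)-(1-f_L))^2}
  = \sqrt2\,|\Delta|$ at a biallelic site.  ED is raised to the fourth
  power *before* smoothing to sharpen peaks, giving $ED^4 \in [0, 4]$.

**Smoothing.**  All three tracks are smoothed per chromosome with a
tricube kernel, $w(d) = (1-(d/h)^3)^3$ for $|d| \le h$, evaluated at
every variant site, with half-width $h$ = half the window span
(`window_kb = 1000`, i.e. a 1-Mb window, applied identically to all
three statistics; the window is a published choice for G′ and we reuse
it for the other two).  Smoothed values are convex combinations of
in-window raw values, which the tests assert.

**Thresholds and regions.**  The cutoff for each statistic is the
empirical 0.999 quantile (linear interpolation between order statistics;
absolute values for the signed Δ track) of its genome-wide smoothed
values.  Candidate regions are maximal runs of consecutive sites at or
above the cutoff; runs separated by at most `merge_gap` bp of
sub-threshold territory are merged; only regions with at least 10
above-threshold sites survive.  Region bounds are the outermost
above-threshold site positions, 1-based and fully closed.  Consensus
annotates every region with the set of methods whose regions overlap it
by ≥ 1 bp and reports reciprocal-overlap fractions; regions are ranked
by supporting-method count.

## The synthetic world

The generator's defaults state one fixed experiment:

| parameter | default | why |
|---|---|---|
| F2 size / bulk size | 715 / 30+30 | the motivating field design |
| genome | 17 × 180 Mb | sunflower-like karyotype, ~3.06 Gb |
| sites per chromosome | 1500 (~8 /Mb) | see below |
| genetic map | 1 cM/Mb, Poisson crossovers, no interference | simplest standard model |
| QTL | chr15:107,000,000 | one major locus |
| effects | a = 60 cm, d = 30 cm, σ = 20 cm | a = 3σ, partial dominance |
| mean height | 175 cm | mid-parent scale of the motivating cross |
| depth / base error | Poisson(27) / 0.005 | ~27× pooled resequencing |

Phenotype: $\mu + a(g-1) + d\,[g{=}1] + N(0,\sigma^2)$ with $g$ the
tall-allele dose at the QTL.  Bulks are the `bulk_size` lowest and
highest phenotypes, ties broken by individual index.  Reads: per pool
and site, depth ~ Poisson(λ) and tall-allele reads ~ Binomial(depth,
$f(1-\varepsilon)+(1-f)\varepsilon$); parents are emitted as opposite
homozygotes.  The nearest simulated site on the QTL chromosome is moved
to the exact QTL coordinate so the causal polymorphism is itself
observable.

**Why ~8 sites/Mb.**  Real resequencing of this design yields thousands
of variants per Mb, which is not computable at desk scale.  The density
interacts with the fixed calling rules (0.999 quantile, 1-Mb window,
≥ 10 consecutive sites) in two opposing ways.  The smoothed null field is
correlated over roughly one window; if a window spans ≥ 10 sites, a
single noise excursion can string ten consecutive sites above the
genome-wide cutoff and the minimum-support rule stops filtering noise
(we measured null false-call rates approaching 100% at ≥ 15 sites/Mb).
Conversely the genomic width of the above-cutoff slice is
$(1-q)\times$ genome ≈ 3 Mb regardless of density, so a large genome —
not a dense one — is what makes the called region wide enough to bracket
a true QTL.  Hence: a realistic 3-Gb genome at deliberately low density.

**Region merging in replicated analyses.**  `merge_gap` defaults to 0
(no merging).  For the replicated recovery and null analyses the package
calls regions with `merge_gap` = 1 Mb, the smoothing span: a
sub-threshold gap shorter than the kernel's own scale is an artifact of
noise riding on one smoothed excursion, not evidence of two separate
loci.

**What a green test does and does not establish.**  The generator
emulates Mendelian segregation, truncation selection, and binomial read
sampling.  It does not emulate alignment artifacts, repeat-region
miscalling, overdispersed coverage, segregation distortion, or a
polygenic background beyond the Gaussian residual.  Recovery of the
simulated QTL therefore validates the statistical machinery, not the
upstream bioinformatics.

**A known limitation, reproduced faithfully.**  With a = 3σ and 4%
truncation tails, both bulks are nearly fixed across a multi-Mb linkage
plateau around the QTL.  On such a plateau the per-site G statistic is
proportional to the local read depth, so the smoothed G′ maximum is
driven by Poisson depth fluctuations and wanders 1–3 Mb.  In our
replicated world the G′ top region contains the exact causal coordinate
in ~80% of replicates (ΔSNP-index and ED: ~95%).  This mirrors the
motivating experiment itself, where the G′ method's candidate intervals
did not include the region jointly identified by the other two
statistics — one reason cross-method consensus, not any single
statistic, defines the final locus.

## Fine mapping

Substitution mapping takes ordered marker calls (A = dwarf-parent
homozygote, H, B = tall-parent homozygote, `-` = missing) and a declared
single-locus inheritance model (`inheritance_model()`, default: the
heterozygote is tall, i.e. tall is dominant — the observed phenotype of
a heterozygous recombinant in the motivating cross).  For each
recombinant, the consistent span is the set of markers whose predicted
phenotype matches the observed class (missing calls are uninformative
and treated as consistent, logged).  The mapped interval is the
intersection across recombinants; `flank_mode = "inner"` (default)
bounds it by the outermost consistent markers — matching how final
intervals are reported as marker coordinates — while `"flanking"`
extends to the nearest excluded marker on each side.  Adding a profile
can only narrow the interval; an empty intersection returns a structured
conflict result with the per-profile report rather than an error.

## Germplasm association

Haplotypes are distinct joint allele strings over a small panel of
sites; accessions with incomplete strings are excluded.  Labels
Hap1..HapK are assigned by descending overall mean height (a reporting
convention, overridable by an explicit label map).  Group means are
compared by one-way ANOVA followed by Duncan's multiple range test:
means $p$ ranks apart are tested against
$R_p = q^*(\alpha_p, p, \nu)\sqrt{MS_e/n_h}$ with protection level
$\alpha_p = 1-(1-\alpha)^{p-1}$, studentized-range quantiles from
`stats::qtukey`, and $n_h$ the harmonic mean group size; a
non-significant range protects its sub-ranges, and compact letters are
assigned so groups sharing a letter are not significantly different.
For two groups the procedure reduces exactly to Fisher's LSD, which the
tests verify.  Single-marker tests are equal-variance Student's t by
default (Welch by flag).  Frequency breakdowns round to one decimal with
the remainder absorbed by the largest cell so strata sum to exactly
100.0.  Relative expression uses 2^−ΔΔCt with technical replicates
averaged within biological replicate before any contrast and group
comparison by t-test on ΔCt; the reference-group mean maps to exactly
1.0.

## Numerical choices and edge cases

* Quantiles: R type 7 (linear interpolation); documented because
  realized cutoffs are data-dependent.
* kb/Mb interval spans: `(end - start + 1)` scaled, rounded half-up to
  two decimals.
* Coordinates: 1-based, fully closed, everywhere (BED export would
  convert to 0-based half-open).
* Filter rule order for the removal report: biallelic → qual → mq →
  parent depth → bulk depth → missing → opposite-homozygote; each
  removed site counts against the first rule it fails, so counts sum to
  rows removed.
* Parental homozygosity from read counts: minor-allele fraction ≤ 0.1
  (configurable); a site where the parents share a major allele is
  dropped as "not opposite".
* Zero-depth bulk sites are excluded from statistics with a log message
  (unreachable after depth filtering).
* Determinism: every generator op re-run with the same seed is
  byte-identical; `sample_reads()` draws from a stream at seed + 1 and
  the pipeline's toy gene annotation at seed + 2 so stage outputs do not
  depend on call order.
* Config serialization is JSON (no YAML parser among the declared
  dependencies).

## Reproducing the acceptance analyses

```{r, eval = FALSE}
# one full replicate of the default world
cfg <- sim_config(seed = 1)
truth <- select_bulks(simulate_f2(cfg))
stats <- compute_bsa_stats(polarize(apply_filters(sample_reads(truth))))
th <- compute_threshold(stats$ED4_smoothed, 0.999, "ED")
call_regions(stats, "ED4_smoothed", th, min_sites = 10, merge_gap = 1e6)
```

The full acceptance properties (statistic oracles, QTL recovery, null
control, Duncan/LSD reduction, t-test calibration) run in
`tests/testthat/test-acceptance.R`; the pipeline smoke and (empty)
numeric-target report are produced by `scripts/acceptance.R`.
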