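---
title: "Rank-based k-mer enrichment in activated chromatin regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based k-mer enrichment in activated chromatin regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankmer)
```

## The question the pipeline answers

LSD1 demethylates H3K4me1/me2 (but not H3K4me3); inhibiting it raises those
marks — and, indirectly, H3K27ac — at a limited set of genomic regions.  When
the inhibitor is conjugated to a pyrrole–imidazole polyamide that reads a
short DNA word in the minor groove (Py/Py pairs read A/T, Im/Py pairs read
G/C), the activated regions should shift toward sequences containing the
polyamide's recognition word.  `rankmer` implements the computational
analysis that tests this: which regions gain a histone mark, what kind of
regions they are, what sequence composition surrounds them, and whether the
nearest genes respond.

The analysis has four stages:

1. **Differential region calling.** Per-region coverage is the length-
   weighted mean bin value, normalized to signal-per-million of the track's
   library total.  A region is *activated* when
   `(treated + c) / (control + c) > f` with pseudocount `c = 1` and
   threshold `f = 3` ("more than 3-fold", read as strict inequality); a
   secondary threshold of 1.5 supports the weaker stratification.
2. **Chromatin-state classification.** A region is a *promoter* when its
   H3K4me3 signal is positive (above twice the genome-wide median by
   default) **and** its center lies within 2 kb of a TSS; an *enhancer*
   when H3K4me2 is positive while H3K4me3 is not; *other* otherwise.  Every
   region receives exactly one state.
3. **k-mer rank enrichment** (the core).  The ±250 bp window around each
   region center (501 bases, center included) is scanned with step 1 for
   all 4^k k-mers (k = 4 and 6 by default); k-mers touching a non-ACGT base
   are skipped.  The complete catalog — zero counts included — is ranked by
   frequency of appearance.  Degenerate classes written with IUPAC W/S
   letters (`WWCGWW`) or compositional rules (`"SSSSSS or five S and one
   W"`) are tested for crowding toward the top ("upward") or bottom
   ("downward") of that ranking with Kolmogorov–Smirnov statistics:
   one-sample against the uniform distribution of normalized ranks, or
   two-sample between two catalogs or two classes.
4. **Expression association.** Each activated region maps to the gene with
   the nearest TSS; the gene set's shift is tested with a paired two-sided
   Student's t on `log2(x + 1)` differences between conditions.

## Statistical choices

**Midranks.** Frequency ties are unavoidable in a 4096-entry catalog, so
all statistics use midranks (tied counts share the mean of the positions
they span); the rank sum is then invariantly `4^k (4^k + 1) / 2`.  The
*display* order — used for top-N listings and `best_class_rank()` — breaks
ties lexicographically instead, so it is a total order.

**KS p-values.** `D` is the sup-norm distance of the empirical CDF of the
class's normalized ranks from the uniform CDF (one-sample) or from the
second sample's ECDF (two-sample, with effective size `n1·n2/(n1+n2)`).
p-values come from the asymptotic Kolmogorov distribution and are floored
at 1e-15 for reporting — values below that are indistinguishable in
practice and are conventionally quoted as "P < 1e-15".  `direction`
compares mean normalized ranks (class vs catalog mean, or sample a vs b);
equal means give `"none"`.

**Calibration and ties.** Comparing midranks of a *discrete* count
distribution against a *continuous* uniform is only honest when counts are
deep enough that tie groups are small: if many class members share a count
they share a midrank, the ECDF jumps in lumps, and `D` inflates.  The
package's own calibration test therefore uses 1500 windows × 501 bp per
replicate (about 180 expected occurrences per 6-mer), at which depth the
p-values for a fixed 64-member class under an i.i.d. uniform genome are
uniform (checked by a KS-of-KS test over 500 replicates).  Users testing
small window sets should prefer the two-sample modes, which compare like
with like.

**Strand mode.** Polyamide binding in the minor groove is strand-agnostic,
so the default counts every window position on both strands
(`counts[x] == counts[revcomp(x)]`); a forward-only mode is retained.
Note `WWCGWW` is its own reverse-complement pattern, so its class
membership is closed under either mode.

**Paired t-test.** The expression test is paired (same genes, two
conditions) on `log2(x + 1)`; a zero-variance difference vector is
reported as degenerate with p = 1 rather than an error.

## The synthetic-data generator

Because the original deposited ChIP-seq/RNA-seq data are not required, the
package ships a generator whose defaults define its standard validation
conditions:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 200 kb | single contig `chrS` |
| `gc_fraction` | 0.5 | i.i.d. base composition |
| `n_peaks_per_class` | 5 | per composition class (GC_RICH, AT_RICH, WCGW_SEEDED, NEUTRAL) |
| `peak_fold` | 4 | H3K4me2/H3K27ac fold of planted peaks (comfortably above the 3-fold calling threshold; H3K4me3 stays at fold 1, mimicking LSD1-inhibition selectivity) |
| `flank_half_width` | 250 bp | planted-composition window half-width |
| `read_depth_scale` | 100 | baseline bin signal |
| `noise_cv` | 0.05 | coefficient of variation of baseline noise |
| `bin_size` | 25 bp | coverage resolution |

Coverage is baseline noise (normal, truncated at zero) plus, per peak, a
symmetric triangle of apex `2·baseline·(fold − 1)` and half-width 250 bp:
with that scaling the *mean* signal over the peak window is exactly
`baseline · fold` in the treated track and `baseline` in the control, so
the planted fold is what the caller should measure.  The triangular shape
makes apex recovery by `detect_peaks()` exact in the noise-free limit.
Composition planting rewrites only the window: AT_RICH/GC_RICH draw bases
with the target composition at the requested intensity; WCGW_SEEDED places
non-overlapping random `WWCGWW` instantiations (each W drawn independently,
so the *class*, not one literal 6-mer, is enriched) on a neutral background
at a density set by intensity; NEUTRAL leaves the genome untouched.
Expression tables plant a log2 effect (default 1.5 ± 0.5 noise — the
original study reports no effect-size scale, so this is a package choice)
on the genes nearest the planted peaks.

What the generator does *not* emulate: read-level sampling noise,
mappability and GC bias, replicate structure, diploid genomes, realistic
gene density, or CpG depletion (real genomes show CG at roughly 0.2-fold
of expectation; the generator's neutral background is i.i.d.).  Passing
tests therefore demonstrate the *algorithms'* correctness and calibration,
not robustness to every artifact of real ChIP-seq data.

## Worked example

```{r example}
cfg <- sim_config(seed = 1)
ds <- simulate_dataset(cfg)

trt <- ds$tracks$H3K27ac$treated
ctl <- ds$tracks$H3K27ac$control
thr <- 2 * median(ctl$values$chrS * 1e6 / ctl$library_total)
cand <- detect_peaks(trt, min_signal = thr, merge_distance = 500)
called <- call_increased_regions(trt, ctl, cand, "H3K27ac")
nrow(called)          # all 20 planted peaks exceed 3-fold

wins <- extract_windows(ds$genome,
                        data.frame(contig = called$contig,
                                   center = called$center), 250)
cat6 <- rank_catalog(count_kmers(wins, 6))
top_summary(cat6, 10)

class_rank_ks(cat6, expand_pattern("SSSSSS or five S and one W"))
best_class_rank(cat6, expand_pattern("WWCGWW"))

genes <- nearest_gene(called, data.frame(contig = ds$annotation$contig,
                                         pos = ds$annotation$tss,
                                         gene = ds$annotation$name))
expression_shift_test(unique(genes$gene), ds$expression)
```

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere (BED convention); a region
  center is `floor((start + end) / 2)`; windows include the center base,
  so a ±250 bp window is 501 bp.
* Windows crossing a contig edge are dropped with a warning, not truncated.
* Peak-apex ties go to the leftmost maximal bin.
* Zero-count k-mers stay in the catalog and ranking, tied among themselves
  after all nonzero counts.
* `quantify_signal` on an all-zero library returns 0 rather than dividing
  by zero; fold changes are protected by the pseudocount.
* Formula charges are written as repeated signs (`+`, `++`); the electron
  mass is subtracted per positive charge before dividing by |charge|, and
  results are rounded half-even to 4 decimals.

## Limitations

The region caller is deliberately simple (mean-signal fold change over
fixed candidates, no replicate-aware statistics, no input/IgG correction)
— it stands in for heavier peak callers so that the sequence-composition
analysis downstream, which is the package's point, has a well-defined and
testable contract.  The nearest-TSS gene assignment is a simplification of
regulatory-domain association rules.  The one-sample KS mode inherits the
tie caveat above; for shallow catalogs use the two-sample comparisons.
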