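---
title: "Detecting selective sweeps and linking them to traits with popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps and linking them to traits with popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

## The problem

Clonally propagated and recently domesticated crops carry the footprints of
selection as local distortions of allele-frequency structure: regions where a
derived population has lost diversity, drifted sharply away from a basal
population, or accumulated near-fixed alleles faster than neutral drift
allows. popsweep implements the standard three-statistic genome scan used to
find such regions in multi-population resequencing panels — for example a
basal, flowering-capable crop population against several derived cultivated
groups — and the follow-up analyses that connect candidate regions to a
phenotype such as bolting time.

All statistics are computed on one shared grid of fixed-length sliding
windows (500 kb sliding by 125 kb by default, tiled from position 0 of each
chromosome; only fully contained windows are emitted so all windows have
identical length). Windows with fewer than five SNPs segregating in the full
cohort are removed once, before anything is computed, so every statistic sees
exactly the same retained-window set and the evidence combination below is
well defined.

## The three scan statistics

**Windowed diversity and the π-ratio.** Per-site nucleotide diversity is the
mean pairwise difference among called chromosomes, `2c(n-c) / (n(n-1))` for
alt count `c` of `n` chromosomes; window θπ is the sum over contained sites
divided by the full window length in bp. The denominator is deliberately the
window size rather than an accessible-site count: it matches the windowed
convention of the standard VCF tooling and keeps equal-length windows
directly comparable. The diversity-ratio statistic is
`log2(θπ_baseline / θπ_focal)`; large positive values flag diversity loss in
the focal (scanned) population. A focal window with zero diversity but
positive baseline diversity yields `+Inf`, which deliberately ranks above
every finite value — total diversity loss is the strongest signal this
statistic can produce — while `0/0` yields an undefined sentinel excluded
from ranking.

**Weir–Cockerham F~ST~ and PBS.** Pairwise differentiation uses the
Weir–Cockerham (1984) variance components `a` (between populations) and
`b + c` (within), computed per site from sample sizes, allele frequencies and
observed heterozygosity, and combined per window as the ratio of sums
`Σa / Σ(a+b+c)` — the weighted windowed estimator of the standard tooling.
Sites enter a pair's estimate only when both groups have at least two called
chromosomes, so missingness never biases frequencies. Negative windowed
estimates are floored at zero and values are capped at `1 - 1e-6` so the
branch-length transform `T = -ln(1 - F_ST)` stays finite. The population
branch statistic of focal group A against B and C is
`PBS_A = (T_AB + T_AC - T_BC) / 2`, which isolates frequency change on the
focal branch and is sensitive to incomplete sweeps. The default triple is
focal = one derived group, B = the basal group, C = the pooled remaining
groups; the paper-style comparison names only the first two populations, so
the third is an explicit, configurable design choice here.

**XP-CLR.** The cross-population composite likelihood ratio models the focal
("object") population's allele frequency `q` around the baseline
("reference") frequency `p`. Neutrally, `q ~ Normal(p, ω·p(1-p))` truncated
to (0, 1), with the escaped probability mass placed as atoms on the
boundaries; the genome-wide drift scale ω is estimated once by method of
moments from `Var(q̂ - p̂)` across all SNPs, with binomial sampling noise in
both frequency estimates subtracted and a ratio-of-sums over sites for
stability. Under a sweep of strength `s` at genetic distance `r` (Morgans,
from a uniform map, 1 cM/Mb by default), each lineage escapes with
probability `c = 1 - ε^{r/s}` (ε is the starting frequency of the beneficial
allele, default 10⁻³); conditional on pre-sweep frequency `q₁`, the
post-sweep frequency is `c·q₁ + (1-c)` with probability `q₁` (the beneficial
mutation arose on the focal-allele background) and `c·q₁` otherwise. The
binomial likelihood of the observed allele count is integrated over this
distribution by fixed-order Gauss–Legendre quadrature (order 64 — beyond
this the scores change only in the eighth digit; the boundary atoms are
handled exactly and are invariant under the sweep map, so the neutral model
is recovered continuously as `s → 0`). Scores are evaluated at grid points
spaced 50 kb apart; SNPs within a 0.01-cM genetic half-width contribute
(the published setting names a "window size" without saying whether it is a
half- or full width; half-width is assumed and configurable), capped at the
100 nearest with ties broken by lower bp position. SNPs in high-LD cliques —
connected components under single linkage of pairwise genotype `r² > 0.95` —
share unit weight, so a clique of m SNPs counts once. The score is
`2(sup_s ℓ(s) - ℓ(0))` over a selection grid `{0} ∪ 10^{-4}…0.5` (12 log
points); because the grid contains the null, the score is non-negative by
construction. Per 500-kb window the score is the maximum over contained grid
points — the published analysis combines XP-CLR with the window statistics
on one outlier scale without stating the mapping, and the maximum is the
natural choice for a localized peak statistic.

## Calling sweeps

Each statistic's top 5% (of its own distribution over retained windows, per
comparison) is flagged; the flagged set is the `⌈qN⌉` largest rankable
values, with ties at a finite threshold all included. A window becomes a
candidate when at least two of the three statistics flag it. Candidate
windows are merged book-ended-inclusive — adjacent windows of the 125-kb
sliding grid overlap by construction, so merged sweeps are maximal contiguous
intervals; supporting methods are unioned. Genes overlap a sweep with ≥1 bp
of intersection (no promoter flank, strand ignored), and two groups' sweep
sets are compared by total intersected length and shared genes. Because the
top-5% rule fixes the flagged-window budget, the number and total length of
called sweeps is a property of the merge rule as much as of the data; sweep
*counts* are therefore not a quantity this package tries to match against
any external analysis.

## What the simulator emulates — and what it does not

The Balding–Nichols generator draws each SNP's ancestral frequency from a
neutral-shaped spectrum (`P(x) ∝ 1/x` over the allele count of a
200-chromosome ancestral pool), each group's frequency from
`Beta(p(1-F)/F, (1-p)(1-F)/F)` with group-specific drift `F`, and diploid
genotypes binomially. Under this model the expected Weir–Cockerham θ between
two groups of drift `F` is `F` itself and group heterozygosity is
`(1-F)·E[2p(1-p)]`, which gives the test suite exact analytic targets.
Planted sweeps are intervals where one group's drift is locally elevated to
`F_sweep` (0.95 by default against a 0.1 background, collapsing local
diversity ~18-fold); this produces the operative signal of a hard sweep —
diversity collapse and excess differentiation — with exactly known truth
intervals, without simulating selection trajectories.

The default configuration mirrors a five-group crop panel: groups of 28, 27,
46, 16 and 17 diploids with drift 0.15, 0.35, 0.40, 0.25 and 0.30 and a SNP
density of 0.0048/bp, chosen once so the basal group's θπ is ≈ 6.9 × 10⁻⁴/bp,
the derived groups fall in the 4.6–6.2 × 10⁻⁴ range, and pairwise F~ST~ spans
roughly 0.20–0.41. The carried mutation rate (2.5 × 10⁻⁹ per nt per year, one
generation per year) documents the intended time scaling but does not drive
the engine, which is parameterized by `F` directly.

What the simulator does *not* reproduce: linkage disequilibrium (sites are
exchangeable given their frequencies, so the LD-weighting path is exercised
only degenerately on real-scale data), realistic site-frequency spectra after
bottlenecks, variable recombination, or genome-scale data volumes. Passing
tests therefore demonstrate that the statistics and the caller behave
correctly under a model where truth is known — not that any particular
empirical dataset would yield a given sweep list.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so every analytic target is
estimable with useful precision: F~ST~ recovery uses 50 000 SNPs over a 30-Mb
chromosome (237 windows, mean windowed F~ST~ within ±0.02 of `F` at
`F ∈ {0.1, 0.2, 0.3}`); the caller benchmark plants ten 500-kb sweeps on a
100-Mb chromosome (797 windows, 2000 XP-CLR grid points). With the top-5%
rule flagging ~40 windows per method, ten single-window truth targets keep
recall and false-call fractions both measurable and attainable — planting
many more sweeps than the outlier budget can flag would make high recall
arithmetically impossible, which is a property of the top-fraction design,
not of the implementation. Sweep intervals are aligned to the 125-kb step so
"truth windows" are exactly the ten fully contained windows.

Other numerical conventions: all internal coordinates are 0-based half-open
(VCF positions and GFF coordinates are converted on ingest, association-locus
positions likewise, so interval arithmetic is uniform); multiallelic sites
and indels are dropped at ingest; ω is floored at 10⁻⁶; likelihoods are
floored at 10⁻³⁰⁰ before logging; the infinite π-ratio sentinel flags at most
its sort-stable share of the outlier budget (an infinite threshold does not
pull in further ties, matching the deterministic top-`⌈qN⌉` contract);
haplotypes are unphased genotype-dosage strings because resequencing-panel
genotypes are unphased and no phasing step belongs to this pipeline — the
count of distinct strings is a documented convention, not an estimate of
phased haplotype number.

## Trait linking

Candidate regions are connected to phenotypes four ways: (i) haplotype
enumeration in a region (distinct dosage strings per group, samples above a
missingness cap excluded); (ii) allele-class comparison at a designated
variant (wild-type / heterozygous / mutant by dosage) with Welch's unequal
variance t-test of each carrier class against wild-type — two-sided by
default with a one-sided option for directional hypotheses, at least three
phenotyped samples per class, raw p-values plus a Bonferroni column;
(iii) Pearson (or Spearman) correlation between a gene's expression and the
phenotype over the sample-id intersection; (iv) overlap of externally
supplied association loci with called sweeps (`pos ∈ [start, end)` in the
internal coordinates). The association scan itself, like read alignment and
variant calling, is out of scope: loci are inputs.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)                       # five-group default panel
bundle <- write_fixture_bundle(tempfile("demo"), cfg)
scan <- sweep_scan(bundle$files[["vcf"]], bundle$files[["popmap"]],
                   bundle$files[["gff"]],
                   config = scan_config(focal = "CG1", baseline = "BG"))
summary(scan)
plot(scan, chrom = "chr1")
```

## Known limitations

The scan assumes biallelic SNPs, a uniform genetic map, and window statistics
computed against full window length; it offers no haplotype-based statistics
(iHS, nSL), no Tajima's D, no soft-sweep models and no variable recombination
maps. The merge rule (book-ended-inclusive over the sliding grid) is one of
several defensible conventions and directly shapes sweep counts and lengths.
For the per-sweep diversity-loss summaries two conventions are available —
the ratio of window-mean diversities (default) and the ratio of window-summed
diversities — because published per-sweep π-ratios do not always state which
was used.
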