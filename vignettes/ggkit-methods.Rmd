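---
title: "Methods: SNP fingerprinting for germplasm collection management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP fingerprinting for germplasm collection management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggkit)
```

## The problem

Clonally propagated crop collections (the motivating case is a world olive
germplasm bank) accumulate duplicates, synonyms (one genotype under several
names), homonyms (one name on several genotypes) and somatic variants.
A panel of roughly a thousand biallelic EST-SNPs genotyped on a few hundred
accessions is enough to separate these cases, because the distribution of
pairwise multilocus differences is sharply bimodal: clonal material differs
by 0–10 alleles while distinct cultivars differ by hundreds. `ggkit`
implements the full analysis — marker QC, pairwise matching with gap-based
thresholding, redundancy grouping, per-locus diversity statistics, one-way
AMOVA with permutation $\phi_{ST}$, and bootstrapped neighbor-joining
trees — together with a synthetic cohort generator so that every stage is
testable without access to any proprietary genotype table.

## Distance, gap, and redundancy groups

For diploid genotypes the per-locus distance is the multiset allele
mismatch: $d(AA,AA)=0$, $d(AA,AB)=1$, $d(AA,BB)=2$, $d(AB,AB)=0$; for
biallelic loci this is $|g_i-g_j|$ on alt-allele dosages. Pair totals sum
over loci at which both calls are non-missing, and
`normalized_diff = n_allele_diff / (2 n_loci_compared)` is reported
alongside because the integer counts assume near-complete data. A pair with
no comparable loci has an undefined distance and never creates an edge.

`distance_histogram()` finds the duplicate threshold from the data: the
longest maximal run of empty consecutive integer distances at least
`min_gap_width` wide (default 50). The threshold is the largest observed
distance below that gap. The width guard exists because small cohorts show
accidental micro-gaps; 50 is far below the real intra/inter separation
(which spans roughly 11–199) yet far above sampling noise in the inter-pair
distribution. With no qualifying gap the threshold falls back to a
configured default (10, the conventional upper bound of somatic variation
on such panels) and the result is flagged `is_bimodal = FALSE`.

Redundancy groups are connected components (not cliques) of the
within-threshold graph: a chain of somatic variants belongs to its
cultivar's neighborhood even when the two extreme variants differ by more
than the threshold, which matches how curators treat mutant families. The
per-group maximum within distance is reported so near-redundancies remain
visible, and every edge with distance $\ge 1$ is listed as a putative
somatic variant (`near_match_edges`).

## Marker QC

The two-stage funnel mirrors standard EST-SNP panel construction.
Discovery-stage filters act on contig annotations: designability $>0.6$,
$\ge 8$ reads and $\ge 4$ ESTs in the contig, $\ge 2$ reads of the minor
allele, $\ge 50$ bp to the nearest candidate in the same contig (both
members of a closer pair are removed — a conservative choice; the source
protocol does not say which one was kept). Panel-stage filters act on
genotype data plus platform scores: GenTrain $>0.5$, call frequency
$>0.9$, call rate $>0.8$, MAF $>0.06$, heterozygote fraction $<0.8$, and
at most 22 missing calls. Wording is taken literally: "higher/lower than"
are strict, "more than 22 excluded" keeps the bound. "Heterozygosity
excess" is interpreted as the observed heterozygote fraction (the usual
platform QC statistic); "call frequency" and "call rate" are exposed as
two thresholds over the same non-missing fraction unless a separate
platform score is supplied, since only genotype data are available
downstream. Criteria whose annotation is absent are skipped with a
warning rather than failing every locus.

## Diversity statistics

All statistics are computed from observed allele frequencies among typed
samples: $H_e = 1-\sum p_i^2$, $uH_e = \frac{2n}{2n-1}H_e$,
$N_e = 1/\sum p_i^2$, $I = -\sum p_i \ln p_i$ (natural log, so the
biallelic maximum is $\ln 2 \approx 0.69$), $F = 1 - H_o/H_e$,
$PIC = 1-\sum p_i^2-\sum_{i<j}2p_i^2p_j^2$, and
$F_{null} = (H_e-H_o)/(H_e+H_o)$. The null-allele estimator is the
deterministic Chakraborty ratio rather than an iterative ML fit: the
package favors a closed-form, testable statistic and documents the
divergence. $F$ and $F_{null}$ are undefined at monomorphic loci. The
Hardy–Weinberg test is the exact conditional enumeration over heterozygote
counts of matching parity, two-sided by summing configurations no more
probable than the observed one. The multi-allelic code path accepts
`"a/b"` call matrices so SSR-style panels can be summarized side by side
with SNPs (`compare_marker_sets()`); no rarefaction correction is applied.

## AMOVA

`amova_one_way()` decomposes squared pairwise distances:
$SS_{tot}=\sum_{i<j}d^2_{ij}/N$, $SS_w=\sum_g\sum_{i<j\in g}d^2_{ij}/n_g$,
variance components via $n_0=(N-\sum n_g^2/N)/(K-1)$ with the among
component floored at zero, and
$\phi_{ST}=\sigma^2_a/(\sigma^2_a+\sigma^2_w)$. The raw allele-difference
counts are squared here; the distance entering the published analysis'
software is not stated, so the package fixes and documents its own metric.
Significance uses random relabeling with the $+1$ correction (the p-value
can never be 0). The permutation loop is vectorized — one indicator-matrix
product per group evaluates all permutations — which is what keeps the
1000-dataset null calibration in the test suite under a minute.

## Neighbor joining

`nj_build()` is the Saitou–Nei algorithm with the Studier–Keppler
$Q$-criterion. Two numerical choices are fixed for reproducibility: ties in
the $Q$ minimization break by the smallest (i, j) pair in creation order,
and negative branch lengths are clamped to zero with the total deficit
recorded as an attribute. On additive input the generating topology and
branch lengths are recovered exactly (tested against trees drawn at
random, with `ape` as the independent oracle). Bootstrap supports resample
loci with replacement; distances default to normalized proportions so
replicates with missing data remain comparable, and a replicate in which
some pair shares no typed locus is discarded and counted. Supports are
integer percentages attached as internal-node labels. Newick export quotes
labels containing reserved characters (the stock `ape` writer substitutes
underscores instead, which breaks round-tripping of accession names like
"Frantoio A. Corsini").

## The synthetic cohort: what it states and what it does not

The generator is a stated world, not a tuning surface. Defaults emulate
the motivating collection: 1,043 biallelic loci with founder MAF uniform
on [0.06, 0.50] (the panel's ascertainment floor; uniform because the true
frequency spectrum of the panel is unknown and the printed MAF spread is
reproduced without further assumptions); 325 cultivated samples built from
216 founders as 59 clone groups totalling 164 samples (sizes
7 + 41×3 + 17×2, the largest mirroring the biggest published redundancy
group), 157 singletons, and 4 somatic variants at k = 1, 2, 9, 10 allele
flips (the span actually observed between variant pairs); 89 wild
genotypes drawn from Balding–Nichols frequencies at differentiation 0.39
(an emulation choice — the source reports only a significant $\phi_{ST}$
with 61% within-group variance, not the parameter itself); 15 F1 progeny
of two founders; 1% missing calls. Somatic variants flip exactly one
allele per chosen locus (hom→het or het→hom), the natural model for point
somatic mutation on a biallelic panel.

The clone-recovery acceptance world uses clone groups 7/3/2/2 and ten
variants at k = 1..10, with k = 9 and k = 10 placed on the large group.
Multi-variant cultivars are a documented real pattern, and they matter
numerically: under 1% missingness a *single* k = 10 pair retains all ten
discriminating loci with probability $0.99^{20}\approx 0.82$, so a world
whose intra-side maximum rests on one pair cannot keep the detected
threshold at or above 10 in 99 of 100 runs; the variant pair on the large
group (≈19 differing loci) makes the intra-side maximum robust. This
analysis was done before the criterion was ever measured.

What the generator does not emulate: linkage between loci (all loci
independent), genotyping error, population structure within the cultivated
pool, ascertainment-induced frequency distortion in the wilds beyond the
Balding–Nichols pull, and platform score distributions (GenTrain and
designability are annotations, never recomputed). A green test therefore
establishes algorithmic correctness and calibration under the stated
world, not concordance with any real collection's group inventory — the
published counts of 59 groups, 164 redundant samples and 156 unique
genotypes are not reproducible without the study's genotypes and are never
asserted.

## Numerical and interface choices

* Genotypes are stored as alt-allele dosages 0/1/2 with a missing
  sentinel; heterozygote order is normalized at parse time, and the ref
  allele of a parsed table is the alphabetically first observed allele (a
  deterministic convention only).
* Coordinates are 1-based inclusive; VCF positions are used as-is. Only
  biallelic diploid VCF records import; multi-allelic and non-diploid
  records are skipped and counted.
* All randomness derives from a single seed through fixed per-purpose
  streams, so cultivar, wild, progeny and missingness draws are
  independently reproducible; RNG state is restored after each draw.
* Report files are byte-deterministic (fixed column order, sorted rows);
  the run manifest records seed, dimensions and md5 digests.
* Config files are JSON or flat `key = value` text (YAML is not among the
  declared dependencies of this build).
* The exact HWE p-value comparison uses a $(1+10^{-12})$ slack on "no more
  probable than observed" to absorb floating-point ties.

## Known limitations

No hierarchical AMOVA, no LD or rarefaction statistics, no parentage
inference, no tree visualization. The CLI is a thin wrapper over the
exported functions; heavy use should go through R. For cohorts much beyond
a thousand samples the $O(N^2 L)$ distance computation and $O(N^3)$ NJ
per bootstrap replicate dominate; loci-thinned bootstraps or subsetting to
unique genotypes (as the pipeline does) are the intended mitigations.
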