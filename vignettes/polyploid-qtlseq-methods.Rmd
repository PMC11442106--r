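---
title: "Polyploid QTL-seq with polyBSA: model, design choices and validation"
author: "polyBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyploid QTL-seq with polyBSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulked segregant analysis (BSA) maps quantitative trait loci by sequencing
two pools of phenotype-extreme progeny and looking for allele-frequency skews
between them. In an autohexaploid F1 cross (sweetpotato being the motivating
crop) the workhorse markers are *simplex* variants: alleles carried on
exactly one of the donor parent's six homologous chromosomes while the other
parent is *nulliplex* (devoid of the allele). Such variants segregate 1:1
among the progeny, so

* the donor parent's SNP-index (fraction of reads carrying the allele) is
  about 1/6 = 0.167,
* an unselected progeny bulk has an expected SNP-index of 1/12, about 0.083,
* a bulk perfectly enriched for carriers reaches 1/6, and one purged of
  carriers reaches 0, so the delta SNP-index (high-trait bulk minus
  low-trait bulk) ranges over ±0.167 at a fully penetrant QTL.

polyBSA implements the statistical core of this analysis: plexity
classification of parental variants, per-bulk SNP-index and delta SNP-index
statistics with simulation-based null thresholds and P values, a sliding
window genome scan with directional QTL-variant counts, two-criterion QTL
region calling, marker nomination, and a synthetic cross simulator used to
validate all of it end to end.

## Segregation model

Polysomic inheritance is modelled by random bivalent pairing: a gamete
receives `ploidy/2` of the parent's `ploidy` homologs, drawn uniformly
without replacement, so the gamete dose of an allele present on `m` homologs
is hypergeometric. For ploidy 6 this gives dose distributions
{1/2, 1/2} (simplex), {0.2, 0.6, 0.2} (duplex) and
{1/20, 9/20, 9/20, 1/20} (triplex); crossing to a nulliplex parent leaves
these unchanged as progeny dose distributions (`gameteDosePmf()`,
`progenyDosePmf()`). Double reduction and preferential pairing are not
modelled.

Under the no-QTL null, each bulk member's dose is an independent draw from
the progeny dose distribution. A bulk of `n` members has allele frequency
`S / (ploidy * n)` with `S` the dose sum, and the observed SNP-index adds a
binomial read-sampling layer at the bulk's depth. `simulateNull()` samples
`S` directly from the exact n-fold convolution of the dose distribution —
distributionally identical to summing per-member draws, but much faster —
then draws binomial reads, and records empirical 95% and 99% thresholds
(2.5/97.5 and 0.5/99.5 percentiles, `quantile()` type 7) of the delta
SNP-index. The independent test oracle, `exactBulkIndexPmf()`, instead
enumerates all `(plexity+1)^n` dose compositions and mixes exact binomial
read distributions, so simulation and oracle share no code path.

P values are empirical and two-sided:
`p = (1 + #{|delta_null| >= |delta|}) / (replicates + 1)`, which is never
zero, and `-log10(p)` is finite by construction. Null distributions are
cached per exact (low-depth, high-depth) pair; each pair's RNG stream is
derived deterministically from the global seed, so results are independent
of variant order and bit-reproducible.

## Plexity classification

A variant is assigned to a donor parent at plexity k when the donor's
allele-read fraction falls inside the plexity window ([0.08, 0.25],
[0.22, 0.45], [0.38, 0.62] for k = 1, 2, 3) and the other parent shows at
most `maxOtherAltReads` (default 0) alternate reads — the strictest reading
of "nulliplex", and the property an allele-specific PCR marker needs. A run
classifies at one plexity; the windows deliberately overlap, so duplex and
triplex calls are not perfectly separable at moderate depth. Sites accepted
in both donor orientations are ambiguous and discarded from both. Fractions
are raw depth ratios; no smoothing.

## Genome scan and region calling

Windows of 100 kb advance in 20 kb steps, anchored at position 1 of each
chromosome (1-based inclusive; the final window is clipped). Per window the
scan reports unweighted means of the bulk indexes, delta and -log10 P, the
directional QTL-variant counts (variants beyond the 95%/99% thresholds,
split by delta sign) and per-bulk zero-index counts.

Candidate regions must satisfy two criteria:

1. **Directional count.** The QTL-variant count exceeds `countThreshold`
   (default 20) in one direction of QTL effect over at least 2 Mb, but not
   in the other direction. Three operationalisations are available.
   `strict` requires every window of a run to exceed the threshold and
   vetoes a run containing any opposite-direction excess window. `lenient`
   merges runs across short gaps while at least `minFrac` (default 0.8) of
   windows qualify. `region` applies the one-directionality requirement at
   region scale: a candidate interval is vetoed only when the opposite
   direction itself sustains a qualifying 2 Mb cluster overlapping it. The
   region mode exists because of a genuinely polysomic phenomenon: progeny
   selected for a donor homolog carry only 2 of its 5 sister homologs per
   gamete instead of 2.5, so variants on sister homologs are pushed to
   *negative* delta right at a strong QTL (expected shift −(1/6)·(1/5) ≈
   −0.033). With dense variants, isolated opposite-direction windows are
   therefore expected exactly where the signal peaks, and window-scale
   vetoes mask the QTL itself.
2. **Zero cluster.** Zero-SNP-index variants cluster over at least 2 Mb in
   one bulk but not the other. A window qualifies when its zero count is at
   least `zeroMin` (default 10) and at least `dominanceRatio` (default 5)
   times the other bulk's; runs merge across short gaps under the same
   `minFrac` rule, because window-level zero counts are Poisson-noisy.

A region is called where a direction-d count interval overlaps a
polarity-consistent zero interval (trait-increasing donor allele ⇒ zeros
cluster in the low bulk, and vice versa); bounds are the intersection,
overlapping calls merge, and the peak window maximises |mean delta|. Marker
candidates inside a region need one bulk index within `zeroTol` (0.02) of 0
and the other within `simplexTol` (0.05) of plexity/ploidy, polarity
consistent with the region, ranked by total bulk depth then |delta|.

## The simulator

`simulateBsaCross()` generates parental variant panels (Poisson counts at
`variantDensity`, uniform positions, configurable donor and plexity mix,
marked homologs drawn uniformly), per-progeny meioses, additive QTL
phenotypes with Gaussian noise, extreme-phenotype bulks (lowest
`bulkLowN` / highest `bulkHighN` ranks off one stable ordering, so bulks are
disjoint even under fully tied phenotypes), and read counts: per-sample
total depth Poisson(`depthMean`) floored at 1, alternate reads binomial at
the true allele fraction. Output is an in-memory `BsaVariantSet` plus truth
tables, or a VCF v4.2 with AD fields via `writeCrossVcf()`.

Two transmission modes are provided. Without recombination, whole homologs
are transmitted (3-of-6 subsets), which maximises linkage signal but makes
every variant on a homolog share one bulk-composition draw — fine for
truth-table clarity, useless for genome-wide calibration because the whole
chromosome is a single pseudo-linkage block. With `recombination = TRUE`,
homologs pair into random bivalents per meiosis and the transmitted
chromatid switches homolog at Poisson crossover points (`cmPerMb`, default
3 cM/Mb, a typical plant rate; Haldane map). The bivalent model reproduces
the hypergeometric gamete-dose law exactly (e.g. {0.2, 0.6, 0.2} for
duplex). What the simulator does not emulate: preferential pairing, double
reduction, epistasis and dominance, sequencing error and mapping artefacts,
non-uniform variant density, and real genetic maps — so passing tests
demonstrate the statistical machinery, not robustness to those features of
real data.

## Validation studies and their problem sizes

The test suite validates the pipeline at these scales, chosen to keep each
study informative at desk scale:

* **Null-engine oracle:** simulated bulk-index distributions match the
  enumeration oracle within Kolmogorov distance 0.01 at 1e5 replicates for
  bulks of 2–3 members and depths 3–5.
* **Type-I calibration:** a no-QTL genome of 15 chromosomes × 10 Mb at one
  variant per 10 kb (about 15,000 scored variants), 126 progeny, bulks of 10
  and 21, depth 100, recombination on. Recombination matters here: it
  decorrelates loci so the genome-wide sig95 rate concentrates near 0.05.
  Measured rate: 0.050.
* **Parameter recovery:** one fully penetrant simplex QTL mid-way on a 30 Mb
  chromosome, 126 progeny, bulks 10/21, depth 100, all-simplex variants at
  one per 100 bp — the density at which the count criterion's threshold of
  20 per 100 kb window is comfortably exceeded by the roughly one sixth of
  donor variants that ride the QTL homolog, after discounting the ~0.7
  probability that a linked variant clears the 99% threshold at depth 100
  (hexaploid cultivar crosses are of this order of density). The analysis
  runs at confidence level 99, count mode `region`, `zeroMin = 5` and
  `dominanceRatio = 3`: at this density a single recombinant low-bulk member
  suppresses the expected window zero count to about 53·e^(−100/60) ≈ 10,
  exactly the default `zeroMin`, and the opposite-bulk zero count is
  Poisson with mean about 1, making a 5-fold dominance test unstable —
  hence the study values. Recovery: 9/10 seeds call a region containing the
  planted position; no-QTL genomes called 0 regions in 20/20 seeds under
  the same analysis settings.

## Numerical and interface choices

Coordinates are 1-based inclusive throughout (VCF convention). Depth comes
from the AD genotype field, with an RO/AO fallback; sites lacking both are
skipped with a warning and missing per-sample depth becomes (0, 0), which
the minimum-depth filter then removes. The minimum depth (default 50)
applies to all four samples — conservative where the original description
is silent on whether parents are included. Multiallelic sites are dropped by
default (simplex logic assumes one segregating alternate allele); splitting
is available. Upstream mapping-quality settings (`min_mq`, `adjust_mq`) are
recorded in run metadata for provenance only — they act at pileup time,
before any VCF exists. Empirical thresholds use `quantile()` type 7;
replicate count (default 10,000) and percentile convention are exposed in
configuration because published pipelines rarely state them. Run metadata
(all parameters, seed, package version) suffices to reproduce a run
byte-for-byte.

## Known limitations

Classification operates on raw parental fractions, so very deep or very
shallow parents shift the effective plexity windows. The null model treats
variants independently; linkage makes neighbouring tests correlated, which
the window criteria absorb but the per-variant P values ignore. The
two-criterion caller assumes dense variant panels; at sparse densities the
count criterion cannot reach 20 per window and regions will not be called
regardless of signal strength. Region bounds are unions of window bounds —
no sub-window precision is claimed.
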