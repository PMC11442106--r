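# polyBSA

Bulked segregant analysis (QTL-seq) for **autopolyploid F1 crosses**, built
for breeders and geneticists working on hexaploid crops such as sweetpotato,
where classical biparental mapping is defeated by polysomic inheritance.

Two pools of phenotype-extreme F1 progeny and the two parents are sequenced.
The informative markers are **simplex** variants — alleles on exactly one of
the donor parent's six homologs, absent (**nulliplex**) from the other
parent — which segregate 1:1 in the progeny. For each variant the package
computes the per-bulk **SNP-index** (fraction of reads carrying the allele)
and the **ΔSNP-index**,

```
SNP-index  = alt reads / total reads                (donor parent ≈ 1/6 ≈ 0.167)
ΔSNP-index = index(high bulk) − index(low bulk)     (null expectation 0)
```

Away from any QTL both bulks sit near the null expectation 1/12 ≈ 0.083. A
QTL drags one bulk toward 0.167 and the other toward 0, so Δ approaches
±0.167. Significance comes from a plexity-adapted null simulation: member
doses are drawn from the hypergeometric gamete-dose law of polysomic
inheritance (for a simplex parent, carriers segregate 1:1), bulk allele
frequencies get a binomial read-sampling layer at the observed depth, and
empirical 95%/99% thresholds and P values are read off the simulated
ΔSNP-index distribution. A 100-kb / 20-kb sliding-window scan counts
threshold-exceeding variants by direction of effect, and QTL regions are
called where (1) that count exceeds 20 over ≥ 2 Mb in one direction only and
(2) zero-SNP-index variants cluster over ≥ 2 Mb in exactly one bulk. Inside
called regions the package nominates allele-specific marker SNPs
(one bulk ≈ 0, the other ≈ 0.167). Duplex and triplex variants are handled
by the same machinery via the `nPlex` setting.

A built-in simulator (`simulateBsaCross()`) generates complete synthetic
hexaploid crosses — parental variant panels, bivalent-pairing meioses with
optional crossovers, additive QTL phenotypes, extreme-phenotype bulks,
binomial read counts — so the whole pipeline is testable without sequencing
data.

## Worked example

Simulate a cross with one trait-increasing QTL at 4 Mb on an 8 Mb
chromosome (126 progeny, bulks of 10 and 21, mean depth 100), then run the
analysis:

```r
library(polyBSA)

cfg <- crossConfig(
  chromLengths = c(chr1 = 8e6),
  variantDensity = 1 / 100, plexityMix = c(1, 0, 0),
  nProgeny = 126, bulkLowN = 10, bulkHighN = 21, depthMean = 100,
  qtls = data.frame(chrom = "chr1", pos = 4e6, donor = "P1", effect = 10),
  recombination = TRUE, seed = 42)
sim <- simulateBsaCross(cfg)

sets   <- classifyAllVariants(filterVariants(sim$variantSet))
scored <- scoreVariants(sets$P1, nLow = 10, nHigh = 21, seed = 1)
windows <- slidingWindowScan(scored, c(chr1 = 8e6))
regions <- callQtlRegions(
  callCountCriterion(windows, level = "99", mode = "region"),
  callZeroClusterCriterion(windows, zeroMin = 5, dominanceRatio = 3),
  windows)
regions[, c("chrom", "start", "end", "direction", "zero_cluster_bulk",
            "peak_window_start")]
#>   chrom start   end direction zero_cluster_bulk peak_window_start
#> 1  chr1     1 8e+06        up               low           4600001

head(selectMarkerCandidates(scored, regions[1, ]), 3)
#>   chrom     pos ref alt idx_low  idx_high     delta rank
#> 1  chr1 6145600   G   T       0 0.1603053 0.1603053    1
#> 2  chr1 5654055   C   T       0 0.1450382 0.1450382    2
#> 3  chr1 2734786   C   G       0 0.1417323 0.1417323    3
```

One region is called, in the **up** direction (the donor allele increases
the trait) with the zero cluster in the **low** bulk, as expected for a
trait-increasing donor allele; the peak window sits near the planted QTL.
(The region spans the whole chromosome because an 8 Mb chromosome at
3 cM/Mb is only ~0.24 Morgans, so selection at the QTL skews allele
frequencies everywhere on it.) The nominated markers have one bulk index at
exactly 0 and the other near the simplex expectation 0.167 — sites suitable
for allele-specific PCR genotyping.

The same analysis runs from the shell over a VCF + YAML configuration:

```sh
polybsa simulate -c config.yaml          # write a synthetic VCF + truth tables
polybsa run      -c config.yaml          # full pipeline, both parent orientations
polybsa plot     -c config.yaml --chrom chr1
```

`runPipeline()` writes per-orientation `scored.tsv`, `windows.tsv`,
`regions.tsv`, `markers.tsv` and `run_metadata.json`; the six-panel
per-chromosome plot mirrors the standard QTL-seq figure layout (per-bulk
SNP-index, superimposed window means, ΔSNP-index with thresholds, window
−log10 P, directional QTL-variant counts).

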