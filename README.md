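# magcentric

Genome-centric analysis of metagenome-assembled genome (MAG) communities,
built for engineered anaerobic-digestion (biogas) microbiomes and applicable
to any shotgun-metagenomics study that works at the level of genome bins.

After assembly and binning, a genome-centric study faces a fixed sequence of
questions: which bins are good enough to interpret; which bins are the same
species; how abundant is each species in each sample; what can each species
do metabolically; which species are actively replicating; and how do
communities differ across process conditions. `magcentric` implements that
whole chain as composable, tested R functions, together with a seeded
synthetic-community generator that plants a known ground truth for every
stage — so the pipeline can be validated end-to-end without terabases of
external reads.

## What it computes

* **Quality tiering** — the composite score `CC3 = Cp − 3·Ct` from CheckM
  completeness (Cp) and contamination (Ct), and nested quality tiers
  (HQ: Cp > 90, Ct < 5; MHQ: Cp ≥ 70, Ct ≤ 10; MQ: Cp ≥ 50; LQ below;
  CONTAMINATED: Ct > 10).
* **Species dereplication** — bottom-s MinHash sketches of canonical k-mers
  with the Mash distance `d = −(1/k)·ln(2j/(1+j))` as a permissive
  pre-filter (d ≤ 0.05), then fragment-based average nucleotide identity
  (1020-bp fragments, best gap-free placement, identity over the aligned
  overlap). Two MAGs join a species when ANI > 95 % with ≥ 50 % of fragments
  aligned in at least one direction; species are the connected components,
  represented by their highest-CC3 member.
* **Abundance profiling** — column-normalised relative abundances (% per
  sample), strict presence calls at 0.001 %, 1-million-read subsampling
  consistency checks, shared-MAG (presence Jaccard) fractions,
  Bacteria/Archaea ratios, abundant (>1 %) × widespread (>10 % of samples)
  classification, taxon aggregation, and Pearson/UPGMA profile clustering.
* **KEGG-module completeness** — a parser for module DEFINITION expressions
  (blocks, OR alternatives, `+` complexes, `−` optional parts), a
  blocks-missing evaluator with the complete / 1 bm / 2 bm / incomplete
  categories, core (>90 %) / soft-core / shell (<10 %) module prevalence over
  HQ–MHQ MAGs, multifunctional (>180 modules) / oligofunctional (<80)
  MAG breadth, per-sample module abundance, and the
  acetoclastic : hydrogenotrophic methanogenesis ratio with its regression
  against ammonia (TAN).
* **CAZyme enrichment** — upper-tail hypergeometric tests of CAZy-class
  counts per MAG against the pooled background, Benjamini–Hochberg q-values,
  significance at p < 1e−5.
* **Replication index (iRep)** — admission filters (Cp > 90, Ct < 5,
  < 175 scaffolds/Mbp, coverage > 5, single replication origin for archaea),
  then sorted log2 window-coverage regression on genome fraction;
  `iRep = 2^slope`. Pairwise Wilcoxon tests with Bonferroni correction
  compare taxa or guilds.
* **Community ecology** — Dominance, Simpson, Shannon H, evenness, Fisher's
  alpha, Berger–Parker and Chao-1; Whittaker and Bray–Curtis
  dissimilarities; UPGMA sample trees; principal coordinates analysis;
  Mann–Whitney/Bonferroni and Welch t-tests for group contrasts.

## Worked example

```r
library(magcentric)

# two planted species, three genomes each
mags <- generateGenomes(nSpecies = 2, genomesPerSpecies = 3,
                        genomeLength = 50000, seed = 101)
mags
#> MagSet with 6 MAGs
#>   genome size: 50000 - 50000 bp
#>   planted species: 2

clusterSpecies(mags)$clusters
#>   cluster_id   mag_id is_representative
#> 1      SC001 SP01_G01              TRUE
#> 2      SC001 SP01_G02             FALSE
#> 3      SC001 SP01_G03             FALSE
#> 4      SC002 SP02_G01              TRUE
#> 5      SC002 SP02_G02             FALSE
#> 6      SC002 SP02_G03             FALSE

g <- genomeSeqs(mags)
r <- aniPair(g[["SP01_G03"]], g[["SP01_G01"]])   # planted 2% divergence
sprintf("ANI %.2f%%, aligned fraction %.1f%%", r$ani, r$aligned_fraction)
#> "ANI 98.10%, aligned fraction 100.0%"

# replication gradient: origin/terminus coverage ratio 2 planted
depth <- generateWindowCoverage("SP01_G01", 2e6, meanDepth = 30,
                                oriTerRatio = 2, noiseSd = 0.05, seed = 5)
estimateIrep(depth)
#>   n_windows n_zero_windows    slope        r2     irep fit_ok
#> 1       360              0 1.021374 0.9988479 2.029851   TRUE

# module completeness: third block's KO missing -> one block missing
m <- parseDefinition("M00357", "K00925 (K00625,K13788) K01895")
blocksMissing(m, c("K00925", "K13788"))
#>   mag_id module_id blocks_total blocks_missing category
#> 1   <NA>    M00357            3              1      1bm
```

The cluster table shows the two planted species recovered exactly, with the
highest-quality genome of each cluster chosen as representative. The ANI
call recovers the planted 2 % substitution rate (expected 98 %), and the
iRep estimate recovers the planted origin:terminus ratio of 2 from noisy
window coverage. `runPipeline()` chains all stages over a directory of
FASTA/TSV inputs described by a YAML config and writes one TSV per result
plus a JSON manifest; `makeSyntheticScenario()` writes a complete input
bundle with truth tables.

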