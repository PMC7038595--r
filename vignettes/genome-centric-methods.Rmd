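---
title: "Methods: genome-centric MAG community analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-centric MAG community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcentric)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, what the synthetic-community
generators emulate (and what they deliberately do not), and the design
choices made where the methodology was genuinely open.

## Quality scoring and tiering

MAG quality is summarised by completeness `Cp` and contamination `Ct`
estimated upstream from single-copy marker genes (CheckM or equivalent —
estimating them is out of scope here; they are consumed as a table). The
composite score is `CC3 = Cp − 3·Ct`: contamination is weighted three-fold
because foreign sequence corrupts downstream functional and replication
inference more than missing sequence does. Tiers are evaluated as nested
thresholds so the tier function is total on `[0,100] × [0,∞)`:
contaminated (`Ct > 10`) first, then HQ (`Cp > 90` and `Ct < 5`, both
strict), then MHQ (`Cp ≥ 70`, `Ct ≤ 10`), then MQ (`Cp ≥ 50`), else LQ. A
literal reading of the MHQ band as an open interval `5 < Ct < 10` would
leave e.g. `Cp = 80, Ct = 2` unclassified; the nested reading keeps every
MAG classified exactly once and preserves monotonicity (raising `Cp` never
demotes, raising `Ct` never promotes — both property-tested). Boundary
convention: `Ct = 10` is still MHQ; contamination must strictly exceed 10
to disqualify.

## Species-level dereplication

Dereplication is a two-stage procedure: a cheap MinHash pre-filter
nominates candidate pairs, and fragment ANI decides species membership.

**Sketches.** Bottom-`s` MinHash (default `s = 1000`) over canonical
`k = 21`-mers. Canonical means the lexicographic minimum of a k-mer and its
reverse complement, so a genome and its reverse complement sketch
identically. The hash is a fixed 64-bit mixer (splitmix64 finaliser) with a
constant seed, truncated to 53 bits so values are exact in doubles —
sketches are bit-reproducible across machines. The Mash distance is
`d = −(1/k)·ln(2j/(1+j))` with `j` the shared fraction of the merged
bottom-`s` sketch, and `d = 1` when nothing is shared. At small divergence
`d` approximates per-base divergence, so the pre-filter cutoff of 0.05
corresponds loosely to the 95 % ANI species boundary; it is deliberately
permissive, and the package can bypass it (`usePrefilter = FALSE`) to
brute-force all pairs — the test suite verifies both paths give identical
partitions.

**Fragment ANI.** The query is cut into non-overlapping 1020-bp fragments
(trailing partials dropped). Each fragment is placed by exact 16-mer seed
voting (stride 4, both strands) onto its best target diagonal and scored by
gap-free identity. Identity is computed over the aligned overlap, and a
placement must cover ≥ 70 % of the fragment: fragments that straddle a
scaffold end are either scored on their overlap or dropped as no-hits,
never charged the clipped bases as mismatches. This choice matters in
practice — with identity computed over the full fragment length, fragmented
assemblies (contigs of a few kb) systematically depress ANI by several
tenths of a percent, enough to flip borderline pairs at the 95 % boundary.
Gap-free extension is sufficient because the package's validation data are
substitution-only; on real genomes with indels the fragment identities are
conservative.

**Species rule and clusters.** A pair is joined when at least one direction
shows ANI strictly above 95 % with aligned fraction ≥ 50 %; requiring only
one direction resolves the ambiguity of demanding coverage "for both
strains" while accepting either comparison. Clusters are connected
components (single linkage), since only cluster membership, not a linkage
criterion, is defined by the species concept used. Representatives maximise
CC3, with ties broken by genome size then lexicographic id — a
deterministic stand-in for manual curation.

## Abundance and presence

Relative abundance is the column-normalised (per-sample) percentage of
read counts or depth×length mass assigned to each MAG; computing the counts
themselves (read mapping) is upstream and out of scope. Presence is a
strict call at 0.001 % — chosen because abundance estimates from millions
of reads remain reproducible down to that level: the package's subsampling
check draws 1 M reads (multinomial) from a full sample and requires
Pearson r > 0.999 between full and subsampled abundances over present MAGs,
which the synthetic 5-M-read community reproduces. The shared-MAG fraction
between two samples is the Jaccard index of their presence sets — the
intersection-over-union convention is stated explicitly because "shared
fraction" admits several readings (e.g. intersection over the smaller set);
Jaccard is symmetric and bounded, and equals 1 exactly on identical
presence vectors. MAGs are classified abundant when their maximum abundance
exceeds 1 % anywhere, and widespread when present in more than 10 % of
samples. Profile clustering uses `1 − Pearson r` distance with UPGMA
linkage, with rows sorted lexicographically first so tie-breaking is
deterministic.

## KEGG module completeness

Module DEFINITION strings are parsed with the conventional grammar:
top-level space-separated units are serial reaction *blocks*; within an
expression, commas are alternatives (lowest precedence), spaces are
conjunctions, `+` joins subunits of a complex (all required), and `−` marks
optional components. Optional components — whether single KOs or
parenthesised groups — never affect satisfaction. A block is satisfied when
its expression tree evaluates true against the MAG's KO set; the record
counts unsatisfied blocks, with categories complete (0), "1 bm" (1),
"2 bm" (2) and incomplete (≥ 3). The evaluator is verified against an
independent oracle that evaluates the raw definition text through R's own
parser, exhaustively over all KO subsets of every bundled module (≤ 1024
subsets each).

KO hits entering the evaluator are filtered at e-value ≤ 1e−5, bit score
≥ 50 and identity ≥ 25 — the usual thresholds for alignment-based KO
transfer. Module *prevalence* over HQ–MHQ MAGs counts a module present when
it is complete **or** 1 bm (the working convention for downstream
statements; a flag restricts to complete-only), with classes core
(> 90 %), soft-core (10–90 %) and shell (< 10 %). MAG functional breadth
uses the same present rule: more than 180 encoded modules is
multifunctional, fewer than 80 oligofunctional. One consequence worth
noting: a single-block module absent from a MAG is "1 bm" by arithmetic
and therefore counts as present under the complete+1bm rule; the bundled
synthetic scenario therefore plants its prevalence classes only on
multi-block modules, and the complete-only flag sidesteps the artefact
entirely.

Per-sample module abundance sums the relative abundances of qualifying
(HQ–MHQ, complete or 1 bm) MAGs; the acetoclastic : hydrogenotrophic ratio
divides two module rows, with 0/0 and x/0 reported as an undefined
sentinel (NA). Its association with ammonia is an ordinary least-squares
regression reporting R² and the two-sided slope p; pairs with missing
metadata are dropped and counted.

## CAZyme enrichment

Each (MAG, CAZy class) pair with at least one class gene is tested for
over-representation with the upper-tail hypergeometric probability
P(X ≥ k) for X ~ Hypergeometric(N, K, n), where the urn is the pooled set
of all genes across the retained (HQ–MHQ) MAGs. The pooled-background
choice is documented and configurable (the alternative — per-sample urns —
would entangle enrichment with abundance). The tail is computed through the
log-space-stable distribution function and verified against exhaustive
enumeration for N ≤ 30. Benjamini–Hochberg q-values are reported for all
tests, but the primary significance rule is the raw threshold p < 1e−5 —
deliberately conservative, and shown by simulation (200 null communities)
to produce zero false calls in ≥ 99 % of runs.

## Replication index

Bidirectional replication from a single origin makes sequencing coverage
decline from origin to terminus; the ratio of origin to terminus coverage
measures the population-average number of active forks. The estimator:
per-window depths (5-kb non-overlapping windows by default) are smoothed
with a circular moving average over 5 adjacent windows in genome order,
log2-transformed, sorted ascending, trimmed 5 % at each tail, and regressed
on cumulative genome fraction over the *untrimmed* scale (trimming must not
shrink the fitted gradient); `iRep = 2^slope`. Sorting makes the estimate
invariant to genome rotation (the origin need not be located) and to the
row order of the depth table; the smoothing mirrors the averaging that
overlapping sliding windows perform in the reference formulation of the
method and suppresses the upward bias that independent per-window noise
otherwise imposes on non-replicating genomes (sorted pure noise is almost
linear in quantile, worth ≈ 2^(3.4·σ) of spurious signal — about 1.11 at
σ = 0.05 unsmoothed). Exactly constant coverage returns exactly 1.0. Fits
with r² < 0.90 are flagged, and estimates are admitted only for MAGs with
Cp > 90, Ct < 5, fewer than 175 scaffolds/Mbp and coverage > 5; archaeal
MAGs additionally require exactly one known replication origin, consumed
as metadata (origin detection is out of scope). GC-bias correction is
omitted: the synthetic data are GC-neutral, and this is a documented
deviation for real data. Group contrasts use pairwise two-sided Wilcoxon
rank-sum tests (normal approximation, mid-rank ties) with Bonferroni
correction over the number of pairs.

## Ecology

Alpha diversity on per-MAG read counts: dominance Σp², Simpson 1 − Σp²,
Shannon H = −Σp·ln p, evenness e^H/S, Berger–Parker max p, Chao-1
S + F₁²/(2F₂) with the bias-corrected fallback S + F₁(F₁−1)/2 when no
doubletons exist, and Fisher's alpha as the root of S = α·ln(1 + N/α)
found by bracketed root-finding to 1e−9 (no finite root exists when every
taxon is a singleton; Inf is returned). Counts, not relative abundances,
feed Fisher's alpha — N is the MAG-assigned read total of the sample.
Whittaker beta diversity is S_union / mean(S_a, S_b) − 1 on presence sets;
Bray–Curtis is Σ|a−b| / Σ(a+b). UPGMA trees come from average-linkage
agglomeration (lexicographic pre-ordering for deterministic ties) and are
ultrametric, with leaves at half the merge distance. PCoA is classical
scaling — double-centre −½D², eigendecompose, scale eigenvectors by √λ —
with negative eigenvalues reported and their axes dropped; on
Euclidean-embeddable distances the coordinates reproduce the input
distances to 1e−9. Group tests are Mann–Whitney with Bonferroni correction,
or Welch's t-test for richness contrasts (e.g. thermophilic vs mesophilic
communities). Metadata-driven sample exclusion (e.g. removing acidogenic
reactors before ordination) is a filter flag, not a hardcoded rule.

## The synthetic-community generators

The generators replace a large external read set with small communities
whose every downstream answer is known:

* **Genomes.** Each species has an i.i.d.-uniform ACGT ancestor; genome *j*
  applies i.i.d. substitutions at `mutationRates[j]`, so ANI to the
  ancestor is analytically `100·(1 − rate)` and between two mutated
  siblings `100·(1 − r₁ − r₂ + (4/3)r₁r₂)`. No indels in this version —
  substitution-only keeps planted ANI exact. Genomes are emitted as 1–10
  contigs with recorded breakpoints to exercise per-scaffold handling. The
  default rate ladder `c(0, 0.01, 0.02, 0.03)` keeps every within-species
  pair above the 95 % boundary (worst pair ≈ 95.1 %) while the rate-0 first
  genome is the ancestor itself.
* **Abundances.** Log-normal base abundances (the conventional model for
  microbial rank-abundance structure; the distribution is a parameter),
  per-sample log-normal perturbation, a planted core whose members are
  floored above the presence threshold in every sample, and non-core MAGs
  zeroed in a ~40 % random subset of samples. Columns normalise to 100.
* **Window coverage.** Expected log2 depth declines linearly with circular
  index distance from a randomly placed origin window so that
  depth(ori)/depth(ter) equals the planted ratio exactly; Gaussian noise is
  added in log2 space. Windows are 0-based half-open.
* **Annotations.** For each planted (MAG, module) category the emitted KO
  set is constructed by withholding the leaves of randomly chosen blocks
  and *verified* against the evaluator, with errors for unachievable plants
  (e.g. "2 bm" on a one-block module). CAZy tables draw class labels per
  gene from background frequencies, multiplied tenfold for planted
  enrichments.
* **Metadata.** TAN (ammonia) is uniform on 0.5–7 g/L and the
  acetoclastic : hydrogenotrophic ratio is planted log-linearly in TAN with
  negative slope, mirroring ammonia inhibition of acetoclastic
  methanogenesis, so the correlation stage has a recoverable signal.

What the generators do **not** emulate: read-level errors and FASTQ
simulation, assembly and binning artefacts, indels and rearrangements,
GC-coverage bias, compositional correlation between MAGs, and phylogenetic
signal in annotations. Passing the synthetic recovery suite therefore
demonstrates the correctness of the implemented computations and their
statistical calibration — not robustness to assembly error or alignment
noise in real data.

## Problem sizes and numerical choices

The validation suite uses 20–100 kb genomes (9–30 MAGs), 6-sample
communities, 2-Mb replication profiles (400 windows), 200-seed null
simulations for enrichment and 500–1000-rep type-I simulations for the
rank tests; these sizes make every planted signal decisively recoverable
while keeping the whole suite and the acceptance script to a few minutes.
The bundled end-to-end scenario (30 MAGs, 3 planted species clusters among
12 genomes plus 18 singletons, 6 samples) writes ~1 MB of plain-text
inputs and recovers the species partition, all planted module prevalence
classes, exactly the planted CAZy enrichment, and the planted replication
ratios within 0.05.

Numerical conventions: doubles are serialised to TSV at 17 significant
digits so tables round-trip bit-identically; hash values are 53-bit so
they are exact in doubles; Fisher's alpha uses `uniroot` at tolerance
1e−12; UPGMA and profile clustering pre-sort labels lexicographically;
division-by-zero sentinels are `Inf` for the Bacteria/Archaea ratio
(bacteria present, archaea absent) and `NA` for the methanogenesis ratio
(denominator module absent).

## Known limitations

Fragment ANI is gap-free and will under-estimate identity between genomes
with indels; the Mash pre-filter can in principle sever a true edge when a
pair sits exactly at the 95 % boundary (single-linkage through closer
cluster members makes this harmless in the validated regimes, and the
brute-force path is available); iRep assumes a single origin and a
log-linear gradient, and multi-origin archaea are excluded rather than
modelled; the CAZy background urn is pooled across MAGs, which tests
gene-repertoire enrichment rather than abundance-weighted enrichment.
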