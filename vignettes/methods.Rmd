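---
title: "Combinatorial eQTL mapping and hotspot detection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial eQTL mapping and hotspot detection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlhot)
```

## The problem

In a biparental cross (an F2 or a recombinant-inbred-line population),
the genotype at a marker can associate with the mRNA abundance of a
gene measured across the offspring lines — an expression quantitative
trait locus (eQTL). An eQTL within 1 Mbp of the gene's transcription
start site (TSS) is *cis*; anything farther, or on another chromosome,
is *trans*. Marker-pair regions that regulate many genes in trans are
regulatory hotspots, and in crop genetics they often point at a
transcription factor segregating between the parents.

`eqtlhot` implements the full chain of that analysis: linkage-map
construction anchored to physical positions, three complementary scan
engines combined by a two-of-three consensus rule, percentile-based
hotspot calling, co-expression networks around hotspot targets,
Fisher-test term enrichment, and a variant prioritization cascade for
candidate regulators. A seeded simulator generates crosses with planted
cis effects and trans hotspots so every stage can be tested against a
known truth.

## Linkage maps

Map distances use the Kosambi function, `m = 25 ln((1+2r)/(1-2r))` cM,
whose inverse is `r = tanh(m/50)/2`. Marker order is taken from the
physical positions — no de novo grouping or ordering is attempted —
and adjacent recombination fractions are estimated from the genotype
calls: for RILs the raw mismatch fraction between homozygous calls is
mapped back through the selfed-RIL expansion `r* = 2r/(1+2r)`; for F2s
a short EM iteration handles the phase ambiguity of the
double-heterozygote class. Wherever the resulting adjacent gap strictly
exceeds 30 cM (a boundary of exactly 30.0 stays joined), the chromosome
is split into lettered linkage groups (`GM13a`, `GM13b`, ...). Missing
calls are excluded pairwise; imputation is deliberately out of scope.

## Scan engines

All three engines share one precomputed grid (1-cM walking step, with
every marker position included so that marker LODs are exact
regressions on the observed genotypes). At each grid position the
expected QTL genotype given the flanking markers is computed from the
no-interference Markov chain of crossovers, and the phenotype is
regressed on the expected additive (and, for F2, dominance) codes —
Haley–Knott regression. The LOD is `(n/2) log10(RSS0/RSS1)`; the
percent variance explained is `100 (1 - RSS1/RSS0)` at the peak; the
additive effect is half the fitted homozygote difference and the
dominance effect is the heterozygote deviation. One peak is reported
per linkage group per gene, bounded by its flanking markers. We chose
regression over the full EM mixture likelihood because it is the
standard fast approximation and agrees with it closely at these
population sizes; the original tools behind the three methods are
external black boxes, so all three engines here are documented
stand-ins validated by simulation, not numeric replicas.

**IM** is the plain interval-mapping scan. **ICIM** first runs
forward–backward stepwise selection of marker cofactors (entry/exit
p-values 0.001/0.002, the customary defaults), then rescans each
interval after subtracting the fitted contribution of every selected
cofactor except the two markers flanking that interval; with no
cofactors selected it reduces to IM exactly. **GCIM** is a two-stage
multi-locus scan: a genome-wide single-marker scan with a polygenic
control — either the top-k cofactor regression (`fixed`) or a
variance-component polygenic term with a marker-derived kinship fitted
by REML (`fixed_REML`) — followed by a lasso-penalized joint refit of
the stage-1 candidates (model picked by BIC along the lambda path),
each surviving locus reported with its drop-one likelihood-ratio LOD.
Two numerical choices proved load-bearing: stage-1 candidates are
thinned to local LOD maxima within the cofactor-exclusion window
(feeding collinear neighbors of one peak into the joint model splits
the drop-one ratios and loses true loci), and the REML kinship is
built leave-one-linkage-group-out (a global kinship absorbs the tested
locus itself). A singular kinship falls back to the fixed model with a
warning.

Default LOD thresholds follow the population conventions: IM and ICIM
use permutation-derived thresholds, GCIM uses a fixed 7.5 for F2 and
4.0 for RIL.

## Permutation thresholds

Permuting every transcript a thousand times is prohibitive, so the
null is made representative instead: `n_sample_genes` transcripts
(default 100) are sampled, each permuted `n_perm` times (default
1,000), the genome-wide maximum LOD of every permutation is recorded,
and all `n_sample_genes x n_perm = 100,000` maxima are pooled. The
threshold is the 95th percentile of that pool, with percentiles
throughout the package defined by linear interpolation between order
statistics. Under permutation the ICIM stepwise stage selects no
cofactors, so its null maxima coincide with IM's and the fast
vectorized IM path is used for both; fully per-permutation ICIM/GCIM
runs remain available through the `method` argument.

## Consensus merging

Interactions are classified cis when the region is on the gene's
chromosome and within 1,000,000 bp of the TSS (boundary inclusive,
distance zero when the TSS falls inside the region). Per gene and per
class, the three methods are compared pairwise; two interactions
co-validate when they share the chromosome and their intervals, padded
by 500,000 bp on each side, intersect — equivalent to an edge-to-edge
distance of at most 1 Mbp. Co-validated interactions are union-merged,
duplicates across the three comparisons collapse into one record, and
any trans consensus whose padded interval touches a cis consensus of
the same gene is reclassified cis. Consensus coordinates are the
un-padded union of the contributing regions: keeping padded bounds
would inflate every region by up to 1 Mbp. Merging is strictly
gene-wise — interactions of different genes never merge — which is
what the per-gene codification format
(`trans_<gene>_<chrom> <start> <end>`) implies.

## Hotspots

Each distinct regulating marker-pair region is scored by its number of
trans interactions and its density in interactions per kbp. A region
is a hotspot only when both criteria hold: count at or above the 95th
(minor) or 99th (major) percentile of all regions of that population,
and density at or above the 80th density percentile. Boundary values
are included — a region exactly at a percentile passes — and the
inclusive rule also fixes the degenerate all-equal case (every region
sits at the 100th percentile and passes).
Zero-width regions have undefined density; they stay count-eligible
but are excluded from the density pool and cannot pass the density
gate. Hotspots sharing a boundary marker on one chromosome merge into
a single region (counts summed, density recomputed, stronger class
kept) and regions are named `<TAG>_<CHROM>:<start>-<end>` with
thousands separators.

## Co-expression and enrichment

Networks use Pearson correlation across lines on normalized
expression. The targeted network (CEN) clusters a hotspot's targets
plus candidate TFs by average-linkage hierarchical clustering on
`1 - PCC` — the default behavior of the heatmap tooling this emulates —
with the cluster count chosen at the largest gap between merge heights
(overridable with `k`; the choice is a stated convention, since in
practice it is often made visually). Transcriptome-wide networks
(TWCEN) take a single query gene and return the genes at PCC >= 0.85
(positive) or <= -0.85 (negative), boundaries included.

Enrichment uses one-sided hypergeometric tails in the direction of the
observed deviation. The correction is deliberately unusual: raw
p-values are multiplied by the number of scanned genes and *not*
clipped at 1 (0.003 over 4,000 genes gives 12), reproducing the
convention of the soybean annotation service this emulates; the
multiplier is an explicit argument so the conventional term-count
Bonferroni is one call away. Significance is corrected value <= 0.01.
A curated flowering/reproduction/senescence/photosynthesis/development
term list can then filter the results to biological-process terms.

## Variant prioritization

Variants in candidate TF genes pass when their predicted consequence
is MODERATE or HIGH *or* they sit in a UTR, and when the alternate
allele is present in a single parental line. The parental rule needs
care with heterozygotes: we retain a variant when exactly one parent
is a homozygous alternate carrier (a heterozygous call in the other
parent is flagged with an asterisk in rendered tables but does not
block the variant), or when a lone heterozygous carrier faces a parent
matching the reference. Treating a heterozygous call as a full carrier
would discard exactly the flagged-heterozygote rows this layout is
meant to report, so the homozygous-carrier reading is used. SIFT
scores below 0.05 are deleterious, at or above 0.05 tolerated, absent
scores are N/A. Candidates are assigned to regions within 300 kbp of
their TSS — wide enough to keep a regulator just outside a hotspot's
flanking markers.

## Expression filtering, normalization and parental DE

A gene counts as expressed when it has at least 2 raw counts in at
least 25% of the lines (both boundaries inclusive; `ceiling` on the
line count). Normalization is the median-of-ratios size-factor method;
size factors are rescaled to a unit geometric mean, which leaves all
ratios untouched and makes normalization exactly idempotent. The
parental differential-expression step is a deliberate simplification
of a count-model DE analysis: Welch t-tests on `log2(normalized + 1)`
with Benjamini–Hochberg adjustment, gated by adjusted p <= 0.05 *and*
linear fold change >= 2 in either direction — the gating logic is what
downstream annotation consumes, so a gene at fold change 1.90 with a
tiny adjusted p-value is still not called differentially expressed.

## The simulator

The generator emulates the structure the analysis assumes, at the
scale of typical early-maturing soybean mapping populations: an F2 of
176 lines (or a RIL set of ~162), 20 chromosomes with 80 evenly
spaced markers each, and tens of
thousands of genes (default 20,000). Genotypes come from
no-interference crossover chains (inverse-Kosambi recombination
between adjacent markers; two independent gametes for F2, one
homozygous genome with expanded fractions `2r/(1+2r)` for RIL;
residual RIL heterozygosity is 0, since het-heavy markers are removed
upstream in practice). Interference affects map construction, not
generation fidelity at this marker spacing, so independent crossover
events suffice.

Expression is negative binomial around a shared log-normal baseline
(median ~100 counts), with per-line library-size factors drawn
log-uniformly from 0.7–1.4 and a per-line log2-scale Gaussian residual
whose SD defines the unit of all effect sizes. A configurable fraction
of genes (default 5%) get a cis effect at the marker nearest their
TSS; each planted hotspot regulator drives its targets in trans (the
default plants a 200-target regulator at 1.5 SD and a 40-target one at
1 SD — tens to hundreds of targets, as real hotspots show). No noise
family is prescribed for real cross data; negative binomial with
configurable dispersion (default 0.05) is this package's choice, and
the dispersion-to-zero limit recovers Poisson counts.

What the simulator does *not* emulate: segregation distortion,
linkage-map errors, shared environmental/batch structure, expression
outliers, and polygenic trans backgrounds beyond the planted hotspots.
Passing recovery tests therefore demonstrates that the pipeline's
logic is correct under its own assumptions, not that real tissue data
will be as clean.

## Problem sizes used by the test and acceptance suites

The recovery suites run at reduced scale, chosen once as
representative: cis-eQTL localization uses 50 seeds of a 176-line F2
with 2 chromosomes x 20 markers and a 1-SD effect (success: top peak
within 10 cM in at least 45/50); hotspot recovery uses 20 seeds of a
162-line RIL with 5 chromosomes x 12 markers, 300 genes and the
200-target 1.5-SD regulator, scanned by IM plus the fixed-model GCIM
(success: a merged major hotspot covering the regulator in at least
18/20); the type-I-error check pools 100 permutations x 10 sampled
genes on a 100-line, 200-marker RIL null and verifies the genome-wide
false-positive rate over 500 null genes lies in the binomial 95%
interval around 0.05. Percentile thresholds, seeds and generator
settings were fixed before running the suites and are not adjusted to
outcomes.

## Known limitations

The three scan engines are simplified reimplementations; their
agreement surface is simulation-based recovery, never numeric equality
with the proprietary tools. One peak is reported per linkage group per
gene and method, which can undercount multi-peak chromosomes. The
pipeline is single-process; all randomness flows from one root seed
through named per-stage substreams, so reruns are bit-identical.
Enrichment takes annotations as given (no ontology propagation), and
variant consequences/SIFT scores are consumed, not predicted.
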