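---
title: "Methods: depth-resolved nitrogen-cycling analysis with nitromat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-resolved nitrogen-cycling analysis with nitromat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitromat)
```

`nitromat` analyses how nitrogen metabolism is partitioned across the first
few millimeters of a laminated microbial mat. This vignette explains the
models and procedures behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical conventions adopted where a design
decision was genuinely open.

## Study design assumed by the pipeline

The canonical design is seven 1-mm layers cut from each of three replicate
cores. Nine markers are assayed by qPCR (DNA template) and RT-qPCR (cDNA
template): domain-level 16S rRNA for Bacteria and Archaea, a
Planctomycetes-16S marker as an anammox proxy, and the functional genes
*nifH*, archaeal and bacterial *amoA*, *Nitrospira*-*nxrB*, *nosZ* and
*nirS*. Metagenome coverage is available for the upper four layers only
(replicate slices pooled for sequencing), which is why the coverage tables
default to four layers while the qPCR panel has seven. Porewater chemistry
(`make_env_fixture()`) spans all seven layers: oxygen is measurable only in
the upper 3–4 mm (encoded `NA` below), ammonium roughly quadruples with
depth (34.1 to 124.0 µM), nitrate and phosphate vary little.

## qPCR profiles

Copy numbers are normalized on two bases — copies per gram of mat and
copies per nanogram of extracted nucleic acid — because extraction
efficiency differs between layers of very different density; conclusions
that hold on both bases are robust to that bias. The expression proxy is
the cDNA/DNA ratio per marker and layer.

*Replicate aggregation.* The ratio is the ratio of replicate means, not the
mean of per-replicate ratios: a single near-zero DNA replicate would
otherwise dominate the statistic. The median is available as an option.

*Below-detection handling.* Records under the detection limit are kept and
flagged, never silently dropped; downstream, flagged replicates are
excluded from aggregation and from the layer tests, and a layer whose DNA
is entirely below detection yields no ratio (with a reason code) rather
than an infinity or a substituted value. We deliberately do not impute
LOD/2: the assays here span eight orders of magnitude, so any constant
substitution would be arbitrary.

*Layer comparisons.* Copy numbers are strongly right-skewed (a Shapiro-Wilk
screen is provided to document this), so layer differences use
Kruskal-Wallis on midranks with tie correction (`stats::kruskal.test`),
followed by all-pairs Conover-Iman comparisons: t statistics on mean ranks
with the pooled rank variance scaled by $(N-1-H)/(N-k)$ and $N-k$ degrees
of freedom. Pairwise p-values are reported unadjusted by default, matching
long-standing practice for this post hoc test in ecology; a Holm option
exists. Results are summarized as a compact letter display computed by
insert-and-absorb: two layers share a letter exactly when they are not
significantly different at the chosen alpha, letters are assigned in
descending order of layer mean with index as tie-break, so output is
deterministic. Note the chi-square reference for Kruskal-Wallis is
conservative at the design's n = 3 replicates per layer; the package tests
verify nominal size at larger group sizes where the approximation is
adequate.

## Nitrogen coverage accounting

Genes are filtered by a packaged map of nitrogen-metabolism KOs covering
six pathway categories (nitrogen fixation, assimilatory nitrate reduction,
DNRA, hydroxylamine dehydrogenase, hydroxylamine reductase,
denitrification) plus the nitrate/nitrite transporter family. Two KOs are
intrinsically ambiguous — K00370 (*narG*/*narZ*/*nxrA*) and K00371
(*narH*/*narY*/*nxrB*) cover both nitrate reductase and nitrite
oxidoreductase subunits — and keep combined symbols rather than a forced
call. For category totals, *narI*/*narV* (K00374) is counted under
denitrification so that the six categories partition the gene set; the
summary carries a footnote recording its DNRA association.

**N-CPM** divides each gene's per-layer coverage by the summed coverage of
*nitrogen* genes in that layer and scales to one million. The
nitrogen-only denominator is the point of the metric (shares of the
nitrogen economy, robust to differences in total sequencing depth between
layers); an all-genes denominator is available as an option. The layer-sum
invariant (each layer sums to 10⁶) is asserted in the tests on random
tables.

**FDIC** divides each gene's per-layer value by that gene's total across
layers, giving a depth profile that sums to one. It is computed on N-CPM
values by default. Note that FDIC from raw coverage and FDIC from N-CPM
agree only when the per-layer nitrogen totals are equal — the per-layer
N-CPM denominators do not cancel otherwise — so the choice of input scale
is part of the method: the default (N-CPM) expresses *relative* depth
structure after normalizing out layer-to-layer coverage differences.
All-zero genes are excluded and reported separately rather than producing
0/0.

Depth trends are summarized as fold changes of mean N-CPM between two
layers with a direction label; `flat` applies within a relative tolerance
(default 0.05) around fold 1. A zero denominator yields an infinity flag,
not an error.

## Community statistics

The multivariate stack follows the PRIMER conventions. Biotic matrices
(layers × cDNA/DNA ratios, or layers × N-CPM) are sample-total standardized
to percent. Bray-Curtis similarity is kept on the 0–100 scale
($100\,(1 - \sum|x_i - y_i| / \sum(x_i + y_i))$); a pair of all-zero
samples is undefined and assigned a configurable convention (default 0,
with a warning). Clustering is unweighted group-average agglomeration on
dissimilarity $100 - S$; samples are pre-sorted lexicographically so merge
order under ties is deterministic.

**SIMPROF** asks, at each dendrogram node, whether the samples beneath it
contain multivariate structure. The statistic is
$\pi = \sum_i |s_{(i)} - \bar{s}_{(i)}|$, the departure of the observed
ordered similarity profile from its expectation under permutations that
shuffle each variable independently across the node's samples. The
expected profile is estimated from one pool of permutations (default 999)
and the null distribution of $\pi$ from a second, independent pool
(default 999); $p = (1 + \#\{\pi^* \ge \pi\})/(1 + n)$. Testing proceeds
from the root downward and stops below any non-significant node; nodes
with fewer than three samples are untested and reported with $p = 1$. The
acceptance suite verifies the test holds its nominal 5% size under
unstructured lognormal data (200 simulations).

**NMDS** minimizes Kruskal stress-1 with monotone regression via
`vegan::monoMDS`, restarted from a metric-scaling configuration plus 50
random starts by default; the lowest-stress solution is returned with
centered coordinates, and the full stress vector is kept so the "best over
restarts" contract is checkable. Convergence follows `monoMDS` defaults;
ties in the monotone regression use the primary approach.

Spearman correlations (biotic × biotic and biotic × environmental blocks)
use midranks with the two-sided t approximation for p-values; pairs with
fewer than three complete observations are skipped with a warning. Vector
overlays correlate each variable with the two ordination axes and scale
the vector $(r_1, r_2)$ onto the unit circle for plotting.

## HAO motif classification and phylogeny

Oxidative HAO of aerobic ammonia oxidizers carries a tyrosine that
cross-links the active site to the catalytic heme of the adjacent subunit;
its absence predicts reductive catalysis. εHao proteins of
*Campylobacterota* instead carry a tryptophan at the equivalent position
and a conserved methionine eight residues upstream. The classifier reads
exactly these diagnostics.

Queries are aligned to an anchored reference alignment by global dynamic
programming against the profile: the score of residue $a$ at column $c$ is
the mean BLOSUM62 score of $a$ against the column's non-gap residues, with
affine gap costs (open 11, extend 1; a length-$L$ gap costs $11 + L$).
Reference columns are immutable — query insertions are recorded separately
and never shift column indexing — so the anchor column computed once on
the reference remains valid for every aligned query. The anchor is a
configuration value (reference row plus ungapped residue position held in
a sidecar file), never hard-coded.

The packaged reference alignment is **synthetic**: offline construction of
a curated alignment of real HAO proteins is not reproducible from code, so
the package ships generated sequences
(`inst/extdata/hao_reference_synthetic.afa`) that reproduce the
diagnostic structure — four labeled families (AOB-HAO, anammox-HAO,
εHao, nitrate-reductase-like), the tyrosine/tryptophan anchor column, the
−8 methionine, and an indel region that exercises gap handling — without
being real proteins. Swapping in a real curated alignment is a matter of
pointing `load_hao_reference()` at different files.

The call rules: tyrosine at the anchor column → oxidative-HAO-like;
tryptophan → εHao-like, with the methionine-at-−8 flag evaluated in the
query's own ungapped coordinates (insertions count — the motif belongs to
the sequence, not the alignment); a gap, an `X`, or any other residue →
ambiguous, with the residue reported.

Trees use p-distances (mismatches over pairwise non-gap columns) and
Saitou-Nei neighbor joining (`ape::nj`). Negative branch lengths — an
artifact of non-additive distances — are clamped to zero with the deficit
moved to a sibling branch, preserving total tree length in the common
single-negative case. When a nitrate-reductase-like reference is present
the tree is rooted on it as an outgroup. Clade assignment walks from each
query tip rootward to the smallest clade containing at least one
reference: a single reference class assigns that class, a mixed clade
yields "unresolved". No bootstrap support or likelihood inference is
attempted; the package makes clade-level statements only.

## The synthetic-data generator

The generator exists so that every stage can run, and be validated against
known truth, without the original sequencing data. Design choices:

- **Noise model**: all abundances are lognormal (Gaussian on log10),
  because both qPCR copy numbers (spanning roughly 10³–10¹¹ per gram) and
  gene coverage vary multiplicatively. The replicate noise default
  (`noise_sd_log10 = 0.15`) is a free parameter — the assay literature
  does not fix replicate variance — chosen as a realistic qPCR
  between-core spread of ~1.4× at one standard deviation.
- **qPCR truth profiles** encode the depth behaviour the pipeline must
  resolve: low biomass in the surface layer, most markers peaking at the
  layer 2–4 chemocline, archaeal *amoA* quantifiable in one layer only
  (exercising the below-detection path), expression ratios peaking in
  layer 3 for the oxygen-requiring markers and layer 4 for *nxrB*,
  *nosZ*, *nirS* and the anammox proxy, with *nosZ* and *nirS* the
  largest ratios.
- **Coverage trends** are log10 slopes per mm on raw coverage: negative
  for nitrogen fixation (−0.144, a 2.7-fold decline over three layers)
  and assimilatory reduction, positive for DNRA, *hao*, *hcp* and
  denitrification, zero for the non-nitrogen background genes that make
  KO filtering non-trivial. Because N-CPM renormalizes within each layer,
  the *share* of a declining category falls faster than its raw coverage
  when other categories rise; fold changes reported on N-CPM are
  therefore emergent, not copies of the input slopes.
- **Determinism**: each output table draws from its own RNG stream seeded
  from `seed` plus a stable offset, so generating one table never
  perturbs another and identical configurations are byte-identical.

What the generator does *not* emulate: sequencing reads and their error
structure, assembly and annotation noise, compositional correlations
between markers, spatial autocorrelation between adjacent layers, and
extraction-efficiency differences between layers (the two qPCR bases are
therefore proportional in simulated data, unlike in real data). Passing
tests demonstrate the statistical machinery is correct and calibrated,
not that real mats behave like the generator.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale: 100 random
tables for the normalization identities, 50 datasets for the rank-test
oracles, 200 simulations × 999+999 permutations for SIMPROF size, 50
random trees for neighbor-joining recovery, 1000 rows for anchor mapping,
and 20 proteins for end-to-end motif recovery. Probabilities and
statistics are serialized at 17 significant digits so determinism is
testable on the output files themselves; tables are tab-delimited UTF-8
with `.` decimals; layers are 1-based integers counting 1-mm slices from
the surface. The pipeline driver (`run_all()`) echoes every seed into its
report and writes no timestamps, making full-run reproducibility an
equality of files.
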