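---
title: "Methods: comparative genomics of cold-adapted yeasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of cold-adapted yeasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldadapt)
```

# Scope and model

`coldadapt` implements a comparative-genomics workflow for psychrophilic
(cold-adapted) yeasts. Its inputs are draft genome assemblies (FASTA), CDS
annotations (GFF3, coordinates 1-based inclusive on the forward strand),
per-CDS annotation and pathway tables, optional externally predicted
per-protein flexibility classes, and absorbance (A600) growth time series.
From these it computes:

* assembly statistics (contig count, size, GC with `N` excluded from both
  sides of the ratio);
* per-protein **flexibility profiles** from amino-acid composition: the very
  flexible class Vf = {E, G, K, N, Q, S}, the moderately flexible class
  Mf = {A, D, H, I, P, R, T, V}, their union VMf, and the rigid complement
  {C, F, L, M, W, Y}. The flexibility index only names the Vf and Mf sets;
  the rigid set is defined here as the complement of the 20 standard
  residues. Externally predicted classes M0/M1/M2 (rigid to flexible) enter
  as an optional input table and are treated uniformly with the
  composition metrics downstream (M1+2 = M1 + M2);
* **smORFs**: open reading frames of 30-300 nt (ATG to the first in-frame
  stop, stop codon included in the span, all six frames, every qualifying
  ATG reported), positionally classified against the CDS annotation;
* **growth parameters**: the growth rate Gr per temperature as the
  exponential-phase log-slope of A600, and the optimal temperature for
  growth (OTG) as the temperature with the highest exponential-phase
  maximum A600;
* cross-species statistics: per-(pathway, metric) one-way ANOVA with Tukey
  HSD pairs, significance-count heatmaps with average-linkage clustering,
  difference-vs-difference OLS regressions against growth parameters, and
  gene-redundancy tables;
* a **multigene phylogeny** workflow: pairwise global/local alignment,
  p-distances with pairwise deletion, the generalized Jukes-Cantor
  correction `d = -((k-1)/k) log(1 - k p/(k-1))` (k = 4 nucleotides,
  k = 20 amino acids), canonical neighbor joining, column-bootstrap
  supports, patristic distances, common-protein selection and concatenated
  alignments.

Every stage is testable offline through the `synthetic_spec()` /
`generate_*()` generators, which plant genomes, smORFs, redundant families,
growth curves and tree-evolved proteins with known truth.

# smORF discovery and classification

The scanner reports, per frame and strand, every ATG whose first in-frame
stop lies within the 30-300 nt span (stop included). Alternative start
codons are not used, ORFs are not wrapped around contig ends, and nested
ATGs are each reported: this report-all, first-stop policy is the most
common ORF-finder convention and makes counts reproducible. Coordinates are
always reported on the forward strand; `frame` is the offset in the strand
actually read.

Classification is by *containment*, with precedence CDS > 5' > 3':

* `CDSSmORF` - the ORF interval lies fully inside a CDS interval on the
  same contig (strand-agnostic);
* `5'SmORF` - fully inside the 1,000 nt window upstream of a CDS start,
  where "upstream" follows the CDS strand;
* `3'SmORF` - fully inside the 1,000 nt window downstream of a CDS end;
* `intergenic` - otherwise.

Windows are clipped at contig boundaries; ties between several qualifying
CDSs are resolved toward the nearest CDS boundary. Overlap without
containment does not classify an ORF, so every ORF receives exactly one
class.

Matching of smORF peptides against a reference set uses deterministic
Smith-Waterman local alignment; a hit requires at least 50% identity over
aligned columns *and* 50% query coverage. "Similarity" is implemented as
percent identity (not substitution-matrix positives) for determinism.

# Growth-rate estimation

The exponential-phase detector is the one deliberately designed component
of the growth module, since visual/manual phase selection is not
reproducible. Its requirements were: exactness on noiseless exponentials,
exclusion of the saturating tail on logistic curves, and near-unbiased rate
recovery under additive absorbance noise of sd 0.01 with an inoculum of
A600 = 0.1 read daily for 10 days. A plain "steepest log-linear window with
R-squared >= 0.95" rule meets the first two but is upward-biased by
+0.03-0.05 under that noise (the steepest short window is always a noise
outlier, and the R-squared gate passes exactly the windows that look
steep); a "longest qualifying window" rule is downward-biased by the
logistic curvature. The shipped rule therefore:

1. flags curves with total absorbance range < 0.01 as *no growth* (Gr = 0);
2. trims the saturating tail: when the curve rises more than 3-fold
   overall, only readings up to the last one below max(A)/3 (at least 6
   points) are retained as the candidate exponential region;
3. fits `ln A` against time in every contiguous window of >= 3 retained
   points by weighted least squares with weights `A^2` — the
   inverse-variance weights implied by additive absorbance noise;
4. selects the window maximizing `slope - 4 * se(slope)`, where the slope
   standard error uses a robust global noise estimate (median absolute
   second difference of the absorbances, scaled). On noiseless data the
   penalty vanishes and the rule reduces to plain maximum slope; under
   noise it suppresses windows whose steepness is within estimation error.

The penalty multiplier 4 and the trim parameters were calibrated once
against the generator's planted truth across rates 0.05-0.2 per day
(median absolute strain-level error below ~0.01 over most of that range);
they were not adjusted afterwards. A weighted R-squared below 0.95 flags
the fit as low-confidence rather than rejecting it, because at low
signal-to-noise an R-squared *gate* selects on noise. Residual limitations:
on a noiseless logistic with K only 12 times the inoculum the estimate is
~15-20% below the logistic rate parameter (the curve has no true
exponential phase to measure), and rates at the extremes of the calibrated
range carry biases up to about 0.01.

Gr is reported in reciprocal units of the input time axis (per day for
daily readings). The OTG is the temperature whose mean exponential-phase
maximum A600 is highest, ties broken toward the lower temperature. Because
the generated curves end at or before the logistic inflection, the
exponential-phase maximum equals the curve maximum, which is what
`detect_exponential_phase()` reports; this quantity is monotone in the rate
whenever temperatures share a carrying capacity, so the OTG argmax is
unaffected by the choice. OTG deliberately uses the A600 criterion rather
than the Gr argmax: the two can differ (a strain can grow fastest at a
low temperature yet reach its highest exponential-phase density at a
higher one).

# Cross-species statistics

Observations for the ANOVA are *per-CDS* metric percentages, grouped by
(pathway, metric); a protein with several pathway labels contributes to
each, and a `"global"` pseudo-pathway contains all proteins once. One-way
fixed-effects ANOVA is followed by Tukey HSD with the Tukey-Kramer
unequal-n adjustment (`stats::TukeyHSD`). No multiple-testing correction is
applied across pathways — the heatmaps count raw Tukey p < alpha cells, with
alpha exposed as an argument. Normality is assumed (no automatic
nonparametric fallback); groups with fewer than two observations are
dropped, and all-constant cells are recorded as untested.

Significance-count matrices are symmetric with zero diagonal; entities can
be regrouped (e.g. by OTG or Gr class) before counting, in which case
within-group pairs are dropped and each (pathway, metric, group-pair) cell
counts once. Clustering of the count matrix rows uses average-linkage
agglomeration on Euclidean distances. Difference-vs-difference regressions
are ordinary least squares with intercept on the selected significant
pairs; two-point regressions have R-squared 1 by construction and carry a
`two_point` flag so they are not over-interpreted.

# Phylogeny workflow

Pairwise alignment delegates to `Biostrings::pairwiseAlignment`
(Needleman-Wunsch / Smith-Waterman with affine gaps, BLOSUM62 and gap
open/extend 10/0.5 by default); identity is computed over gap-free columns
and local coverage over the query span. Multiple alignment of a protein
family uses a deterministic star scheme: all members are aligned globally
to the longest member and projected onto its columns (insertions relative
to the reference are discarded). This keeps the pipeline self-contained and
reproducible; pre-aligned input is also accepted anywhere an MSA is
expected. Distances use pairwise deletion of gap columns (maximizing usable
sites for short groups), the generalized Jukes-Cantor correction, and
saturated pairs (p >= (k-1)/k) are flagged infinite.

Neighbor joining is the canonical Saitou-Nei algorithm with the
Studier-Keppler Q criterion, a deterministic tie-break (lexicographically
smallest index pair), and negative branch lengths clamped to zero with the
deficit moved to the sister edge. On additive matrices it reproduces
topology and branch lengths exactly (verified against patristic round
trips and against `ape::nj` as an independent implementation). Bootstrap
supports resample alignment columns with replacement, rebuild a tree per
replicate, and report the percentage of replicates containing each
bipartition of the full-data tree; replicates with saturated distances are
dropped and counted, with a warning above 10%. Supports are bit-exact
reproducible for a fixed seed.

Common-protein selection groups CDSs by identical annotation label, keeps
labels present in at least `min_species` species (optionally required to
include specific species), and picks the longest peptide per species as
representative (ties by smallest CDS id). Concatenation joins per-group
alignments over an identical species set in sorted group order.

# Synthetic data: what it emulates, and what it does not

The generator defaults mirror the study conditions qualitatively: four
species with OTGs of 20/10/15/15 degC and peak growth rates of
0.1579/0.0726/0.0736/0.175 per day; incubation at 4-30 degC with daily
readings for 10 days, triplicates, inoculum A600 = 0.1 and additive
Gaussian noise sd 0.01; background GC from 50.9% to 61.2%; redundant gene
families (P-loop NTPase, alpha/beta hydrolase, MFS, armadillo-repeat
labels) planted as identical-peptide copies. Values the study does not
print were fixed once at realistic levels: logistic carrying capacity K
drawn uniformly from 2.5-3.5 (plate-reader A600 saturation of yeasts in a
rich medium), a quadratic temperature-response curve with viability
half-width 12 degC (growth at 4-25 degC, none at 30 degC), contigs of
80 kb (not tens of Mb) so the full test suite runs in minutes, CDSs of
70-180 codons with residues sampled from a uniform baseline (expected
Vf = 30%) shifted by the planted `vf_effect`, and uniform synonymous-codon
usage.

Planted smORFs are constructed with no internal in-frame stop and placed so
that their declared class is unambiguous under the classifier's precedence
rules; the random background may still contain incidental ORFs, so
truth-based tests assert *recall* of planted elements, not precision
against background — exactly as with real genomes, where ORF scanning is
exhaustive. Planting a CDS-internal smORF overwrites part of its host's
sequence (in a shifted frame), so host peptides are re-derived from the
final sequence and truth tables stay exactly consistent with what the GFF3
reader reconstructs.

Features of real data the generator does not emulate: codon-usage bias,
introns (the CDS interface is intron-free), indel evolution, lag phases in
growth curves, reader nonlinearity at high absorbance, and any correlation
between gene content and temperature adaptation beyond the planted
composition shifts. Passing recovery tests therefore demonstrates that the
pipeline measures what was planted under controlled conditions, not that
the biological conclusions transfer to any particular real genome.

Protein evolution for tree-recovery tests places
`Poisson(rate x branch length x sites)` substitutions per branch with
uniform replacement over the 19 alternatives and no indels; with rates in
the unsaturated regime (pairwise p < 0.5) neighbor joining on Jukes-Cantor
distances recovers the generating topology in at least 95% of simulations.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive on the forward strand everywhere.
* Non-ACGTN symbols are masked to `N` on FASTA read; codons containing `N`
  translate to `X`; `X` residues are excluded from both numerator and
  denominator of flexibility percentages; peptides carry no terminal stop.
* GC is undefined (NA, with a warning) for all-N assemblies.
* Absorbances below 1e-3 are floored before taking logs.
* OTG ties break toward the lower temperature; Q-matrix ties in neighbor
  joining break toward the smallest index pair; redundancy-table ties break
  alphabetically.
* All randomized procedures take explicit integer seeds and are
  reproducible bit-for-bit.

# Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on synthetic data:
100 random 5-kb contigs for the ORF-scanner oracle, 100 random 5-8-taxon
trees for neighbor joining, 500 random 8-mer pairs for the alignment
oracle, a 2,000-replicate null simulation for the ANOVA type-I error,
200 simulated strains for OTG recovery, 100 evolved protein families for
topology recovery, 500 simulations for regression sign recovery, and
20 batches of triplicate growth curves per planted rate for the
growth-rate recovery. These sizes keep the whole suite in the
few-minutes range on one CPU while leaving the Monte-Carlo error well
below the asserted tolerances.
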