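# coldadapt

Comparative genomics of cold-adapted (psychrophilic) yeasts in R.

Yeasts from glacial habitats survive low temperatures partly through
protein-level adaptations: enzymes with more flexible structures stay
catalytically active in the cold. A recurring comparative-genomics question
is whether genome-wide protein flexibility — summarized from amino-acid
composition — tracks a strain's growth physiology (its optimal temperature
for growth and its growth rate). `coldadapt` implements the full analysis
chain needed to ask that question from draft assemblies and microplate
growth curves, for anyone comparing annotated genomes of cold-adapted
fungi or other microbes:

* **Assembly statistics** — contig count, genome size, GC (`N` excluded).
* **Protein flexibility** — per-CDS percentages of very flexible
  (Vf = E, G, K, N, Q, S), moderately flexible (Mf = A, D, H, I, P, R, T, V)
  and rigid residues, their aggregate VMf, plus externally predicted
  M0/M1/M2 classes (M1+2 = M1 + M2) taken as an input table.
* **smORFs** — exhaustive six-frame scan for 30–300 nt ORFs (ATG to first
  in-frame stop), classified by containment as `CDSSmORF` (inside a CDS),
  `5'SmORF` / `3'SmORF` (within 1,000 nt up/downstream, strand-aware) or
  `intergenic`; cross-genome sharing counts and identity/coverage matching
  against reference peptide sets.
* **Growth kinetics** — the growth rate Gr per temperature, estimated as
  the exponential-phase slope of ln A600 versus time (noise-robust window
  selection), and the optimal temperature for growth (OTG), the temperature
  with the highest exponential-phase A600.
* **Cross-species statistics** — per-(pathway × metric) one-way ANOVA with
  Tukey HSD pairs, significance-count heatmaps, average-linkage clustering
  of species by their difference profiles, Δflexibility-vs-Δgrowth OLS
  regressions, and gene-redundancy tables/ratios.
* **Multigene phylogeny** — pairwise and star alignments, p-distances with
  pairwise deletion, the generalized Jukes–Cantor correction
  `d = −((k−1)/k)·ln(1 − k·p/(k−1))` (k = 4 or 20), canonical
  neighbor joining, bootstrap supports, patristic distances,
  common-protein selection and concatenated alignments.
* **Synthetic data with planted truth** — genomes, smORFs, redundant
  families, growth curves and tree-evolved proteins generated from a
  `synthetic_spec()`, so every stage is testable without downloads.

## Worked example

```r
library(coldadapt)

spec <- synthetic_spec(seed = 42)
g <- generate_genome(spec, "P_glacialis")

genome_stats(g$assembly)
#>   n_contigs total_length_bp gc_percent
#> 1         2          160000   59.64937

orfs <- classify_smorfs(find_orfs(g$assembly), g$cds)
table(orfs$position_class)
#>    3'SmORF    5'SmORF   CDSSmORF intergenic
#>        658        698        497       1260

prof <- flexibility_profile(g$cds$cds_id, g$cds$peptide)
head(prof[, c("protein_id", "vf_percent", "vmf_percent")], 3)
#>           protein_id vf_percent vmf_percent
#> 1 P_glacialis_cds001   28.57143    68.57143
#> 2 P_glacialis_cds002   31.50685    75.34247
#> 3 P_glacialis_cds003   30.93525    78.41727

gr <- generate_growth_curves(spec, "P_glacialis")
estimate_growth_params(gr$curves)
#> Growth parameters (Gr = exponential-phase log-slope per input time unit)
#>   P_glacialis (OTG 15):
#>         4: Gr 0.0304 +/- 0.0085  max A600(exp) 0.140
#>        10: Gr 0.1350 +/- 0.0071  max A600(exp) 0.387
#>        15: Gr 0.1581 +/- 0.0187  max A600(exp) 0.504
#>        20: Gr 0.1160 +/- 0.0289  max A600(exp) 0.378
#>        25: Gr 0.0528 +/- 0.0080  max A600(exp) 0.167
#>        30: Gr 0.0222 +/- 0.0317  max A600(exp) 0.115

d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
            dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
ape::write.tree(neighbor_joining(d))
#> [1] "(A:1,B:1,C:3);"
```

Reading the output: the synthetic *P. glacialis* genome (two 80 kb contigs,
GC ≈ 59.6%) yields ~3,100 smORFs dominated by intergenic and flanking
classes; per-CDS Vf percentages sit near the planted 30% baseline; the
growth-parameter table recovers the planted optimum at 15 °C with the
peak rate ≈ 0.16/day (planted 0.175, triplicates with absorbance noise);
and neighbor joining solves the three-taxon distance matrix exactly.

On real data, replace the generator calls with `read_genome_fasta()`,
`read_cds_gff3()` and `read_growth_tsv()`, then proceed with the same
functions; `compare_flexibility()`, `significance_heatmap()`,
`cluster_entities()` and `delta_regression()` chain the per-CDS profiles
into the cross-species comparison, and `select_common_proteins()`,
`star_align()`, `concatenate_alignments()` and `bootstrap_tree()` build the
multigene phylogeny.

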