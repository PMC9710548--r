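# chimpr

Multi-label cell typing for jointly profiled scRNA-seq/CITE-seq single-cell
data.

## What it does

Cell typing from a transcriptome alone bleeds evidence across
phenotypically adjacent populations (cytotoxic T cells vs NK cells);
surface-protein (ADT) markers alone say nothing about a cell's
transcriptional program and are shared across lineages. `chimpr`
integrates the two modalities multiplicatively:

1. **Transcriptome scores.** Each cell type is a weighted gene set
   (weights = reference log fold changes). Each cell gets a
   variance-adjusted squared distance
   `d²_c = Σ_j w_j x²_{cj} / σ̂²_j`
   on Z-scored log-normalized expression, calibrated against a
   permutation null via a moment-fitted gamma distribution; the reported
   score is the gamma CDF value in [0, 1].
2. **Protein bits.** Each ADT marker is split into low/high clusters by
   *exactly* minimizing the two-cluster within-cluster sum of squares (a
   scan over sorted split points — the objective 2-means targets, solved
   without seeds). A type with several sufficient markers takes the OR of
   its markers' high calls.
3. **Integration.** `chimp = camml × bit`. Since bits are 0/1, the
   integrated score can never exceed the transcriptome score: protein
   evidence vetoes, never inflates. The package treats this inequality as
   an exact invariant.

Also included: the continuous eCDF protein baseline and the
median-split baseline, single-label assignment with
proportion comparison (Pearson r, t-based p, MSE), one-vs-rest Wilcoxon
marker detection with scale-aware effect sizes, a modified Shannon
diversity index (`mSDI = −Σ pᵢ ln pᵢ` over ε-smoothed score proportions,
ε = 0.001) for per-cell label entropy, the QC/normalization pipeline
(detected-gene and mitochondrial filters, log-normalization, CLR,
Z-scaling), 10x-style MTX / GMT / marker-map IO, and a synthetic
joint-modality generator with known ground truth.

## Worked example

```r
library(chimpr)

cfg <- sim_config(n_cells = 1000)          # 5 PBMC-like types, known truth
sim <- simulate_joint(cfg, seed = 42)
sim$rna
#> CountMatrix [RNA]: 535 features x 1000 cells, 288417 nonzeros

rna  <- filter_genes_min_cells(
          qc_filter_cells(sim$rna, min_genes = 100, max_mito_frac = 0.05)$counts,
          min_cells = 5)
norm <- zscore_scale(lognormalize_rna(rna))

# weighted sets from a labeled reference: logFC > 5, intersected with
# curated collections, weighted by logFC
ref  <- simulate_reference(cfg, seed = 43)
tc   <- truth_collections(sim$truth)
sets <- build_weighted_sets(ref, tc$collections, tc$type_map)
sets[[1]]
#> WeightedGeneSet 'Tcell': 25 genes, weight range [5.57, 6.4]

camml <- score_cell_types(norm, sets, n_perm = 100, seed = 42)
adt   <- count_matrix(sim$adt$values[, rna$cell_ids],
                      feature_ids = sim$adt$feature_ids,
                      cell_ids = rna$cell_ids, modality = "ADT")
bits  <- cite_binary_scores(adt, sim$truth$marker_map,
                            types = camml$type_names)
chimp <- combine_scores(camml, bits)
round(chimp$values[1:3, ], 3)
#>            Tcell Monocyte Bcell    NK DC
#> cell-00001 0.316    0.005     0 1.000  0
#> cell-00002 0.002    0.001     0 1.000  0
#> cell-00003 0.992    0.000     0 0.012  0

labels <- assign_single_label(chimp, tiebreak_scores = camml)
table(labels$label)
#>    Bcell       DC Monocyte       NK    Tcell
#>      177       97      258      118      350

msdi(chimp)
#> MsdiResult: 1000 cells, R = 5, epsilon = 0.001, median = 0.2043

compare_proportions(labels, setNames(cfg$types$prop, cfg$types$name),
                    types = cfg$types$name)
#> ProportionComparison: r = 0.990 (p = 0.00126), MSE = 0.0001852
```

The first score row reads: cell-00001 carries strong NK evidence in both
modalities (score 1.0), weak T-cell evidence (0.316), and its B/DC bits
were vetoed to exactly 0 by the protein calls. The mSDI median of ~0.2
(max ln 5 ≈ 1.61) says most cells are confidently single-typed.

`run_pipeline()` wires all stages (simulate/QC/normalize/sets/score/
discretize/integrate/label/entropy) from a YAML config and writes every
stage artifact plus a reproducibility manifest; a thin CLI wrapper lives
at `inst/cli/chimp.R` with one subcommand per stage.

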