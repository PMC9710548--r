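# Default synthetic joint scRNA-seq/CITE-seq configuration (v1).
# Five PBMC-like populations, type-specific 25-gene modules at fold
# change 2^6, bimodal ADT markers with biologically real cross-type
# positivity. The qc block holds desk-scale thresholds matched to the
# simulated genome size.
n_cells: 5000
intermediate_frac: 0.05
fold_change: 64
module_size: 25
module_base_mean: 1
n_background_genes: 400
nb_size: 2
libsize_sigma: 0.3
n_mito_genes: 10
mito_frac: 0.02
seed: 1
types:
- name: Tcell
  prop: 0.35
- name: Monocyte
  prop: 0.25
- name: Bcell
  prop: 0.20
- name: NK
  prop: 0.10
- name: DC
  prop: 0.10
markers:
- {marker: CD3,    low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Tcell]}
- {marker: CD8,    low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Tcell, NK]}
- {marker: CD2,    low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Tcell, NK]}
- {marker: CD56,   low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [NK]}
- {marker: CD16,   low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [NK, Monocyte]}
- {marker: CD14,   low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Monocyte]}
- {marker: CD11b,  low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Monocyte, NK, DC]}
- {marker: CD19,   low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Bcell]}
- {marker: CD20,   low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Bcell]}
- {marker: HLA-DR, low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [Bcell, Monocyte, DC]}
- {marker: CD11c,  low_mean: 8, low_size: 4, high_mean: 150, high_size: 25, positive_types: [DC, Monocyte]}
marker_map:
  Tcell: [CD3, CD8]
  Monocyte: [CD14, CD11b]
  Bcell: [CD19, CD20, HLA-DR]
  NK: [CD56, CD2]
  DC: [CD11c, HLA-DR]
qc:
  min_genes: 100
  max_mito_frac: 0.05
  min_cells: 5
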