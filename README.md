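# geppi — protein–protein interaction prediction from graph-energy sequence descriptors

`geppi` predicts protein–protein interactions (PPIs) from amino-acid
sequence alone, for researchers who need a sequence-only predictor or a
reference implementation of graph-energy sequence encoding. Each protein
is described by three fused blocks:

- **PGE** (physicochemical graph energy, 200 entries): the sequence is
  one-hot encoded over a fixed isoelectric-point ordering of the 20
  residues; a 20-residue window slides one position at a time, each
  20×20 window matrix `M` is read as the biadjacency matrix of a
  bipartite graph, and the window's value is the graph energy
  `E = Σᵢ|λᵢ| = 2·Σ σ(M)` (sum of singular values), zero-padded to 200
  windows;
- **CGE** (contact graph energy, 200 entries): the same construction over
  a real-valued 20×20 amino-acid contact-energy matrix;
- **dipeptide composition** (400 entries): `f_mn = N_mn/(L−1)` over the
  400 ordered adjacent residue pairs.

Fused 800-entry descriptors are standardized and PCA-reduced to `d`
dimensions (default 80), pairs are concatenated to `2d` entries, and a
**weighted sparse representation classifier** assigns the label: a test
pair `y` is coded over the L2-normalized training dictionary `X` by

```
min ‖Wβ‖₁   subject to   ‖y − Xβ‖₂ ≤ ε
```

with Gaussian-kernel locality weights `W`, and classified by minimum
class-restricted residual `r_c = ‖y − Xβ_c‖₂`. The constrained problem is
solved by an ADMM solver with an exact residual-ball projection in the
dictionary's SVD basis and a sign-fixed support polish. Evaluation is
stratified 5-fold cross-validation reporting ACC, SEN, Pre, MCC and AUC.

The bundled contact matrix (`inst/extdata/contact_energy_synthetic.tsv`)
is a clearly labelled **synthetic stand-in** built from the Kyte–Doolittle
hydropathy scale; supply measured contact energies through
`load_contact_matrix()` for scientific use.

## Worked example

Generate a synthetic dataset with a planted compositional interaction
signal and cross-validate the full pipeline:

```r
library(geppi)

spec <- synthetic_spec(n_pos = 100, n_neg = 100,
                       length_range = c(120, 250),
                       delta = 0.5, seed = 11)
ds <- generate_dataset(spec, "demo.fasta", "demo_pairs.tsv")

report <- cross_validate(ds$pairs, ds$proteins, k = 5, seed = 11)
print(report)
```

```
Cross-validated PPI prediction (5 folds)

          acc sen    mcc    pre   auc
1        97.5  95  95.12 100.00 100.0
2       100.0 100 100.00 100.00 100.0
3        92.5  95  85.11  90.48  98.5
4       100.0 100 100.00 100.00 100.0
5       100.0 100 100.00 100.00 100.0
Average  98.0  98  96.05  98.10  99.7

(values in %)
```

Each row is one held-out fold of 40 pairs; `Average` mirrors the usual
benchmark-table layout. Accuracy near 98% and AUC near 100% mean the
planted composition signal survives feature extraction, reduction and
classification; on null data (`delta = 0`) the same pipeline stays at
chance (~50%), confirming the harness does not leak. Scores written by
`write_predictions()` are residual margins — positive means
interaction-like.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/`:

```sh
Rscript inst/cli/geppi simulate   --out-dir run1 --delta 0.5 --seed 11
Rscript inst/cli/geppi train-eval --fasta run1/synthetic.fasta \
    --pairs run1/synthetic_pairs.tsv --out-dir run1
```

## Package layout

- `R/` — sequence I/O (Biostrings-backed FASTA, pair lists), descriptors,
  PCA reduction, WSRC, CV harness, synthetic generator, pipeline commands
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (dense eigensolver, brute-force AUC, glmnet)
- `vignettes/graph-energy-ppi.Rmd` — the methods vignette: model,
  parameter choices, solver details, generator scope and limitations
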