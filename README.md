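# ovsubtype

Molecular subtype classification of high-grade serous ovarian carcinoma
(HGSC) from RNA-seq counts — bulk samples, single cells, and spatial
transcriptomics spots with one model.

HGSC tumors fall into four expression-defined molecular subtypes:
differentiated (D), immunoreactive (I), mesenchymal (M) and proliferative
(P). The classifiers that defined these subtypes were built on microarrays
and transfer poorly to sequencing counts, and not at all to sparse
single-cell or spatial data. `ovsubtype` implements a counts-native
workflow:

1. **Signature selection.** TMM-normalized log2 CPM; ten differential-
   expression designs (each subtype vs. the rest, plus all six pairs), each
   scored with a Mann–Whitney U test and a negative-binomial
   quasi-likelihood F-test with Benjamini–Hochberg correction; the union of
   DE genes is filtered to genes detected across platforms and marked up by
   subtype bipartition (D vs other, DI vs MP, DM vs IP, DP vs IM, up/down).
2. **Control-gene normalization.** Four stable, highly expressed control
   genes (non-DE, ≥ 7 log2 CPM, lowest coefficient of variation) serve as
   in-sample references: every classifier feature is
   `log2CPM(gene) − log2CPM(control)`, which cancels per-sample global
   shifts from platform, batch, or depth.
3. **Four-channel neural network.** One fully connected network per control
   gene — 10 hidden layers (750…50 neurons), swish activations, four-way
   softmax — trained with adam (learning rate 0.003, categorical
   cross-entropy, ≤ 500 epochs) on a stratified 2:1 train/test split, with
   per-epoch checkpointing and best-validation-epoch restoration; the four
   softmax outputs are averaged. Training samples are additionally rendered
   as depth-downsampled spot-like and cell-like views so the model learns
   the detection floor of sparse units.
4. **Application.** Bulk samples are scored directly; single cells and
   Visium spots go through a sparse-tolerant path (no TMM across cells,
   control-gene dropout fallback, explicit rejection of units with too few
   detected panel genes), then unit calls are aggregated into per-sample
   subtype proportions and spatial area fractions with mixed-signature and
   co-dominance flags.

A synthetic count generator (`simulate_bulk`, `simulate_sc`,
`simulate_spatial`) with planted subtype modules, housekeeping genes,
library-size variation and dropout provides ground truth for every stage;
the whole pipeline is validated offline at desk scale.

## Worked example

```r
library(ovsubtype)

# a labeled synthetic bulk cohort (413 samples: 108 D, 91 I, 98 M, 116 P)
sim     <- simulate_bulk(sim_config(seed = 1))
factors <- tmm_factors(sim$counts)
expr    <- log2cpm(sim$counts, factors)

# ten DE designs -> signature panel with 4 control genes
de    <- run_all_designs(expr, sim$counts, sim$labels, factors = factors)
panel <- build_panel(de, expr, sim$labels)
panel
#> ov_panel: 552 signature genes, 4 control genes (G00359, G00373, G00363, G00358)

# four-channel model, stratified 2:1 split, held-out evaluation
model <- train_subtype_model(sim$counts, sim$labels, panel,
                             config = train_config(seed = 1))
model
#> ov_model: four-channel subtype classifier
#>   signature genes: 552; control genes: G00359, G00373, G00363, G00358
#>   channel G00359     best epoch  10 (validation kappa 0.906)
#>   channel G00373     best epoch  25 (validation kappa 0.849)
#>   channel G00363     best epoch  10 (validation kappa 0.848)
#>   channel G00358     best epoch  20 (validation kappa 0.866)
#>   held-out: accuracy 1.000, kappa 1.000, macro AUC 1.000

# classify new units; spots/cells take the sparse path automatically
sp    <- simulate_spatial(sim$truth$config,
                          region_map_fractions(20, 20, c(I = 0.38, M = 0.35,
                                                         D = 0.27)),
                          genes = sim$truth$genes)
calls <- predict_cells(model, sp$counts)
spatial_report(calls, sp$coords)$area_fractions
#>    D    I    M    P
#> 0.27 0.38 0.35 0.00
aggregate_sample(calls, "section")
#>   sample_id prop_D prop_I prop_M prop_P dominant secondary secondary_prop
#> 1   section   0.27   0.38   0.35      0        I         M           0.35
#>   n_units co_dominant
#> 1     400        TRUE
```

The held-out metrics are printed by `summary(model)`; per-unit calls carry
the four probabilities, the argmax label, and a `mixed` flag raised when a
second subtype's probability reaches 0.2 — the bulk-sample signature of a
tumor containing regions of more than one subtype. Exact panel sizes and
epoch numbers vary with the seed; the validation kappas above are scored on
a mixed bulk + downsampled-view validation set, which is why they sit below
the held-out bulk accuracy. Passing auxiliary single-cell/spatial count
matrices as expression masks to `build_panel()` (as `ov_cli`'s `signature
--aux-counts` does) trims the panel to cross-platform-detectable genes.

There is also a command-line front end:

```sh
inst/scripts/ovsubtype simulate --modality bulk --out-dir sim --seed 1
inst/scripts/ovsubtype signature --counts sim/counts.tsv --labels sim/labels.tsv \
    --out-panel panel.tsv
inst/scripts/ovsubtype train --counts sim/counts.tsv --labels sim/labels.tsv \
    --panel panel.tsv --out-model model/
inst/scripts/ovsubtype predict --model model/ --counts sim/counts.tsv \
    --out predictions.tsv
```

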