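# drvae

Semi-supervised variational autoencoders for drug response prediction with
joint modeling of drug-induced transcriptomic perturbations.

## What problem this solves

Predicting whether a cancer cell line responds to a drug from its
pre-treatment gene expression is a small-n / large-p problem: viability
screens label only a few hundred cell lines per drug against ~1000 landmark
genes. Perturbation assays — matched vehicle-control and drug-treated
expression profiles — are plentiful but mostly unlabeled. `drvae`
implements **Dr.VAE**, a deep generative model that uses both at once, for
researchers in pharmacogenomics and machine learning for drug discovery.

The model couples three parts, trained end to end:

- a shared encoder/decoder embedding expression profiles `x1` (pre) and
  `x2` (post) into one latent space (`z1`, `z2`),
- a **latent linear perturbation** `p(z2 | z1)` with mean
  `z1 + W z1 + b` (initialized as the identity map),
- a linear softmax response classifier on `[z1, z2 - z1]`.

The generative factorization is

```
p(x1, x2, z1, z2, z3, y) =
  p(x1 | z1) p(x2 | z2) p(z2 | z1) p(z1 | z3, y) p(z3) p(y)
```

with diagonal-Gaussian conditionals, a standard-normal `p(z3)` and a
uniform binary `p(y)`. Training maximizes the sum of four evidence lower
bounds — labeled/unlabeled perturbation pairs and labeled/unlabeled
pre-treatment singletons — plus a weighted classifier cross-entropy, by
Adam on reparameterized single-sample gradients (the package ships its own
reverse-mode autodiff over dense matrix operations). Ablations included:
**SSVAE** (no perturbation branch), **PertVAE** (unsupervised perturbation
model used as an embedding), and the **identity-perturbation** model
("w/I", `set_identity_perturbation()`).

Also implemented: the preprocessing pipeline (case-control matching by
batch/bead, Pearson pair filtering, per-gene standardization, first-PC
removal, waterfall binarization of AAC drug sensitivity, drug selection
rules), the grouped/stratified repeated cross-validation protocol with
AUROC/AUPR and paired one-sided Wilcoxon comparisons, the
effect-to-replicate variance ratio (ERVR), and a seeded synthetic
pharmacogenomic generator with known ground truth that makes the whole
system testable offline.

## Worked example

Simulate a single-drug cohort (150 perturbation pairs, half labeled, 120
labeled singletons, 50 genes), fit Dr.VAE, and compare post-treatment
prediction with the identity-perturbation ablation:

```r
library(drvae)

cfg_data <- synthetic_config(n_genes = 50, latent_dim_true = 2,
                             n_cell_lines_pairs = 150, n_singletons = 120,
                             effect_scale = 1.5, noise_sd_gene = 0.1,
                             decoder_gain = 0.2, seed = 7)
ds <- synthetic_generate(cfg_data)
batch <- as_drvae_batch(ds)
batch
#> <drvae_batch: 150 pairs (75 labeled), 120 singletons (120 labeled), 50 genes>

ev  <- synthetic_eval_pairs(ds, 100, seed = 8)   # held-out pairs
val <- drvae_batch(x1_pairs = ev$x1[1:30, ], x2_pairs = ev$x2[1:30, ])

cfg <- drvae_config(n_genes = 50, latent_dim = 8, z3_dim = 8,
                    hidden_codec = 32, hidden_aux = 16,
                    class_loss_weights = 10, batch_size = 64,
                    max_epochs = 60, patience = 15, learning_rate = 3e-3)
model <- drvae_fit(batch, val, cfg, seed = 9)

pred    <- predict_posttreatment(ev$x1[31:100, ], model)
pred_id <- predict_posttreatment(ev$x1[31:100, ],
                                 set_identity_perturbation(model))
c(drvae    = rmse_pred(pred,    ev$x2[31:100, ]),
  identity = rmse_pred(pred_id, ev$x2[31:100, ]))
#>     drvae  identity
#> 0.1818377 0.3702785

pr <- predict_response(batch$x1_singletons, model)
auroc(pr$prob_sensitive, batch$y_singletons)
#> [1] 0.9909502
```

The trained perturbation map halves the post-treatment prediction RMSE
relative to plain reconstruction (0.18 vs 0.37 on held-out pairs), showing
the latent drug effect was actually learned; the response classifier
reaches AUROC 0.99 on this clean synthetic cohort.

A thin command-line front end over the same functions is in
`inst/cli/drvae.R` (subcommands `simulate`, `preprocess`, `train`,
`predict`, `ablate-identity`, `evaluate`, `compare`).

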