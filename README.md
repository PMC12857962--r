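# graphDDI

Predicts drug–drug interactions (DDIs) — clinically relevant effects of
co-administering two drugs — from molecular structure alone. Each drug
is parsed from its SMILES string into a heavy-atom molecular graph
G = (V, E, X_v, X_e) and encoded by a graph transformer whose attention
logits carry a learned bias keyed on *chemical distance* (the
shortest-path bond distance between atoms):

    Attention(Q, K, V, S) = softmax((QK^T + S) / sqrt(d_k)) V

Atom states are pooled hierarchically (atoms → differentiable-pooling
clusters → a global-attention molecule vector), fused with a trainable
character-level SMILES sequence encoder through cross-attention and an
adaptive sigmoid gate (h_final = λ·h_graph + (1−λ)·h_smiles), and drug
pairs are classified by an MLP over
[h_i; h_j; h_i⊙h_j; |h_i−h_j|]. Representations are pretrained
contrastively with four valence-preserving molecular augmentations
(atom masking, bond perturbation, subgraph sampling, scaffold hopping),
an NT-Xent objective at temperature 0.1, and cosine-similarity hard
negative mining. The training objective is

    L_total = L_DDI + α·L_contrastive + β·L_reg   (α = 0.5, β = 1e-5)

optimized in three phases (contrastive pretrain → joint → fine-tune).
All neural components run on a small reverse-mode autodiff engine
included in the package; no deep-learning framework is required.

The package also ships a download-free synthetic benchmark: a fragment
grammar generates valence-valid molecules, and a deterministic
functional-group rule labels pairs (amine × carboxyl, or two aromatics
with a halogen), so the whole pipeline is exercisable and testable at
desk scale. See the methods vignette
(`vignettes/graphDDI-methods.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(graphDDI)

## synthetic benchmark: 60 drugs, 300 balanced rule-labeled pairs
ds <- generateDataset(generatorConfig(n_drugs = 60, n_pairs = 300, seed = 7))
split <- makeSplit(ds$pairs, ds$drugs, "transductive", seed = 7)

## scaled-down model, short schedule
cfg <- runConfig(d_model = 64, n_layers = 2, n_heads = 2, d_bert = 32,
                 head_dims = c(256, 64), batch_size = 32,
                 hard_negative_k = 8, phase1_epochs = 1,
                 phase2_epochs = 3, phase3_epochs = 1, seed = 7)
fit <- trainModel(ds$drugs, split, cfg)
met <- evaluateModel(fit$model, ds$drugs, split$test)
round(c(ACC = met$ACC, AUC = met$AUC, F1 = met$F1), 3)
#>   ACC   AUC    F1
#> 0.750 0.912 0.800
```

Even after this deliberately tiny schedule (5 epochs total on 180
training pairs) the model ranks held-out interacting pairs well above
non-interacting ones (AUC 0.91); the full desk-scale run in
`scripts/acceptance.R` (300 drugs, 3000 pairs, 5/20/5 epochs) reaches
training accuracy around 0.95 and held-out AUC above 0.98 (seed 1:
train ACC 0.949, test ACC 0.935, test AUC 0.985). Individual
pieces are exposed too:

```r
g <- parseSmiles("CC(=O)O")          # acetic acid: 4 atoms, 3 bonds
chemicalDistance(g)$dist[1, 4]       # topological distance methyl -> OH oxygen
#> [1] 2
functionalGroups(g)$type
#> [1] "carboxyl"
interactionRule(parseSmiles("CCN"), g)   # amine x carboxyl
#> [1] 1
```

A command-line entry point mirrors the R API
(`inst/cli/graphddi.R`): `simulate`, `augment`, `pretrain`, `train`,
`evaluate`, `predict`, `ablate`.

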