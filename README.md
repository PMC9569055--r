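# mspcd

Predicting circRNA–disease associations by multi-source similarity fusion and
a hierarchical neural network.

Circular RNAs (circRNAs) regulate disease processes, and confirmed
circRNA–disease associations are scarce because each one requires wet-lab
validation. `mspcd` ranks unobserved circRNA–disease pairs so that laboratory
effort can be spent on the most promising candidates. It is aimed at
computational biologists who have a binary association table plus whatever
auxiliary biology is available — circRNA sequences, GO/miRNA annotations, a
disease term hierarchy — and want a reproducible, scriptable predictor with an
honest evaluation protocol.

## Method

Given the binary association matrix `S_d` (rows = circRNAs, columns =
diseases), the package builds five similarity models:

* **CS** — sequence similarity `(l_m + l_n − d(c_m, c_n)) / (l_m + l_n)` from
  the weighted Levenshtein distance `d` (insert/delete 1, substitute 2);
* **CF** — mean Jaccard similarity of the circRNAs' disease, GO and miRNA
  association profiles;
* **CG**, **DG** — Gaussian interaction profile kernels
  `exp(−δ‖p_m − p_n‖²)` over the rows and columns of `S_d`, with data-driven
  bandwidth δ;
* **DS1**, **DS2** — disease semantic similarities over a directed acyclic
  hierarchy, with ancestor contributions decaying by μ = 0.5 per layer (DS1)
  or weighted by term rarity `log(n_dis / n_DAGs(k))` (DS2).

Availability flags gate the fusion: `CV = (CS + CF)/2` where both circRNAs
have sequences, else `CG`; `DV = (DS1 + DS2)/2` where both diseases are in the
hierarchy, else `DG`. A pair (i, j) is then scored by a hierarchical network:
two three-layer ReLU towers map the raw rows `CV[i, ]` and `DV[j, ]` to
high-order features `CH` and `DH`; the element-wise product `CD = CH ⊙ DH`
and the concatenation `[CH; CD; DH]` feed a ReLU–ReLU–sigmoid head that
outputs the association probability. Training is mini-batch Adam on binary
cross-entropy with an L2 weight penalty, fully seeded.

Evaluation tooling includes balanced negative sampling, stratified k-fold
cross-validation, a 20% independent split, AUC/accuracy/precision/recall/F1,
a baseline harness (random forest, SVM, feedforward net on cascaded
similarity rows), and top-k ranking of unknown pairs. A synthetic-data
generator with planted block structure makes the whole pipeline testable
without any external download.

## Worked example

```r
library(mspcd)

data <- generate_dataset(synthetic_config(n_circ = 60, n_disease = 18,
                                          n_blocks = 3, seq_len = 60, seed = 42))
data$Sd
#> assoc_matrix: 60 x 18, 111 associations (density 0.1028)

feats <- build_features(data$Sd, data$Sg, data$Sm, data$seqs, data$dag)
feats$CV
#> sim_matrix: 60 x 60, range [3.736e-07, 1]

cfg <- model_config(highorder_dim = 16, tower_hidden = c(64, 32),
                    head_hidden = c(32, 16), epochs = 60, seed = 42)
res <- run_cross_validation(data$Sd, data$Sg, data$Sm, data$seqs, data$dag,
                            model_config = cfg, k = 5, seed = 42)
res$average
#> AUC 0.8450 | acc 0.7841 | prec 0.7615 | rec 0.8292 | F1 0.7930

model <- train_model(feats$CV, feats$DV, res$dataset, cfg)
rank_candidates(model, data$Sd, feats$CV, feats$DV, top_k = 5)
#>     circrna     disease     score
#> 1 circ_0019 disease_001 0.9738857
#> 2 circ_0039 disease_009 0.9731061
#> 3 circ_0012 disease_003 0.9721327
#> 4 circ_0039 disease_007 0.9689970
#> 5 circ_0024 disease_007 0.9641142
```

The cross-validated AUC of 0.845 says that on held-out pairs a true
association outranks a sampled non-association about 84.5% of the time at
this reduced problem size (the default 300 × 40 configuration scores higher;
see the vignette). The ranking lists the five unobserved pairs the trained
model considers most likely to be real associations — the analogue of a
literature-validation shortlist.

The same pipeline is available from the shell (`exec/mspcd`):

```sh
mspcd simulate --out data/ --seed 1
mspcd crossval --data data/ --out runs/cv --seed 1
mspcd predict  --data data/ --out runs/pred --top-k 15 --seed 1
```

Every run writes a `manifest.json` (resolved options, seed, convention
choices, package version) that fully determines its outputs.

## Documentation

The methods vignette (`vignettes/mspcd-methods.Rmd`) documents the model and
its assumptions, every convention choice (GIP bandwidth form, semantic-model
denominator, log base), the leakage semantics of the default vs `--strict-cv`
protocols, what the synthetic generator does and does not emulate, and known
limitations.
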