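---
title: "Multi-source similarity fusion and hierarchical neural networks for circRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mspcd methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspcd)
```

## The problem

Circular RNAs (circRNAs) are covalently closed non-coding RNAs implicated in a
growing list of diseases, largely through interactions with disease-related
miRNAs. Experimentally confirming a circRNA-disease association is slow and
expensive, so computational ranking of candidate associations is used to
prioritize laboratory work. `mspcd` treats the problem as supervised link
prediction on a bipartite graph: given a binary circRNA x disease association
matrix $S_d$ plus auxiliary biology (circRNA nucleotide sequences, circRNA-GO
and circRNA-miRNA annotation tables, and a disease term hierarchy), score
every unobserved pair.

The pipeline has three stages: (1) five similarity models turn the raw inputs
into circRNA-circRNA and disease-disease similarity matrices; (2) a flag-gated
fusion combines them into one feature matrix per entity type; (3) a
hierarchical neural network maps each (circRNA row, disease row) pair to an
association probability.

## The five similarity models

**Sequence similarity (CS).** For circRNAs $c_m, c_n$ with sequences of
lengths $l_m, l_n$,
$$CS(c_m, c_n) = \frac{l_m + l_n - d(c_m, c_n)}{l_m + l_n},$$
where $d$ is the weighted Levenshtein distance with insertion/deletion cost 1
and substitution cost 2. Under this cost scheme
$d(a,b) = l_a + l_b - 2\,\mathrm{LCS}(a,b)$, which the test suite verifies
against an independent longest-common-subsequence dynamic program. Distances
are computed by `utils::adist`; ambiguity characters (N etc.) are kept as
literal symbols. Pairs where either circRNA lacks a sequence get a placeholder
0 and are masked by the fusion flags.

**Functional similarity (CF).** The mean of three Jaccard coefficients between
the circRNAs' binary profiles: rows of $S_d$ (diseases), $S_g$ (GO terms) and
$S_m$ (miRNAs). A Jaccard with an empty union is defined as 0 rather than NaN,
so annotation-poor circRNAs stay in the analysis; a consequence, documented
deliberately, is that $CF(c,c) < 1$ is possible for a circRNA with an empty
annotation row, and the fused diagonal is then $(1 + CF(c,c))/2 < 1$. We do
not force the diagonal to 1: the matrix is consumed row-wise as a feature
vector, not as a kernel.

**GIP kernels (CG, DG).** Gaussian interaction profile kernels over the rows
(circRNAs) and columns (diseases) of $S_d$:
$K(m,n) = \exp(-\delta\,\lVert p_m - p_n\rVert^2)$. The bandwidth is
data-driven. Two conventions are implemented: the default sets $\delta$ to the
*mean squared profile norm* and uses it directly as the multiplier; the
`reciprocal` option uses its reciprocal, the form common elsewhere in the GIP
literature, which makes the kernel scale-free in the profile density. Both are
exposed (`gip_params()`, `--gip-convention`) and every run manifest records the
choice; the default favors faithfulness to the published formula over
interoperability. All-zero profile sets raise a degenerate-bandwidth error
rather than returning a constant kernel.

**DAG semantic similarity (DS1, DS2).** Diseases are placed in a directed
acyclic hierarchy (e.g. MeSH-derived), edges parent to child. For a disease
$d$, its term set $N_d$ is $d$ plus all ancestors; the layer-decay
contribution is $G_d(d) = 1$ and
$G_d(k) = \max\{\mu\,G_d(k') : k' \in \mathrm{children}(k) \cap N_d\}$,
with $\mu = 0.5$ by default, so $G_d(k) = \mu^{\text{shortest path } k \to d}$.
Model 1 scores a pair by the shared terms' summed contributions normalized by
the two total contributions. Model 2 reweights terms by rarity,
$G'(k) = \log(n_{\text{dis}} / n_{\text{DAGs}}(k))$: a term present in every
covered disease's hierarchy contributes nothing. Three conventions here were
genuinely open and are resolved as follows, all configurable:

* the logarithm base is unspecified in the originating formulation; we default
  to the natural log, the convention of the semantic-similarity literature;
* $n_{\text{dis}}$ counts DAG-covered diseases (an uncovered disease has no
  term set to be counted in);
* the model-2 denominator: the printed form mixes rarity-weighted terms in the
  numerator with layer-decay sums in the denominator, which breaks the
  $[0,1]$ range and the unit diagonal. The default (`primed`) normalizes by
  the rarity-weighted sums, keeping DS2 in $[0,1]$ so that the fusion average
  with DS1 stays on one scale; `as_printed` reproduces the mixed form, and the
  fusion then warns (without clipping) if any fused value exceeds 1.

## Fusion

Binary flags record which auxiliary source is available: $FQ(m,n) = 1$ iff
both circRNAs have sequences, $FS(m,n) = 1$ iff both diseases are in the DAG
(diagonals follow the same both-covered rule). The fused matrices are
$$CV = \tfrac{1}{2}(CS + CF) \text{ where } FQ = 1, \text{ else } CG, \qquad
  DV = \tfrac{1}{2}(DS_1 + DS_2) \text{ where } FS = 1, \text{ else } DG.$$
Setting all flags to zero recovers the GIP kernels exactly, a property the
suite tests.

## The network

Each pair is scored from the raw rows $CV_{i\cdot}$ (length $n_c$) and
$DV_{j\cdot}$ (length $n_d$) — the similarities themselves are the input; no
standardization is applied. Two independent towers of three fully connected
ReLU layers (defaults $n_c \to 256 \to 128 \to N$ and
$n_d \to 256 \to 128 \to N$, $N = 64$) produce high-order features $CH$ and
$DH$; the element-wise product $CD = CH \odot DH$ captures multiplicative
co-occurrence; the concatenation $[CH; CD; DH]$ feeds a head of two ReLU
layers and a sigmoid unit (defaults $3N \to 128 \to 64 \to 1$). The hidden
widths are our choice (geometric tapers); the originating description fixes
only the depth, the activations and the high-order sweep grid
$N \in \{8, 16, 32, 64, 128\}$, over which performance is reported to be flat
for $N \ge 16$ — we default to 64, the grid midpoint.

Training minimizes binary cross-entropy plus an L2 penalty ($10^{-4}$ on all
weight matrices, biases unpenalized) by mini-batch Adam
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$), learning rate 0.001
and batch size 128 — the midpoints of the published tuning grids — for 200
epochs. The loss, optimizer and initialization (uniform Glorot) are likewise
our choices where the original description says only "DNN", "regularization"
and a sigmoid output; binary cross-entropy is the canonical likelihood for
that output, and a named, fully seeded initialization scheme is required by the
reproducibility contract: initialization and shuffling derive entirely from
`model_config()$seed`, and two runs with one seed give bitwise-identical loss
traces.

## Evaluation protocol

Positives are all ones of $S_d$; the same number of negatives is drawn
uniformly without replacement from the zero cells (a few of which may be
unverified true positives — at realistic sparsity this mislabeling is a
negligible fraction). Folds are stratified by label, with class remainders
staggered so fold sizes differ by at most one; the independent-split protocol
holds out $\lfloor 0.2 n \rfloor$ samples, stratified. Thresholded metrics use
cutoff 0.5 by default (the cutoff is configurable; the original description
leaves it unstated); recall is $TP/(TP+FN)$. AUC uses the rank-statistic form
(ties counted one half), verified against an all-pairs comparison oracle.

One protocol subtlety is reproduced deliberately: the similarity matrices —
including the GIP kernels, which read $S_d$ itself — are built from the *full*
association matrix before splitting. Validation positives therefore influence
the features, an information leak inherent to the mirrored pipeline order.
`strict = TRUE` (or `--strict-cv`) recomputes CG and DG per fold with the
validation positives zeroed, closing the leak at extra cost; the sequence,
functional and semantic models never read $S_d$'s held-out cells' labels
directly apart from CF's disease profile, which is part of the same leak and
is *not* recomputed (matching the mirrored order). Both numbers are honest
answers to different questions; the manifest records which was run.

Candidate ranking scores every zero cell and returns the top $k$ (default 15),
ties broken by (row, column) index so the output is reproducible.

## The synthetic data generator

Real circRNA-disease datasets cannot be redistributed here, so the package
ships a generator whose defaults define its reference study conditions: 300
circRNAs and 40 diseases in 6 paired blocks; associations
$\mathrm{Bernoulli}(0.30)$ within a paired block and $\mathrm{Bernoulli}(0.01)$
across (these bracket the published datasets' sparsity while leaving enough
positives, about 700, to train on); per-block ancestor sequences of 100 nt
with members point-mutated at rate 0.05 (substitution-only, so the expected
pairwise edit cost stays analytically predictable, roughly
$2 \times \text{rate} \times \text{length}$ under costs (1,1,2)); GO (120
terms) and miRNA (80) annotations drawn 80% from a per-block pool and 20%
from the background; a disease hierarchy built from a root, per-block ancestor
nodes and random within-block trees; and 10% of circRNAs without sequences
and 10% of diseases outside the DAG to exercise the fusion fallbacks. The
dataset is a pure function of the seed.

What the generator emulates is the *learnable structure* the method assumes —
functionally similar circRNAs associate with similar diseases, and every
similarity channel carries block signal. What it does not emulate: the heavy-
tailed degree distributions of curated databases, correlated annotation noise,
sequence homology unrelated to disease, or hierarchy depth heterogeneity.
Passing the recovery tests therefore demonstrates that the implementation
learns planted multi-channel structure end-to-end, not that it reproduces any
published real-data figure.

At these defaults a full five-fold run (similarity construction, five 200-epoch
trainings, evaluation) takes on the order of two to three minutes on one CPU
core; the unit tests use a further-reduced 60 x 18 dataset where meaningful
performance bars become unstable, so they assert mechanisms rather than AUC.

## Numerical choices and degenerate inputs

* Similarity matrices are validated symmetric within $10^{-9}$ and stored
  exactly symmetrized; matrix files carry 17 significant digits so write/read
  round trips are bit-exact.
* Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  cross-entropy only; predictions themselves are raw sigmoid outputs.
* Empty Jaccard unions give 0; zero semantic denominators give 0; all-zero GIP
  profile sets raise errors.
* Edit-distance identity matching, duplicate edges, cycles and self-loops in
  the DAG are rejected at parse time with named diagnostics.
* Identifier matching everywhere is exact and case-sensitive after trimming
  surrounding whitespace: silently case-folding identifiers like
  `hsa_circ_0067997` risks false merges.

## Known limitations

* The default (mirrored) cross-validation protocol lets the GIP features see
  held-out positives; use `strict = TRUE` for leak-free kernel features and
  expect lower numbers.
* Negative "labels" are unverified pairs, not confirmed non-associations;
  reported metrics inherit that assumption.
* Sequence similarity is global edit distance; it is not an alignment and will
  under-score pairs related by large rearrangements (an alignment-based model
  is explicitly out of scope).
* The model consumes similarity rows, so adding a new entity changes every
  feature vector's length; models are not transferable across datasets of
  different sizes.
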