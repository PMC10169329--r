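---
title: "Methods: Gaussian-kernel linear-optimization link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-kernel linear-optimization link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gklink)
```

## The problem

miRNAs silence transcripts post-transcriptionally; lncRNAs can sequester
miRNAs as competing endogenous RNAs. The experimentally confirmed
miRNA–lncRNA interaction map is sparse — a curated network of a few
hundred miRNAs and lncRNAs typically has 2–10% of its pairs observed — and
testing pairs at the bench is expensive. `gklink` treats the problem as
bipartite link prediction: use the structure of the observed network (and,
optionally, per-RNA side data) to rank the unobserved pairs.

The core modelling assumption is *profile smoothness*: two RNAs with
similar interaction profiles (or similar sequences, expression patterns,
or annotations) tend to interact with similar partners. Everything below
is machinery for encoding that assumption and exploiting it linearly.

## Similarity construction

Four interchangeable similarity sources feed the model; each yields a
symmetric matrix with unit diagonal and entries in [0, 1] (the contract
`check`ed at every boundary).

**Gaussian interaction-profile (GIP) kernel** (`profile = "network"`).
For profile rows $p_i$, $\mathrm{GKS}(i,j) = \exp(-\gamma\,\|p_i -
p_j\|^2)$ with $\gamma = n / \sum_i \|p_i\|^2$. The bandwidth is the
reciprocal *mean squared row norm*, which makes the kernel invariant to a
common rescaling of the profiles — there is no free bandwidth parameter.
Applied to rows of `Adj` it gives the miRNA similarity; to rows of `Adjᵀ`,
the lncRNA similarity. The exponent is the squared Euclidean distance;
with 0/1 profiles it counts non-shared partners.

**Sequence** (`profile = "sequence"`). Needleman–Wunsch global alignment
with affine gaps (match 2, mismatch 0, gap open −0.5, gap extend −0.1 per
base), computed by `Biostrings::pairwiseAlignment` over the RNA alphabet.
Raw scores are normalized by the geometric mean of the two self-scores and
clipped at 0, so identical sequences score 1 and unrelated ones near 0.
The mismatch score and the normalization are package choices: a mismatch
of 0 keeps all similarity weights nonnegative, and self-score
normalization is the standard way to make alignment scores of
different-length sequences comparable.

**Expression** (`profile = "expression"`). Pearson correlation between
expression vectors (≥ 2 conditions), clipped at 0. Negative correlations
are treated as "no similarity" rather than anti-similarity because the
integrated adjacency interprets every entry as a nonnegative edge weight;
a zero-variance vector is uninformative and gets off-diagonal 0.

**Functional annotations** (`profile = "function"`). Ochiai (cosine) set
similarity $|A \cap B| / \sqrt{|A|\,|B|}$ between annotation-term sets;
empty sets give 0.

Bio-profile collections are incomplete in practice. RNAs without a
profile record receive an identity-like similarity row via
`fill_missing()` — self-similarity 1, everything else 0 — so the model
falls back on the interaction structure for them instead of failing.
`profile = "none"` applies this to every RNA, reducing the model to pure
network structure with self-loops.

## The linear-optimization model

The similarities and interactions are stacked into one symmetric
$(m+l)\times(m+l)$ integrated adjacency
$Adj' = \begin{bmatrix}S_m & Adj\\ Adj^\top & S_l\end{bmatrix}$,
read as a weighted graph over all RNAs. The contribution matrix $C$
minimizes the convex ridge objective

$$F(C) \;=\; \alpha\,\|Adj' - Adj'C\|_F^2 \;+\; \|C\|_F^2 ,$$

i.e. each column of $C$ says how every vertex's connectivity pattern is
composed from the others', with an $L_2$ penalty keeping the composition
small. Setting the gradient
$\alpha(2\,Adj'^\top Adj'\,C - 2\,Adj'^\top Adj') + 2C$ to zero gives the
closed form $(\alpha\,Adj'^\top Adj' + I)\,C^* = \alpha\,Adj'^\top Adj'$.
The rating matrix $RS = Adj'\,C^*$ scores every vertex pair; its top-right
$m\times l$ block is the miRNA–lncRNA prediction surface. Because $C^*$ is
an analytic function of the symmetric $Adj'$, $RS$ is symmetric and the
top-right block equals the transpose of the bottom-left one —
`extract_scores()` asserts this at a $10^{-8}$ relative tolerance, so the
choice of block is immaterial and any violation flags numerical trouble.

For eigenvalues $\lambda$ of $Adj'$, the eigenvalues of $C^*$ are
$\alpha\lambda^2/(1+\alpha\lambda^2) \in [0, 1)$: the model shrinks every
spectral direction, most strongly the weak (noise) directions. This
identity is verified to $10^{-8}$ in the test suite and is the cleanest
way to see that the solve is well-conditioned for any $\alpha \ge 0$.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.007 | reconstruction weight; larger trusts the observed network more, smaller regularizes harder. Cross-validated AUC is flat near the default (see `alpha_sweep()`, grid 0.001–0.019, step 0.0015, 13 values), so the model is robust to this choice. |
| `profile` | `"network"` | similarity source; the network profile needs no side data and is the headline mode. |
| alignment scores | 2 / 0 / −0.5 / −0.1 | match, mismatch, gap-open, gap-extend for the sequence profile. |

### Numerical choices

The normal equations are solved by Cholesky factorization of
$\alpha\,Adj'^\top Adj' + I$ (symmetric positive definite for
$\alpha > 0$) with two triangular solves; no explicit inverse is formed.
$C^*$ is symmetrized ($\tfrac12(C + C^\top)$) to remove factorization
round-off, and non-finite values are rejected at every matrix boundary.
$\alpha = 0$ short-circuits to the zero model. Score ties in ranked output
are broken lexicographically by (miRNA, lncRNA) identifier so every output
file is deterministic.

## Cross-validation protocol

A *sample* is a positive edge; the unobserved pairs are never split. Per
repeat, the positives are shuffled and cut into $k$ folds whose sizes
differ by at most one (5118 positives at $k=5$ give folds of 1023–1024,
training complements of 4095). For each fold:

1. the fold's positives are set to 0 in the training adjacency;
2. when `profile = "network"`, the GIP similarities are **recomputed from
   the masked adjacency** — otherwise the held-out edges would leak into
   training through the kernel (bio-profile similarities do not depend on
   the adjacency and are reused);
3. the model is fitted and the held-out positives take their scores from
   this fold model, as do all never-positive pairs.

Pooling held-out positive scores and the per-fold negative scores yields
one AUC per repeat (midrank convention: a tie counts one half, exactly the
Mann–Whitney statistic), reported as mean ± sample standard deviation over
repeats. Repeat $r$ reseeds the generator with `seed + r − 1`, so any
repeat can be reproduced in isolation. The per-fold negative scoring and
pooled-AUC choices are package decisions where several conventions exist;
averaging per-fold AUCs instead changes results only marginally.

Leave-one-out CV masks each positive in turn and takes its score from its
own masked model; negatives are scored once by the model trained on all
positives. Refitting per negative pair would multiply the number of solves
by the number of negatives (hundreds of thousands at realistic sizes) and
was rejected; the documented consequence is a small protocol difference
from `k = n` k-fold CV, checked on a toy network in the test suite.

## The synthetic universe

Real curated interaction networks are not redistributable, so the package
ships a seeded generator whose defaults define the study conditions used
throughout the tests: a planted bipartite block model with $m=60$ miRNAs,
$l=100$ lncRNAs, 5 communities assigned round-robin (deterministic block
sizes), within-block edge probability 0.3 and cross-block probability
0.02 — about 8% density, the same sparsity regime as curated networks at a
size where the full CV harness runs in seconds. Block structure is exactly
the model's inductive bias, making recovery of masked within-block edges
the natural end-to-end check. Side data are generated block-consistently:
per-block ancestor sequences with i.i.d. substitutions (a substitution
always changes the base), per-block latent expression profiles plus
Gaussian noise, and per-block annotation-term pools sampled at a shared
fraction.

What the generator does *not* emulate: realistic miRNA/lncRNA lengths or
base composition, heavy-tailed degree distributions, expression
distributions of real tissues, or annotation ontology structure. Passing
tests therefore demonstrate that the machinery recovers planted structure
under its own assumptions — not field performance on any particular
curated database.

Two properties calibrate expectations at the default conditions, both
recomputed by `scripts/acceptance.R` at every run. First, cross-validated
recovery is partial: roughly a fifth of planted edges are cross-block
noise edges carrying no recoverable signal, and within blocks each miRNA
shares only a couple of partners with its peers, so the mean 5-fold CV AUC
sits in the 0.6–0.7 range rather than near the in-sample value. Second,
the margin over a shuffled-network control with identical edge count
(which hovers at chance) is the meaningful effect size, and it is what the
acceptance harness asserts alongside the absolute level.

## Problem sizes

The test suite works at deliberately small scales — similarity matrices up
to a few hundred RNAs, optimizer-oracle comparisons on 8×8 and 10×10
instances, CV on networks of 60×100 and below — chosen so each property is
checked in well under a minute while leaving the algebra identical to
full-scale runs. The dense Cholesky solve is comfortable to $m+l$ of a few
thousand; beyond that an iterative solver would be the next step and is
out of scope.

## Known limitations

- One profile at a time: the model has no learned weighting for fusing
  multiple similarity sources simultaneously.
- Negative evidence is absent: an unobserved pair is "unknown", never
  "known non-interacting", and the AUC convention inherits that.
- The dense solve scales cubically in $m+l$.
- Identifier matching between the edge list and side-data files is exact
  string matching; no alias resolution is attempted.
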