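---
title: "Methods: PERMA-guided multi-topology graph attention for student well-being"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PERMA-guided multi-topology graph attention for student well-being}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permanet)
```

## The problem

Student well-being is a latent, multi-dimensional construct. Seligman's
PERMA framework decomposes it into five dimensions — Positive emotions,
Engagement, Relationships, Meaning, Achievement — and treats overall
well-being as roughly the average level across them. `permanet` predicts,
from tabular behavioural features (learning behaviour, social interaction,
physical health and mental state blocks), both an overall well-being score
$\hat y_i \in (0,1)$ and the five dimension scores
$\hat y_i^{(p)} \in (0,1)$, while explicitly modelling relationships
*between* students: similar students tend to have similar well-being, and
which notion of similarity matters differs per student.

## Model

The pipeline has four stages.

**1. PERMA token embedding.** Raw features $x_i \in [0,1]^d$ are mapped in
two parallel ways: an interpretable linear score map
$H_{\mathrm{PERMA}} = XW + b$ with $W \in \mathbb R^{d\times 5}$, and a
token sequence — one token per PERMA dimension,
$t_p = \mathrm{lift}(\mathrm{GELU}(x^\top U_p + e_p))$, of model width
$m$. Keeping both resolves the tension between a 5-column interpretable
map and a wide embedding: the score map feeds reporting and the
PERMA-weighted graph, the tokens feed the transformer. Both are
initialized from a psychological prior: the score map is a convex
combination `strength * prior + (1 - strength) * Xavier`, and each $U_p$'s
feature rows are rescaled by the prior's relevance of that feature to
dimension $p$, so e.g. social-time features start out dominating the
Relationships token. No canonical feature-to-PERMA assignment exists for
survey instruments, so the prior is configurable; the default puts 0.6 of
each feature's mass on its block-dominant dimension(s) (learn → E/A,
social → R, physical → P, mental → P/M) and spreads the rest evenly.

**2. Four relationship graphs.** Over the same cohort we build four
thresholded, symmetric adjacencies: cosine similarity of features (angular
structure), a Gaussian kernel on Euclidean distances (overall feature
differences), a binary shared-learning-style graph, and a PERMA-weighted
graph $a_{ij} = \sum_p w_p\,\mathrm{sim}_p(x_i^{(p)}, x_j^{(p)})$ where
$x^{(p)}$ masks features by the prior's column $p$ and $\mathrm{sim}_p$ is
clipped cosine. Design choices worth stating:

* negative cosines are clipped to 0 before thresholding, so all four
  graphs share a $[0,1]$ weight scale and one threshold (default 0.3,
  closed: weights exactly at 0.3 survive) is meaningful across them;
* distances become similarities through a Gaussian kernel with the median
  nonzero pairwise distance as bandwidth — a monotone, bounded mapping
  that needs no per-dataset tuning; if all distances are zero the graph is
  complete with unit weights;
* graphs are dense matrices; cohorts here are at most tens of thousands
  of nodes.

**3. Relational encoding and fusion.** Per topology, three GCN layers
$H_{l} = \mathrm{ReLU}(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H_{l-1}
W_l)$ on the self-looped normalized adjacency, then one multi-head GAT
layer on the raw thresholded adjacency (LeakyReLU slope 0.2, softmax over
each node's neighbourhood including itself, ELU output, heads
concatenated). GCN runs first so the attention maps reflect already
smoothed representations. The four branch outputs are fused per student by
graph-level attention conditioned on embeddings of learning style and
stress level: $\beta = \mathrm{softmax}_k(v_k^\top \tanh(W_g[h_{style}\|
h_{stress}]+b_g))$. The scoring vectors $v_k$ start at zero, so every
student begins at exactly uniform weights $(0.25, 0.25, 0.25, 0.25)$ and
the fusion only departs from uniformity if the data demand it. $\beta$ is
per student and exported for inspection.

**4. PERMA-aligned transformer and heads.** The five tokens, residually
enhanced by the fused graph vector (a single-key cross-attention — with
one key/value per student the softmax is a singleton, so the update is
the value-projected graph vector itself), pass through a pre-norm
transformer encoder with exactly five attention heads, one per PERMA
dimension. Heads project $m \to 64$; their concatenation (320 wide for
the reference width 256) returns to $m$ through the output projection —
this preserves both stated widths rather than forcing
$5 \times 64 = 256$. Pre-norm blocks were chosen over post-norm for
stable training at 6 layers without warmup sensitivity. Global average
pooling over the five tokens feeds two sigmoid affine heads (overall and
5-dimensional). There is no CLS token; the sequence has a fixed,
meaningful length of 5.

**Loss.** $L = \lambda_1\,\mathrm{MSE}(\hat y, y) + \lambda_2\,
\overline{\mathrm{MSE}}(\hat Y, Y) + \lambda_3\,\mathrm{MSE}(\hat y,
\tfrac15\textstyle\sum_p \hat y^{(p)})$ with defaults
$\lambda = (1.0, 0.8, 0.5)$. The third term ties the overall prediction
to the mean of the dimension predictions — the structural assumption of
the PERMA framework — and involves predictions only, so it also acts on
unlabelled rows in principle (training here applies it to the batch).
The overall and per-dimension terms are squared error, consistent with
MAE/RMSE evaluation of labels on $[0,1]$.

## Training

AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, weight
decay $10^{-5}$), linear warmup then cosine annealing to $10^{-6}$,
gradient clipping at global norm 1.0, dropout 0.1 in attention and
feed-forward sublayers, early stopping on validation total loss with
patience 15, parameters restored from the best validation epoch. The
default learning rate is $10^{-4}$ (the sensitivity analyses identify it
as optimal over the alternatives, including $2\times 10^{-4}$). Splits
are stratified 7:2:1 by learning style × stress level (× culture when the
cohort is multi-cultural), per-stratum proportions within one sample,
strata smaller than 3 merged into the largest stratum.

Training is *transductive*: the four graphs are built once over the whole
cohort from features and metadata only (never labels), message passing
always runs over the full graph, and the loss reads only training-row
predictions; validation and test labels can therefore not leak into
gradients. Mini-batches index students for the loss while the forward
pass is full-graph.

Because no deep-learning framework is a dependency, gradients come from a
small reverse-mode autodiff tape written in base R (`R/autodiff.R`):
nodes record values and vector-Jacobian products in creation order and a
reverse sweep accumulates gradients. Its correctness is established by
finite-difference tests per primitive and on the full model loss, and the
eval-mode forward is bit-reproducible.

## Evaluation framework

Beyond MAE/RMSE on the overall score, three PERMA-specific metrics:

* **PDA** (dimension accuracy): $\tfrac15\sum_p (1 - \tfrac1n\sum_i
  |y_i^{(p)}-\hat y_i^{(p)}|)$;
* **PCI** (consistency index): $1 - \tfrac1n\sum_i |\hat y_i -
  \tfrac15\sum_p\hat y_i^{(p)}|$ — a function of predictions only;
* **PCE** (composite): $0.4\,\mathrm{PDA} + 0.3\,\mathrm{PCI} +
  0.3\,(1-\mathrm{RMSE}_{norm})$.

The normalized RMSE is defined here as RMSE divided by the label range
(1 for unit-interval labels), capped at 1 — this keeps PCE in $[0,1]$
and is dataset-independent; no canonical definition exists. The
consistency-violation rate reports the fraction of students with
$|\hat y_i - \tfrac15\sum_p \hat y_i^{(p)}| > \epsilon$; the tolerance
$\epsilon$ has no canonical value and defaults to 0.1, always reported
alongside the rate. Model comparison uses two-sided paired t-tests on
per-student absolute errors ($n-1$ denominator in $s_d$); p-values are
reported raw by default (Holm adjustment optional) since multiplicity
conventions vary; degenerate zero-variance differences are flagged
explicitly rather than returning NaN.

## Synthetic cohorts

The package ships no survey data; a generator emulates the statistical
structure the method assumes so the whole pipeline is exercisable at desk
scale. Per student, a latent PERMA vector $\pi_i \in [0,1]^5$ is drawn
from a truncated normal whose mean vector and spread depend on the
student's culture (default: two cultures with shifted profiles — one
higher on P and R, the other on A and E, sd 0.15, mixing 60/40).
Features are $\mathrm{clip}_{[0,1]}(L\pi_i + \varepsilon)$ with a
block-aligned nonnegative loading matrix $L$ and feature noise sd 0.05,
then min-max rescaled per column; PERMA labels are the latents; the
well-being label is $\mathrm{clip}_{[0,1]}(\mathrm{mean}(\pi_i) +
\eta)$ with label noise sd 0.05; learning styles are uniform over 4
categories; stress level is the tertile of $1 - \pi_{i,P}$ (stress is
treated as an observed attribute with no published generative
definition, so a deterministic, testable rule anchored to low positive
emotion was chosen). Culture enters only through the latent
distribution — no further cultural mechanism is asserted — and is used
downstream for stratified evaluation.

Three presets: `large` (n = 12757, d = 23) and `small` (n = 268, d = 23)
mirror the scales of the two survey datasets the method targets;
`default` (n = 512, d = 23) is the desk-scale preset used by the
harnesses, examples and the acceptance script.

What the generator does *not* emulate: item-level survey artefacts
(ceiling effects, Likert discreteness, missingness), nonlinear
feature–latent links, correlated latent dimensions beyond the culture
means, or any temporal dynamics. Tests passing on these cohorts
establish that the implementation realizes the intended model and that
learning and consistency mechanisms behave directionally as claimed —
not that the architecture attains any particular accuracy on real
survey data.

## Reduced-scale configuration

The reference architecture (6 encoder layers of width 256, five 64-wide
heads, 1024 feed-forward, 128 tokens, 3×128 GCN, 8×32 GAT) is the
default `permanet_config("full")`. The `"reduced"` preset used by the
harnesses keeps the same family at desk scale: 2 layers of width 64,
five 16-wide heads, 128 feed-forward, 32 tokens, 3×32 GCN, 2×32 GAT,
30 epochs, batch 128, learning rate $10^{-3}$ with 30 warmup steps —
a short schedule on a small model warrants the larger step size, chosen
once alongside the preset. On the default n = 512 cohort one reduced fit
takes a couple of minutes on a laptop CPU and comfortably beats the
train-mean predictor on held-out MAE; the ablation and sweep harnesses
and the tests use this scale throughout.

## Numerical conventions and degenerate inputs

* Zero-norm feature rows get zero cosine similarity everywhere (warning,
  not error); all-zero distance matrices give the complete graph.
* Softmaxes subtract the row maximum; masked entries contribute
  $e^{-\infty} = 0$. Layer normalization uses population variance with
  $\epsilon = 10^{-5}$.
* GELU is exact ($x\Phi(x)$), not the tanh approximation.
* Stress tertiles break ties by student index, so group sizes are always
  within one of each other.
* Constant feature columns map to 0.5 under min-max rescaling.
* A non-finite training loss aborts with a diagnostic; the sweep harness
  catches this and flags the configuration as diverged instead of
  failing the whole sweep.
* All randomness (initialization, splits, batch order, dropout, the
  generator) descends from explicit seeds; identical seeds give
  bit-identical runs on a fixed platform.

## Known limitations

Dense graphs bound practical cohort size (memory is $O(n^2)$); no
k-NN sparsification or sampling is provided. The base-R training loop is
orders of magnitude slower than a GPU framework — the full reference
configuration is provided and tested for correctness, but sustained
training at n ≈ 13k is outside desk scale. Static, single-time-point
prediction only. The optional culture embedding (off by default) is the
only architectural use of culture; otherwise culture is an evaluation
stratifier, and no cultural-adaptation mechanism beyond the stratified
latent means is claimed.
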