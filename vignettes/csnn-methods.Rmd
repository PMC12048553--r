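---
title: "Chemical space networks and labels-as-features prediction: methods and design"
author: "csnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical space networks and labels-as-features prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnn)
```

## The problem and the model

Public drug–target interaction (DTI) databases for human G protein-coupled
receptors (hGPCRs) are extremely sparse: the vast majority of
compound–receptor pairs carry no annotation at all. This package exploits
*network homophily* — the empirical tendency of chemically similar compounds
to share bioactivity — to fill in such matrices *in distribution*, i.e. for
compounds that live inside the annotated chemical space rather than beyond
it.

The central object is the **chemical space network (CSN)**: a graph whose
nodes are compounds and whose edges connect pairs with Tanimoto similarity
strictly above a threshold $\epsilon$,

$$T(d_i, d_j) = \frac{\langle d_i, d_j\rangle}
  {\lVert d_i\rVert^2 + \lVert d_j\rVert^2 - \langle d_i, d_j\rangle},$$

evaluated on binary substructure fingerprints. On a homophilous CSN,
a query's one-hop neighbourhood carries most of the information needed to
predict its bioactivity, which motivates three predictor families of
increasing capacity, all *transductive* (they may consult labelled data at
inference time, never the query's own label):

1. **Training-free argmax.** The label frequencies of the query's labelled
   neighbours on a receptor are tallied and the most frequent class is
   predicted; the frequency vector itself is the labels-as-features (LaF)
   summary. With no labelled neighbour the predictor *abstains* — "no
   neighbourhood, no prediction" is the out-of-distribution guard, not a
   failure mode. For affinity regression the analogue aggregates neighbour
   $-\log_{10}(K_i)$ values by mean, max, min or similarity-weighted mean.
2. **Flat baselines ± N.** Conventional compound-to-prediction models
   (random forest, multilayer perceptron, ridge) on the concatenation of a
   dense compound representation (300) and a receptor embedding (320),
   optionally extended by the LaF summary: the 6 class frequencies for
   classification (width 626) or the single neighbourhood-mean column for
   regression (width 621). The ±N contrast isolates the value of
   neighbourhood information at matched model capacity.
3. **Neighbourhood neural networks.** A one-hop *directed* star graph per
   query (all edges incident on the query), with the neighbour's label
   one-hot plus Tanimoto similarity as edge features, aggregated by an
   edge-attributed graph convolution
   $$r_i = h_\Theta\!\Big((1+\epsilon_{\mathrm{gin}})\,x_i +
     \sum_{j \in N(i)} \mathrm{ReLU}(x_j + W_p\,e_{j,i})\Big)$$
   followed by a two-hidden-layer MLP head on the concatenation of $r_i$
   with skip features. The single-receptor variant emits 6 class scores
   (concatenated width $256+320+6 = 582$); the multi-receptor variant
   encodes, per edge, the neighbour's class-or-no-data across all 128
   receptor slots as a flattened $128\times 7$ one-hot block (width 896),
   uses a 64-dimensional local representation (concatenated width
   $64+896 = 960$), and emits 896 scores reshaped to $128\times 7$ with a
   per-receptor softmax; no-data positions are masked in the cross-entropy.

Because every edge points at the query and a single aggregation already
pools the neighbourhood, one convolution layer suffices and no graph
pooling is needed.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon` | 0.4 | CSN similarity threshold; edges require $T > \epsilon$ (strict). |
| `maxNeighbours` | 40 | Neighbourhood cap, applied after thresholding by similarity rank. |
| leakage threshold | 0.65 | Held-out compounds with any cross-set $T > 0.65$ (strict "over") force removal of the dataset compound. |
| split fractions | 80/10/10 | Scaffold-grouped train/test/val; an i.i.d. record-level mode is also provided. |
| fingerprint | 4096 + 166 bits | Circular substructure bits (radius 3) plus substructure keys, packed to 533 bytes. |
| learning rate | 1e-5 / 5e-5 | Single- / multi-receptor network (Adam, weight decay 1e-4, batch 16, 100 epochs, 5 repeats). |
| confidence | 0.8 | Prediction-probability cutoff for the high-confidence subset. |
| Z threshold | 3 | Strict hit-calling threshold, `two_sided` or `positive`. |
| $K_i$ cutoff | 100 nM | Predicted-hit rule: class ≠ "No effect" **and** $-\log_{10}(K_i) > 7$. |

All thresholds live in one place (`runConfig()`) so a pipeline run is fully
reproducible from its config and seed.

## Numerical and design choices

* **Packing is lossless and exact.** Bits are packed MSB-first, eight per
  byte, zero-padded; Tanimoto similarity is computed by popcount directly on
  packed bytes and therefore *equals* the unpacked value, so no inequality
  between packed and unpacked similarity arises. $T(0,0)$ is defined as 0:
  an empty fingerprint matches nothing. The bit order is a convention only
  (popcount is order-invariant) and is fixed by the round-trip tests.
* **Strict threshold.** "Similarity above $\epsilon$" is read strictly
  ($>$), consistent with zeroing values $\le 0.4$; the boundary case is
  pinned by a fixture whose similarity is exactly 0.4.
* **Ties.** Neighbour ties at the cap boundary break by ascending compound
  id; argmax ties break toward the lowest class index and are flagged
  rather than silently resolved, so downstream consumers can filter
  ambiguous calls.
* **Frequencies are proper distributions.** When some neighbours are
  unlabelled on the queried receptor, the frequency vector divides by the
  number of *labelled* neighbours. Dividing by all edges would deflate all
  classes uniformly, never change the argmax, and break the interpretation
  of the skip-connection features.
* **Edge features enter the convolution through a learned linear
  projection** $W_p$ to node-feature width, the standard contract for
  edge-attributed convolutions; raw widths (7 or 896) and node width (300)
  would otherwise be incompatible.
* **Scores are normalised exactly once.** The head emits raw scores; the
  softmax is applied inside the loss and at prediction time, avoiding a
  degenerate double normalisation.
* **Masked loss.** The batch loss is the mean over supervised graphs of the
  summed cross-entropy on unmasked positions; records whose positions are
  all masked do not enter the denominator, so adding them never changes the
  value (tested to 1e-12). A batch with zero unmasked positions raises an
  error instead of returning a silent 0.
* **$\epsilon_{\mathrm{gin}}$ is a fixed hyperparameter** (default 0),
  deliberately named apart from the similarity threshold.
* **Gradients are analytic** and verified against central finite
  differences on toy graphs to a relative error below $10^{-4}$; all
  training randomness (initialisation, shuffling) flows from a single seed,
  and repeated runs are bit-identical on one platform.
* **Z-scores** use the sample (n−1) standard deviation by convention of
  common screening toolchains; the population convention is config-exposed.
  The modified score $0.6745\,(x - m)/\mathrm{MAD}$ uses the *unscaled*
  MAD; the 0.6745 factor makes it consistent with the plain Z under
  normality. Within one receptor both scores are affine in
  $\log_{10}(\mathrm{RLU})$, so their correlation is exactly 1; the
  substantive calibration check is that the modified score's standard
  deviation is ≈ 1 on Gaussian data. Degenerate groups (zero sd or zero
  MAD) are errors naming the receptor.
* **Receptor distances** use the Bergsma bias-corrected Cramér's V with
  clamping at zero — the standard "corrected" form — computed on
  co-occurring compounds only; fewer than 5 co-occurring compounds yields
  the maximum distance 1.
* **Weighted F1** weights classes by their share of true instances, so
  classes absent from the truth get weight 0 and the weights always sum
  to 1; metrics are checked against a brute-force confusion-matrix oracle.
* **Abstentions** are reported under both conventions (excluded with a
  count, or scored as errors) because specificity bookkeeping differs
  between them.

### Encoder stand-ins

Pretrained molecular and protein encoders are out of scope. Both encoders
are pluggable interfaces with deterministic stand-ins that preserve the
dimensional contract: compounds map to 300-dimensional vectors by a seeded
random projection of their fingerprint bits, receptors to 320-dimensional
per-id seeded Gaussian vectors. Real embedding tables can be dropped in via
the `table` argument of `denseRepresentation()` / `targetEmbedding()`.
Random projections preserve geometry but carry no learned chemistry; where
a conclusion depends on representation quality, the stand-ins understate
achievable performance, which is acceptable because the package's claims
concern the *relative* value of neighbourhood information.

### Scaffolds

Scaffolds are computed by iterative terminal-atom pruning of the molecular
graph (rings plus linkers survive; acyclic molecules map to the
empty-scaffold group), canonicalised as SMILES. This graph-framework
variant prunes exocyclic double-bonded atoms too, which some toolkits
retain; for splitting, what matters is a consistent grouping key. Scaffold
assignment is greedy: scaffolds in order of decreasing size (ties shuffled
under the seed) go to the partition with the largest remaining deficit
relative to its target fraction — deterministic and within a compound of
the 80/10/10 targets whenever group sizes permit.

## What the synthetic generator emulates — and what it does not

`generateSpace()` builds a homophilous chemical space directly from the
generative assumptions: cluster prototypes are random bit vectors
(512 toy bits by default, density 0.1), members are per-bit mutations
(flip rate 0.01), each (cluster, receptor) pair draws a latent class
(uniform over 6) and a latent affinity (uniform over 4–9 on the
$-\log_{10} K_i$ scale, the range typical of published GPCR affinity
sets), members inherit the cluster class with probability $h$ (the
homophily dial), affinities add Gaussian noise (sd 0.3), and labels are
retained i.i.d. (50% by default). Screens draw per-receptor Gaussian
log-luminescence baselines with active pairs shifted by a stated effect
size in sd units.

This reproduces the *structural* premises the methods rely on — tight
chemical clusters, cluster-level label coherence controlled by a single
parameter, sparse labelling, log-normal plate readouts — and deliberately
not the *content* of real chemistry: no real molecules or assay artefacts,
uniform class priors rather than the heavy class imbalance of curated
databases, and clusters that coincide with scaffold groups (so
scaffold-split evaluations are maximally pessimistic for neighbourhood
methods: a held-out cluster has no training neighbours and correctly
abstains). Passing tests therefore demonstrate that the machinery is
correct and that the homophily→accuracy relationship behaves as designed;
they do not certify performance numbers on any real compound library.

A consequence worth stating: the training-free predictors are evaluated
transductively (any compound except the query may serve as a neighbour),
while trained models follow the stricter neighbour policy in which
evaluation graphs may only reference training compounds. Both policies are
explicit (`neighbourPolicy()`) and audited (`auditPolicy()`), with
violations raised as errors.

## Problem sizes

The test-suite and acceptance computations run at desk scale, chosen so the
full suite completes in a few minutes on one CPU: toy fingerprints of
64–512 bits, libraries of 30–539 compounds, 3–8 receptors, networks up to
200 compounds checked edge-for-edge against the naive $O(n^2)$ scan,
gradient checks on 2-node graphs, 5-seed homophily sweeps over
$h \in \{0.2, \dots, 1.0\}$, and screening calibrations at $10^4$–$10^5$
draws. All code paths are size-agnostic; the fingerprint and model widths
default to the full-scale values (4262 bits, 300/320/582/896/960).

## Known limitations

* The neighbourhood cap is applied before label filtering, so a query whose
  40 most similar neighbours are unlabelled on a receptor can abstain even
  though labelled compounds exist further down the ranking.
* Multi-receptor edge features omit the similarity column (the flattened
  one-hot block is exactly $128 \times 7$ wide); similarities remain
  available on the graph object but do not reach the multi-receptor
  convolution as edge input.
* The multi-receptor skip connection excludes the receptor embedding by
  construction (the concatenated width is $64 + 896 = 960$); receptor
  identity enters only through the position of the blocks.
* Training is plain R; it is intended for the desk-scale problems above,
  not for hundred-thousand-compound libraries. The all-pairs build is exact
  ($O(n^2)$) with no norm-bound pruning.
* Baseline grids mirror the intent, not the letter, of common Python
  implementations: the forest maps tree count and leaf size directly, but
  the perceptron is single-hidden-layer and the class-balanced weighting
  uses prior reweighting.
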