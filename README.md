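# csnn — Chemical Space Networks and Labels-as-Features DTI Prediction

`csnn` is an R package for annotating sparse drug–target interaction (DTI)
matrices — the setting typical of human G protein-coupled receptor (hGPCR)
pharmacology, where only a small percentage of all compound–receptor pairs
carry any annotation — by exploiting **network homophily**: chemically
similar compounds tend to share bioactivity.

It is aimed at computational chemists and ML practitioners who want
*in-distribution* DTI imputation with an explicit out-of-distribution
guard, and at screening groups who need the accompanying statistics
(Z-score hit calling, enrichment, novelty filtering) for single-point
luminescence screens.

## The core model

Compounds are encoded as binary substructure fingerprints (4096 circular
bits, radius 3, concatenated with 166 substructure keys; packed losslessly
into 533 bytes) and connected into a **chemical space network (CSN)**: an
all-vs-all graph keeping the pairs with Tanimoto similarity

    T(a, b) = |a ∧ b| / (|a| + |b| − |a ∧ b|)

strictly above a threshold ε (default 0.4). Three transductive predictor
families operate on a query's one-hop neighbourhood, never touching the
query's own label:

* **training-free argmax** — predict the most frequent neighbour label per
  receptor (the *labels-as-features*, LaF, principle); abstain when the
  neighbourhood is empty; aggregate neighbour affinities (mean / max / min /
  similarity-weighted) for −log10(Ki) regression;
* **flat baselines ± N** — random forest / MLP / ridge on compound ⊕
  receptor representations (300 + 320), optionally extended by the LaF
  frequency vector (626 wide) or the neighbourhood mean (621 wide);
* **neighbourhood neural networks** — an edge-attributed graph convolution
  `r = h_Θ((1+ε_gin)·x_q + Σ_j ReLU(x_j + W_p e_j))` over the directed star
  graph with label one-hots (+ similarity) as edge features, a skip
  connection carrying the LaF summary, and a masked-cross-entropy head:
  one variant per single receptor (6 classes, concat width 582), one for
  all 128 receptors in a single forward pass (896-wide edge blocks,
  concat width 960, per-receptor softmax over 6 classes + a no-data index).

Supporting machinery: Murcko-type scaffold 80/10/10 splits with a 0.65
cross-set Tanimoto leakage filter, audited transductive neighbour
policies, weighted-F1 / regression / enrichment metrics, bias-corrected
Cramér's V receptor distances, and a synthetic homophilous chemical-space
generator so that everything is testable without external data.

## Worked example

```r
library(csnn)

sp  <- generateSpace(syntheticSpec(nClusters = 10, compoundsPerCluster = 8,
                                   nReceptors = 4, homophily = 0.9,
                                   labelSparsity = 0.3, seed = 42))
csn <- buildCSN(sp$fingerprints)
csn
#> ChemicalSpaceNetwork: 80 compounds, 280 edges (Tanimoto > 0.4)

nb <- queryNeighbours(csn, "CPD0001")
head(nb, 3)
#>   compound_id similarity
#> 1     CPD0002  0.8787879
#> 3     CPD0004  0.8787879
#> 5     CPD0006  0.8676471

lf <- labelFrequency(nb, sp$dti, sp$scheme, receptorId = "REC001")
argmaxPredict(lf)[c("className", "support", "tie")]
#> $className
#> [1] "Allosteric modulator"
#> $support
#> [1] 6
#> $tie
#> [1] FALSE
```

Six of CPD0001's neighbours are labelled on REC001 and their majority class
becomes the training-free prediction. The end-to-end simulated pipeline
(CSN → scaffold split → argmax classification and neighbourhood-mean
regression → simulated screen with Z-score hit calling) reports:

```r
run <- runPipeline(runConfig(seed = 42, space = syntheticSpec(
  nClusters = 10, compoundsPerCluster = 8, nReceptors = 4,
  homophily = 0.9, labelSparsity = 0.3, seed = 42)))
round(run$argmaxMetrics$weightedF1, 3)   #> 0.866
round(run$regressionMetrics$mse, 3)      #> 0.136
round(mean(run$screen$hit), 4)           #> 0.0187
```

At homophily 0.9 the training-free classifier reaches weighted F1 ≈ 0.87
on held-out compounds and the neighbourhood-mean regressor an MSE ≈ 0.14
on the −log10(Ki) scale; ~1.9% of simulated screen wells exceed |Z| > 3
(agonist wells are shifted 6 sd up, the rest is Gaussian tail mass).

A thin command-line front end is available for the most common steps:

```sh
Rscript scripts/csnn.R simulate --seed 1 --out fixtures/
Rscript scripts/csnn.R build-csn --fingerprints fixtures/fingerprints.tsv --out csn/
Rscript scripts/csnn.R zscore --screen plate.csv --threshold 3 --mode modified
```

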