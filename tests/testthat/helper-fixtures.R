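# deterministic toy fixtures used across the suite; everything is generated
# in code, nothing is stored on disk

# random toy fingerprint matrix with ids
toyBits <- function(n, nbits = 64, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    B <- matrix(rbinom(n * nbits, 1L, density), n, nbits)
    storage.mode(B) <- "integer"
    rownames(B) <- sprintf("c%03d", seq_len(n))
    B
  })
}

# brute-force Tanimoto on unpacked 0/1 vectors (independent oracle: the
# inner-product form inter / (|a|^2 + |b|^2 - inter))
bitTanimoto <- function(a, b) {
  inter <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - inter
  if (den == 0) 0 else inter / den
}

# naive O(n^2) edge list oracle for CSN construction
bruteForceEdges <- function(B, epsilon) {
  n <- nrow(B)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t <- bitTanimoto(B[i, ], B[j, ])
    if (t > epsilon)
      out[[length(out) + 1]] <- data.frame(
        id_i = rownames(B)[i], id_j = rownames(B)[j], similarity = t,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id_i = character(), id_j = character(),
                      similarity = numeric()))
  do.call(rbind, out)
}

# canonical small homophilous space shared by several tests
smallSpace <- function(seed = 3, ...) {
  generateSpace(syntheticSpec(nClusters = 5, compoundsPerCluster = 6,
                              nReceptors = 4, seed = seed, ...))
}

# hand-built star graphs with controllable dimensions (query + edges)
toyGraph <- function(x = c(0.5, 1, 2), edges = list(), labelIdx = 1,
                     nClasses = 6, targetDim = 4, sim = 0.9) {
  nE <- length(edges)
  nf <- rbind(q = x)
  ef <- matrix(0, nE, nClasses + 1)
  ids <- character(nE)
  for (e in seq_along(edges)) {
    nf <- rbind(nf, edges[[e]]$x)
    ef[e, edges[[e]]$class] <- 1
    ef[e, nClasses + 1] <- sim
    ids[e] <- paste0("n", e)
  }
  rownames(nf) <- c("q", ids)
  lab <- rep(0, nClasses); lab[labelIdx] <- 1
  new("NeighbourhoodGraph", queryId = "q", receptorId = "R",
      mode = "single", nodeFeatures = nf, edgeFeatures = ef,
      similarities = rep(sim, nE), neighbourIds = ids,
      targetEmbedding = rep(0.1, targetDim), label = lab, ood = nE == 0)
}

# nn6 parameters whose aggregation block is the identity map
identityParams <- function(d, nClasses = 6, targetDim = 4) {
  p <- csnnInit("nn6", nodeDim = d, targetDim = targetDim,
                nClasses = nClasses, aggHidden = d, aggOut = d,
                headHidden = d, seed = 1)
  p$Wp <- p$Wp * 0; p$bp <- p$bp * 0
  p$W1 <- diag(d); p$b1 <- numeric(d)
  p$W2 <- diag(d); p$b2 <- numeric(d)
  p
}

# transductive training-free argmax evaluation over every labelled DTI
argmaxWeightedF1 <- function(sp, csn) {
  truth <- integer(0); pred <- integer(0)
  for (r in seq_len(nrow(sp$dti))) {
    nb <- queryNeighbours(csn, sp$dti$compound_id[r])
    lf <- labelFrequency(nb, sp$dti, sp$scheme,
                         receptorId = sp$dti$receptor_id[r])
    if (lf$support == 0) next
    truth <- c(truth, match(sp$dti$class[r], sp$scheme$classNames))
    pred <- c(pred, argmaxPredict(lf)$class)
  }
  classificationMetrics(truth, pred, sp$scheme$nClasses)$weightedF1
}

# sorted edge-table key for set comparisons
edgeKey <- function(df) {
  sort(paste(pmin(df$id_i, df$id_j), pmax(df$id_i, df$id_j),
             round(df$similarity, 12)))
}
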