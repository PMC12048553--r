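test_that("local aggregation reduces to the query features on empty graphs", {
  x <- c(0.5, 1, 2)
  g0 <- toyGraph(x, edges = list())
  p <- identityParams(3)
  expect_equal(aggregateLocal(g0, p), x)  # h = identity, eps = 0, no edges
})

test_that("aggregation sums over edges (duplicates count twice)", {
  x <- c(0.5, 1, 2)
  e1 <- list(x = c(1, 0, 1), class = 2)
  p <- identityParams(3)
  # edge projection zeroed: contribution per edge is relu(x_j)
  one <- aggregateLocal(toyGraph(x, list(e1)), p)
  two <- aggregateLocal(toyGraph(x, list(e1, e1)), p)
  expect_equal(one, x + c(1, 0, 1))
  expect_equal(two, x + 2 * c(1, 0, 1))
})

test_that("model outputs are invariant to edge order, bit-exactly", {
  sp <- smallSpace()
  csn <- buildCSN(sp$fingerprints)
  nodeRepr <- denseRepresentation(sp$fingerprints, dim = 10, seed = 2)
  targetEmb <- targetEmbedding(sp$receptorIds, dim = 6, seed = 2)
  g <- buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr,
                        targetEmb, sp$scheme)
  nE <- length(g@neighbourIds)
  expect_gt(nE, 1)
  perm <- rev(seq_len(nE))
  gp <- new("NeighbourhoodGraph", queryId = g@queryId,
            receptorId = g@receptorId, mode = g@mode,
            nodeFeatures = g@nodeFeatures[c(1, perm + 1), ],
            edgeFeatures = g@edgeFeatures[perm, , drop = FALSE],
            similarities = g@similarities[perm],
            neighbourIds = g@neighbourIds[perm],
            targetEmbedding = g@targetEmbedding, label = g@label,
            ood = g@ood)
  p <- csnnInit("nn6", nodeDim = 10, targetDim = 6, aggHidden = 8,
                aggOut = 8, headHidden = 8, seed = 3)
  expect_identical(predictCsnn(g, p)$probs, predictCsnn(gp, p)$probs)
})

test_that("zeroed heads emit uniform distributions with matching widths", {
  sp <- smallSpace()
  csn <- buildCSN(sp$fingerprints)
  nodeRepr <- denseRepresentation(sp$fingerprints, dim = 10, seed = 2)
  targetEmb <- targetEmbedding(sp$receptorIds, dim = 320, seed = 2)
  g <- buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr,
                        targetEmb, sp$scheme)
  p <- csnnInit("nn6", nodeDim = 10, seed = 1)
  # default nn6 concatenated width: 256 + 320 + 6 = 582
  expect_equal(p$dims$skipDim, 582)
  expect_length(csnn:::.csnnForward(g, p)$u, 582)
  p$W5 <- p$W5 * 0; p$b5 <- p$b5 * 0
  pr <- predictCsnn(g, p)
  expect_equal(pr$probs, rep(1 / 6, 6))
  expect_equal(pr$confidence, 1 / 6)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
  # multi-receptor head: 64 + 896 = 960 in, 896 out reshaped to 128 x 7
  gm <- buildGraphMulti("CPD0001", csn, sp$dti, nodeRepr,
                        sp$receptorIds, sp$scheme, nReceptors = 128)
  pm <- csnnInit("nn128", nodeDim = 10, seed = 1)
  expect_equal(ncol(gm@edgeFeatures), 896)
  expect_equal(pm$dims$skipDim, 960)
  expect_length(csnn:::.csnnForward(gm, pm)$u, 960)
  prm <- predictCsnn(gm, pm)
  expect_equal(dim(prm$probs), c(128, 7))
  expect_equal(unname(rowSums(prm$probs)), rep(1, 128))
  pm$W5 <- pm$W5 * 0; pm$b5 <- pm$b5 * 0
  prm0 <- predictCsnn(gm, pm)
  expect_equal(prm0$probs, matrix(1 / 7, 128, 7))
})

test_that("the masked batch loss behaves like summed cross-entropy", {
  g <- toyGraph(labelIdx = 2)
  p <- identityParams(3)
  p$W5 <- p$W5 * 0; p$b5 <- p$b5 * 0
  # uniform logits, C = 6, one labelled position -> ln 6
  expect_equal(csnnLoss(p, list(g)), log(6), tolerance = 1e-12)
  # perfect prediction in the large-logit limit -> loss near 0
  p$b5[2] <- 50
  expect_lt(csnnLoss(p, list(g)), 1e-6)
  # unlabelled graphs are fully masked and never change the loss
  gNA <- toyGraph(labelIdx = 1)
  gNA@label <- rep(NA_real_, 6)
  expect_equal(csnnLoss(p, list(g, gNA)), csnnLoss(p, list(g)),
               tolerance = 1e-12)
  # a batch with zero unmasked positions is undefined
  expect_error(csnnLoss(p, list(gNA)), "unmasked")
})

test_that("analytic gradients match finite differences on toy graphs", {
  g <- toyGraph(x = c(0.5, 1, 2),
                edges = list(list(x = c(1, 0.2, 0.7), class = 2),
                             list(x = c(0.3, 0.9, 0.1), class = 5)),
                labelIdx = 3)
  p <- csnnInit("nn6", nodeDim = 3, targetDim = 4, aggHidden = 5,
                aggOut = 4, headHidden = 6, seed = 2)
  an <- csnnGrad(p, list(g))$grads
  h <- 1e-5
  for (pn in names(an)) {
    for (i in seq_len(min(4, length(an[[pn]])))) {
      p2 <- p; p2[[pn]][i] <- p2[[pn]][i] + h
      p3 <- p; p3[[pn]][i] <- p3[[pn]][i] - h
      fd <- (csnnLoss(p2, list(g)) - csnnLoss(p3, list(g))) / (2 * h)
      denom <- max(abs(fd), abs(an[[pn]][i]), 1e-8)
      expect_lt(abs(fd - an[[pn]][i]) / denom, 1e-4,
                label = paste("grad", pn, i))
    }
  }
})

test_that("training is deterministic and reduces the loss", {
  sp <- generateSpace(syntheticSpec(nClusters = 6, compoundsPerCluster = 6,
                                    nReceptors = 3, homophily = 0.95,
                                    labelSparsity = 0.3, seed = 11))
  csn <- buildCSN(sp$fingerprints)
  nodeRepr <- denseRepresentation(sp$fingerprints, dim = 10, seed = 2)
  targetEmb <- targetEmbedding(sp$receptorIds, dim = 6, seed = 2)
  graphs <- lapply(seq_len(nrow(sp$dti)), function(i)
    buildGraphSingle(sp$dti$compound_id[i], sp$dti$receptor_id[i], csn,
                     sp$dti, nodeRepr, targetEmb, sp$scheme))
  cfg <- csnnConfig("nn6", learningRate = 1e-3, epochs = 6, seed = 5)
  fit1 <- csnnTrain(graphs, cfg,
                    initArgs = list(nodeDim = 10, targetDim = 6,
                                    aggHidden = 16, aggOut = 16,
                                    headHidden = 16))
  fit2 <- csnnTrain(graphs, cfg,
                    initArgs = list(nodeDim = 10, targetDim = 6,
                                    aggHidden = 16, aggOut = 16,
                                    headHidden = 16))
  expect_identical(fit1$params, fit2$params)  # bit-identical reruns
  expect_lt(fit1$history[length(fit1$history)], fit1$history[1])
})

test_that("confidence filtering keeps only confident, non-abstained calls", {
  preds <- list(list(abstain = FALSE, confidence = 0.95, class = 1L),
                list(abstain = FALSE, confidence = 0.5, class = 2L),
                list(abstain = TRUE, confidence = NA_real_,
                     class = NA_integer_))
  expect_equal(confidenceFilter(preds, 0.8)$keep, c(TRUE, FALSE, FALSE))
  expect_equal(confidenceFilter(preds, 0)$keep, c(TRUE, TRUE, FALSE))
  expect_equal(confidenceFilter(preds, 1)$retainedFraction, 0)
})

test_that("model parameters serialize with shapes intact", {
  p <- csnnInit("nn6", nodeDim = 5, targetDim = 4, aggHidden = 3,
                aggOut = 3, headHidden = 4, seed = 9)
  path <- withr::local_tempfile()
  writeCsnnParams(p, path)
  back <- readCsnnParams(path)
  expect_equal(back$W3, p$W3)
  expect_equal(back$dims$skipDim, p$dims$skipDim)
  expect_equal(back$mode, "nn6")
})
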