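#' Initialise neighbourhood-network parameters
#'
#' Two model variants share one architecture: an edge-attributed graph
#' convolution aggregates the query's neighbourhood into a local
#' representation
#' \deqn{r_i = h_\Theta\big((1+\epsilon) x_i + \sum_{j} \mathrm{ReLU}(x_j + W_p e_{j,i})\big)}
#' (edge features are mapped to node-feature width by a learned linear
#' projection, the standard edge-attributed convolution contract), which is
#' concatenated with skip-connection features and transformed by a two-
#' hidden-layer MLP into raw class scores. Normalisation happens exactly
#' once, inside the loss and at prediction time.
#'
#' * `nn6` (single receptor): aggregation output 256 (hidden 256), skip =
#'   receptor embedding (320) + neighbourhood label-frequency vector (6),
#'   head hidden 512, output 6 scores. Concatenated width 256+320+6 = 582.
#' * `nn128` (all receptors): aggregation output 64, skip = the flattened
#'   multi-receptor neighbourhood frequency vector (896); concatenated
#'   width 64+896 = 960; output 896 scores reshaped to 128 x 7 with a
#'   per-receptor softmax over 6 classes + the no-data index.
#'
#' @param mode `"nn6"` or `"nn128"`
#' @param nodeDim compound representation width (default 300)
#' @param targetDim receptor embedding width (default 320; `nn6` only)
#' @param nClasses number of bioactivity classes (default 6)
#' @param nReceptors receptor slots (default 128; `nn128` only)
#' @param aggHidden hidden width of the aggregation transform (default 256)
#' @param aggOut output width of the aggregation transform (256 for `nn6`,
#'   64 for `nn128`)
#' @param headHidden hidden width of the prediction head (default 512)
#' @param epsGin fixed mixing weight for the query's own features
#'   (default 0, not learned)
#' @param seed initialisation seed
#' @return a list of class `csnnParams`
#' @export
csnnInit <- function(mode = c("nn6", "nn128"), nodeDim = 300L,
                     targetDim = 320L, nClasses = 6L, nReceptors = 128L,
                     aggHidden = 256L,
                     aggOut = if (mode == "nn6") 256L else 64L,
                     headHidden = 512L, epsGin = 0, seed = 1L) {
  mode <- match.arg(mode)
  edgeDim <- if (mode == "nn6") nClasses + 1L
             else nReceptors * (nClasses + 1L)
  skipDim <- if (mode == "nn6") aggOut + targetDim + nClasses
             else aggOut + nReceptors * (nClasses + 1L)
  outDim <- if (mode == "nn6") nClasses else nReceptors * (nClasses + 1L)
  withr::local_seed(seed)
  he <- function(nout, nin) matrix(stats::rnorm(nout * nin), nout, nin) *
    sqrt(2 / nin)
  params <- list(
    mode = mode, epsGin = epsGin,
    dims = list(nodeDim = nodeDim, targetDim = targetDim,
                nClasses = nClasses, nReceptors = nReceptors,
                edgeDim = edgeDim, aggHidden = aggHidden, aggOut = aggOut,
                headHidden = headHidden, skipDim = skipDim,
                outDim = outDim),
    Wp = t(he(nodeDim, edgeDim)), bp = numeric(nodeDim),
    W1 = he(aggHidden, nodeDim), b1 = numeric(aggHidden),
    W2 = he(aggOut, aggHidden), b2 = numeric(aggOut),
    W3 = he(headHidden, skipDim), b3 = numeric(headHidden),
    W4 = he(headHidden, headHidden), b4 = numeric(headHidden),
    W5 = he(outDim, headHidden), b5 = numeric(outDim))
  class(params) <- "csnnParams"
  params
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# skip-connection features of a graph under a parameter set's mode
.skipFeatures <- function(graph, params) {
  d <- params$dims
  if (params$mode == "nn6") {
    etot <- if (length(graph@neighbourIds))
      colMeans(graph@edgeFeatures[, seq_len(d$nClasses), drop = FALSE])
    else numeric(d$nClasses)
    c(graph@targetEmbedding, etot)
  } else {
    .multiEtot(graph)
  }
}

# full forward pass; returns logits and all intermediates needed by backprop
.csnnForward <- function(graph, params) {
  d <- params$dims
  Xq <- as.numeric(graph@nodeFeatures[1, ])
  nE <- length(graph@neighbourIds)
  if (nE > 0) {
    Xn <- graph@nodeFeatures[-1, , drop = FALSE]
    E <- graph@edgeFeatures
    S <- Xn + E %*% params$Wp +
      matrix(params$bp, nE, d$nodeDim, byrow = TRUE)
    A <- pmax(S, 0)
    aggsum <- colSums(A)
  } else {
    S <- A <- matrix(0, 0, d$nodeDim)
    E <- matrix(0, 0, d$edgeDim)
    aggsum <- numeric(d$nodeDim)
  }
  a <- (1 + params$epsGin) * Xq + aggsum
  z1 <- as.numeric(params$W1 %*% a) + params$b1
  h1 <- pmax(z1, 0)
  z2 <- as.numeric(params$W2 %*% h1) + params$b2
  r <- pmax(z2, 0)
  u <- c(r, .skipFeatures(graph, params))
  z3 <- as.numeric(params$W3 %*% u) + params$b3
  h3 <- pmax(z3, 0)
  z4 <- as.numeric(params$W4 %*% h3) + params$b4
  h4 <- pmax(z4, 0)
  logits <- as.numeric(params$W5 %*% h4) + params$b5
  list(logits = logits, Xq = Xq, E = E, S = S, a = a, z1 = z1, h1 = h1,
       z2 = z2, r = r, u = u, z3 = z3, h3 = h3, z4 = z4, h4 = h4, nE = nE)
}

#' Local neighbourhood aggregation
#'
#' Exposes the aggregation block on its own: the edge-projected,
#' ReLU-gated sum over neighbours mixed with the query's features and
#' transformed by \eqn{h_\Theta}. Permutation-invariant over edges; with no
#' edges it reduces to \eqn{h_\Theta((1+\epsilon) x_i)}.
#'
#' @param graph a [NeighbourhoodGraph-class]
#' @param params a `csnnParams` list from [csnnInit()]
#' @return the local representation vector (length `aggOut`)
#' @export
aggregateLocal <- function(graph, params) .csnnForward(graph, params)$r

# per-graph summed cross-entropy on unmasked positions + logit gradient.
# Returns NULL for graphs with no supervised position.
.graphLossGrad <- function(graph, fw, params) {
  d <- params$dims
  if (params$mode == "nn6") {
    y <- graph@label
    if (anyNA(y)) return(NULL)
    p <- .softmax(fw$logits)
    list(loss = -sum(y * log(p)), dlogits = p - y, npos = 1L)
  } else {
    lab <- graph@label
    mask <- !is.na(lab)
    if (!any(mask)) return(NULL)
    width <- d$nClasses + 1L
    Z <- matrix(fw$logits, ncol = width, byrow = TRUE)
    dZ <- matrix(0, nrow(Z), width)
    loss <- 0
    for (r in which(mask)) {
      p <- .softmax(Z[r, ])
      loss <- loss - log(p[lab[r]])
      g <- p
      g[lab[r]] <- g[lab[r]] - 1
      dZ[r, ] <- g
    }
    list(loss = loss, dlogits = as.numeric(t(dZ)), npos = sum(mask))
  }
}

#' Masked batch cross-entropy loss
#'
#' Mean over supervised graphs of the summed cross-entropy on unmasked
#' positions. For the single-receptor model every labelled graph contributes
#' one position; for the multi-receptor model the positions with the no-data
#' marker are masked out, so adding fully-masked records never changes the
#' value. A batch with zero unmasked positions is an error (the loss is
#' undefined there).
#'
#' @param params a `csnnParams` list
#' @param graphs list of [NeighbourhoodGraph-class]
#' @return scalar loss
#' @export
csnnLoss <- function(params, graphs) {
  tot <- 0; nvalid <- 0L
  for (g in graphs) {
    lg <- .graphLossGrad(g, .csnnForward(g, params), params)
    if (is.null(lg)) next
    tot <- tot + lg$loss
    nvalid <- nvalid + 1L
  }
  if (nvalid == 0L) stop("batch has zero unmasked positions; loss undefined")
  tot / nvalid
}

# zero-filled gradient container matching params
.zeroGrads <- function(params) {
  g <- lapply(params[c("Wp", "bp", "W1", "b1", "W2", "b2",
                       "W3", "b3", "W4", "b4", "W5", "b5")],
              function(x) x * 0)
  g
}

#' Analytic gradients of the batch loss
#'
#' Backpropagates [csnnLoss()] through the head, the skip concatenation,
#' the aggregation transform and the edge projection. Matches
#' finite-difference gradients (verified in the test suite).
#'
#' @inheritParams csnnLoss
#' @return list with `loss` and `grads` (named like the parameter slots)
#' @export
csnnGrad <- function(params, graphs) {
  d <- params$dims
  G <- .zeroGrads(params)
  tot <- 0; nvalid <- 0L
  contribs <- list()
  for (g in graphs) {
    fw <- .csnnForward(g, params)
    lg <- .graphLossGrad(g, fw, params)
    if (is.null(lg)) next
    nvalid <- nvalid + 1L
    tot <- tot + lg$loss
    contribs[[nvalid]] <- list(fw = fw, dlogits = lg$dlogits, graph = g)
  }
  if (nvalid == 0L) stop("batch has zero unmasked positions; loss undefined")
  for (ct in contribs) {
    fw <- ct$fw
    dz5 <- ct$dlogits / nvalid
    G$W5 <- G$W5 + dz5 %o% fw$h4
    G$b5 <- G$b5 + dz5
    dh4 <- as.numeric(crossprod(params$W5, dz5))
    dz4 <- dh4 * (fw$z4 > 0)
    G$W4 <- G$W4 + dz4 %o% fw$h3
    G$b4 <- G$b4 + dz4
    dh3 <- as.numeric(crossprod(params$W4, dz4))
    dz3 <- dh3 * (fw$z3 > 0)
    G$W3 <- G$W3 + dz3 %o% fw$u
    G$b3 <- G$b3 + dz3
    du <- as.numeric(crossprod(params$W3, dz3))
    dr <- du[seq_len(d$aggOut)]
    dz2 <- dr * (fw$z2 > 0)
    G$W2 <- G$W2 + dz2 %o% fw$h1
    G$b2 <- G$b2 + dz2
    dh1 <- as.numeric(crossprod(params$W2, dz2))
    dz1 <- dh1 * (fw$z1 > 0)
    G$W1 <- G$W1 + dz1 %o% fw$a
    G$b1 <- G$b1 + dz1
    if (fw$nE > 0) {
      da <- as.numeric(crossprod(params$W1, dz1))
      dS <- matrix(da, fw$nE, d$nodeDim, byrow = TRUE) * (fw$S > 0)
      G$Wp <- G$Wp + crossprod(fw$E, dS)
      G$bp <- G$bp + colSums(dS)
    }
  }
  list(loss = tot / nvalid, grads = G)
}

#' Training configuration
#'
#' Defaults follow the published protocol: adaptive-moment (Adam) gradient
#' descent, batch size 16, 100 epochs, weight decay 1e-4, learning rate
#' 1e-5 for `nn6` and 5e-5 for `nn128`, five independent repeats for the
#' mean +/- sd summary.
#'
#' @param mode `"nn6"` or `"nn128"`
#' @param learningRate step size (mode-dependent default)
#' @param weightDecay L2 coefficient added to the gradient (default 1e-4)
#' @param batchSize minibatch size (default 16)
#' @param epochs training epochs (default 100)
#' @param seed master seed for init and shuffling
#' @param nRepeats independent repeats (default 5)
#' @return list of class `csnnConfig`
#' @export
csnnConfig <- function(mode = c("nn6", "nn128"),
                       learningRate = NULL, weightDecay = 1e-4,
                       batchSize = 16L, epochs = 100L, seed = 1L,
                       nRepeats = 5L) {
  mode <- match.arg(mode)
  if (is.null(learningRate))
    learningRate <- if (mode == "nn6") 1e-5 else 5e-5
  stopifnot(learningRate > 0, weightDecay >= 0, epochs >= 1)
  structure(list(mode = mode, learningRate = learningRate,
                 weightDecay = weightDecay, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 nRepeats = as.integer(nRepeats)),
            class = "csnnConfig")
}

#' Train a neighbourhood network
#'
#' Minibatch Adam on the masked cross-entropy, deterministic under the
#' config seed (initialisation and shuffling both flow from it). Aborts with
#' diagnostics if the loss turns non-finite.
#'
#' @param graphs training graphs (built under the train-mode neighbour
#'   policy)
#' @param config a [csnnConfig()]
#' @param initArgs extra arguments passed to [csnnInit()] (dimensions)
#' @param verbose print the per-epoch mean batch loss
#' @return list with `params`, `history` (mean batch loss per epoch) and
#'   `config`
#' @export
csnnTrain <- function(graphs, config, initArgs = list(), verbose = FALSE) {
  params <- do.call(csnnInit,
                    c(list(mode = config$mode, seed = config$seed), initArgs))
  pn <- c("Wp", "bp", "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
          "W5", "b5")
  m <- .zeroGrads(params); v <- .zeroGrads(params)
  beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
  t <- 0L
  history <- numeric(config$epochs)
  withr::local_seed(config$seed + 1L)
  supervised <- vapply(graphs, function(g)
    if (config$mode == "nn6") !anyNA(g@label) else any(!is.na(g@label)),
    logical(1))
  graphs <- graphs[supervised]
  if (!length(graphs)) stop("no supervised graphs to train on")
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(graphs))
    starts <- seq(1, length(graphs), by = config$batchSize)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batchSize - 1,
                                length(graphs))]
      lg <- csnnGrad(params, graphs[idx])
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged at epoch %d batch %d (loss %g)",
                     ep, bi, lg$loss))
      losses[bi] <- lg$loss
      t <- t + 1L
      for (p in pn) {
        grad <- lg$grads[[p]] + config$weightDecay * params[[p]]
        m[[p]] <- beta1 * m[[p]] + (1 - beta1) * grad
        v[[p]] <- beta2 * v[[p]] + (1 - beta2) * grad^2
        mhat <- m[[p]] / (1 - beta1^t)
        vhat <- v[[p]] / (1 - beta2^t)
        params[[p]] <- params[[p]] -
          config$learningRate * mhat / (sqrt(vhat) + epsAdam)
      }
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
  }
  list(params = params, history = history, config = config)
}

#' Predict with a trained neighbourhood network
#'
#' Emits class probabilities (normalised exponentials of the raw scores) and
#' the maximum-probability class with its confidence. Out-of-distribution
#' graphs (no labelled neighbourhood) abstain rather than fabricate a
#' distribution.
#'
#' @param graph a [NeighbourhoodGraph-class]
#' @param params trained `csnnParams`
#' @return for `nn6`: list with `abstain`, `probs` (length 6), `class`,
#'   `confidence`; for `nn128`: list with `abstain`, `probs`
#'   (`nReceptors x 7` matrix), `class` and `confidence` per receptor.
#' @export
predictCsnn <- function(graph, params) {
  d <- params$dims
  if (graph@ood) {
    return(if (params$mode == "nn6")
      list(abstain = TRUE, probs = rep(NA_real_, d$nClasses),
           class = NA_integer_, confidence = NA_real_)
    else
      list(abstain = TRUE,
           probs = matrix(NA_real_, d$nReceptors, d$nClasses + 1L),
           class = rep(NA_integer_, d$nReceptors),
           confidence = rep(NA_real_, d$nReceptors)))
  }
  logits <- .csnnForward(graph, params)$logits
  if (params$mode == "nn6") {
    p <- .softmax(logits)
    k <- which.max(p)
    list(abstain = FALSE, probs = p, class = as.integer(k),
         confidence = p[k])
  } else {
    Z <- matrix(logits, ncol = d$nClasses + 1L, byrow = TRUE)
    P <- t(apply(Z, 1, .softmax))
    k <- max.col(P, ties.method = "first")
    list(abstain = FALSE, probs = P, class = as.integer(k),
         confidence = P[cbind(seq_len(nrow(P)), k)])
  }
}

#' Filter predictions by confidence
#'
#' Retains predictions whose confidence strictly exceeds the threshold
#' (abstentions are never retained) and reports the retained fraction.
#'
#' @param predictions list of [predictCsnn()] results (single-receptor mode)
#' @param threshold probability threshold (default 0.8)
#' @return list with `keep` (logical), `retainedFraction`
#' @export
confidenceFilter <- function(predictions, threshold = 0.8) {
  keep <- vapply(predictions, function(p)
    !isTRUE(p$abstain) && !is.na(p$confidence) && p$confidence > threshold,
    logical(1))
  list(keep = keep, retainedFraction = mean(keep))
}

#' Train with independent repeats and summarise test metrics
#'
#' Runs `nRepeats` independently seeded trainings and evaluates each on the
#' supplied test graphs, reporting per-repeat weighted F1 plus the
#' mean +/- standard deviation, the published stability protocol.
#'
#' @param graphs training graphs
#' @param testGraphs evaluation graphs (built under the eval-mode policy)
#' @param config a [csnnConfig()]
#' @param initArgs extra arguments for [csnnInit()]
#' @return list with `runs` (data frame seed/weightedF1), `mean`, `sd`,
#'   `models`
#' @export
csnnTrainRepeats <- function(graphs, testGraphs, config, initArgs = list()) {
  res <- lapply(seq_len(config$nRepeats) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    fit <- csnnTrain(graphs, cfg, initArgs = initArgs)
    truth <- integer(0); pred <- integer(0)
    for (g in testGraphs) {
      if (cfg$mode == "nn6") {
        if (anyNA(g@label) || g@ood) next
        pr <- predictCsnn(g, fit$params)
        truth <- c(truth, which.max(g@label))
        pred <- c(pred, pr$class)
      } else {
        if (g@ood) next
        pr <- predictCsnn(g, fit$params)
        mask <- !is.na(g@label)
        truth <- c(truth, g@label[mask])
        pred <- c(pred, pr$class[mask])
      }
    }
    nC <- if (cfg$mode == "nn6") fit$params$dims$nClasses
          else fit$params$dims$nClasses + 1L
    f1 <- classificationMetrics(truth, pred, nClasses = nC)$weightedF1
    list(fit = fit, f1 = f1)
  })
  f1s <- vapply(res, `[[`, numeric(1), "f1")
  list(runs = data.frame(seed = config$seed + seq_along(f1s) - 1L,
                         weightedF1 = f1s),
       mean = mean(f1s), sd = stats::sd(f1s),
       models = lapply(res, `[[`, "fit"))
}

#' Serialize / load model parameters
#'
#' Writes shapes, config metadata and weights as JSON at full precision.
#'
#' @param params a `csnnParams` list
#' @param path output file
#' @return `writeCsnnParams()` returns `path` invisibly; `readCsnnParams()`
#'   the parameter list.
#' @export
writeCsnnParams <- function(params, path) {
  obj <- c(list(format = "csnn-params", version = 1L), unclass(params))
  writeLines(as.character(jsonlite::toJSON(obj, digits = I(17),
                                           auto_unbox = TRUE)), path)
  invisible(path)
}

#' @rdname writeCsnnParams
#' @export
readCsnnParams <- function(path) {
  x <- jsonlite::fromJSON(readLines(path))
  if (!identical(x$format, "csnn-params")) stop("not a csnn model: ", path)
  x$format <- NULL; x$version <- NULL
  for (p in c("Wp", "W1", "W2", "W3", "W4", "W5"))
    x[[p]] <- as.matrix(x[[p]])
  for (p in c("bp", "b1", "b2", "b3", "b4", "b5"))
    x[[p]] <- as.numeric(x[[p]])
  class(x) <- "csnnParams"
  x
}
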