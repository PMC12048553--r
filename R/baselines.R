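#' Flat feature vector for compound-to-prediction baselines
#'
#' Concatenates the compound's dense representation (300), the receptor
#' embedding (320) and, for the `+N` (labels-as-features) variants, the
#' neighbourhood summary: the 6-entry label-frequency vector for
#' classification (total width 626) or the single neighbourhood-mean
#' affinity column for regression (width 621). Without the neighbourhood
#' the width is 620. An empty neighbourhood appends zeros and raises the
#' OOD flag.
#'
#' @param queryId compound id
#' @param receptorId receptor id
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param dti DTI frame (with `value` for regression)
#' @param nodeRepr dense representation matrix
#' @param targetEmb receptor embedding matrix
#' @param withNeighbourhood append LaF columns (`+N` variant)?
#' @param task `"classification"` or `"regression"`
#' @param scheme a [bioactivityClasses()] scheme
#' @param allowed optional allowed neighbour ids (transductive policy)
#' @param maxNeighbours neighbourhood cap (default 40)
#' @return numeric feature vector with attribute `ood`
#' @export
featurize <- function(queryId, receptorId, csn, dti, nodeRepr, targetEmb,
                      withNeighbourhood = TRUE,
                      task = c("classification", "regression"),
                      scheme = bioactivityClasses(), allowed = NULL,
                      maxNeighbours = 40L) {
  task <- match.arg(task)
  out <- c(nodeRepr[queryId, ], targetEmb[receptorId, ])
  ood <- FALSE
  if (withNeighbourhood) {
    nb <- .policyNeighbours(csn, queryId, allowed, maxNeighbours)
    if (task == "classification") {
      lf <- labelFrequency(nb, dti, scheme, receptorId = receptorId)
      ood <- lf$support == 0
      out <- c(out, lf$freqs)
    } else {
      vals <- dti[dti$receptor_id == receptorId & !is.na(dti$value), ,
                  drop = FALSE]
      lookup <- stats::setNames(vals$value, vals$compound_id)
      lookup <- lookup[names(lookup) != queryId]
      pred <- aggregateRegression(nb, lookup, method = "mean")
      ood <- is.na(pred)
      out <- c(out, if (is.na(pred)) 0 else pred)
    }
  }
  attr(out, "ood") <- ood
  out
}

# weighted F1 CV score for classification, negative MSE for regression
.cvScore <- function(truth, pred, task, nClasses) {
  if (task == "classification")
    classificationMetrics(truth, pred, nClasses = nClasses)$weightedF1
  else -mean((truth - pred)^2)
}

.defaultGrid <- function(family) {
  switch(family,
         rf = expand.grid(ntree = c(100, 500, 1000),
                          nodesize = c(1, 2, 4, 8)),
         mlp = expand.grid(size = c(32, 16, 8), decay = c(1e-3, 1e-6)),
         ridge = expand.grid(lambda = 10^seq(-6, 2, by = 1)))
}

.fitOne <- function(x, y, family, point, task, seed) {
  withr::local_seed(seed)
  if (family == "rf") {
    if (task == "classification") {
      cw <- table(y)
      cw <- stats::setNames(as.numeric(length(y) / (length(cw) * cw)),
                            names(cw))
      randomForest::randomForest(x, y, ntree = point$ntree,
                                 nodesize = point$nodesize, classwt = cw)
    } else {
      randomForest::randomForest(x, y, ntree = point$ntree,
                                 nodesize = point$nodesize)
    }
  } else if (family == "mlp") {
    if (task == "classification") {
      nnet::nnet(x, nnet::class.ind(y), size = point$size,
                 decay = point$decay, softmax = TRUE, maxit = 500,
                 MaxNWts = 1e6, trace = FALSE)
    } else {
      nnet::nnet(x, y, size = point$size, decay = point$decay,
                 linout = TRUE, maxit = 500, MaxNWts = 1e6, trace = FALSE)
    }
  } else {
    MASS::lm.ridge(y ~ x, lambda = point$lambda)
  }
}

.predictOne <- function(model, x, family, task, levelsY = NULL) {
  if (family == "rf") {
    p <- stats::predict(model, x)
    if (task == "classification") as.character(p) else as.numeric(p)
  } else if (family == "mlp") {
    p <- stats::predict(model, x)
    if (task == "classification") levelsY[max.col(p, ties.method = "first")]
    else as.numeric(p)
  } else {
    as.numeric(cbind(1, x) %*% coef(model))
  }
}

#' Fit a baseline model with 2-fold cross-validated grid search
#'
#' Model families: a random-forest ensemble (class-balanced weighting for
#' classification), a single-hidden-layer multilayer perceptron, and
#' ridge-regularised linear regression. The best grid point is chosen by
#' 2-fold cross-validation (weighted F1 for classification, MSE for
#' regression); the final model is refit on all data at that point.
#'
#' @param x numeric feature matrix
#' @param y labels: factor/character for classification, numeric for
#'   regression
#' @param family `"rf"`, `"mlp"` or `"ridge"`
#' @param task `"classification"` or `"regression"` (`ridge` is regression
#'   only)
#' @param grid data frame of hyperparameter points (family-specific
#'   defaults)
#' @param cvFolds number of folds (default 2)
#' @param seed seed for fold assignment and model fits
#' @return list with `model`, `best` (chosen grid row), `cvScores`,
#'   `family`, `task`, `levels`
#' @export
fitBaseline <- function(x, y, family = c("rf", "mlp", "ridge"),
                        task = c("classification", "regression"),
                        grid = NULL, cvFolds = 2L, seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  if (family == "ridge" && task != "regression")
    stop("ridge baseline is regression-only")
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2)
      stop("degenerate training data: single class ", levels(y))
  }
  if (is.null(grid)) grid <- .defaultGrid(family)
  stopifnot(nrow(grid) >= 1)
  withr::local_seed(seed)
  folds <- sample(rep(seq_len(cvFolds), length.out = length(y)))
  nC <- if (task == "classification") nlevels(y) else NA
  cvScores <- vapply(seq_len(nrow(grid)), function(gi) {
    point <- grid[gi, , drop = FALSE]
    mean(vapply(seq_len(cvFolds), function(f) {
      tr <- folds != f
      m <- .fitOne(x[tr, , drop = FALSE], y[tr], family, point, task,
                   seed + f)
      p <- .predictOne(m, x[!tr, , drop = FALSE], family, task, levels(y))
      if (task == "classification")
        .cvScore(as.integer(y[!tr]), match(p, levels(y)), task, nC)
      else .cvScore(y[!tr], p, task, nC)
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which.max(cvScores), , drop = FALSE]
  model <- .fitOne(x, y, family, best, task, seed)
  structure(list(model = model, best = best, cvScores = cvScores,
                 family = family, task = task,
                 levels = if (task == "classification") levels(y) else NULL),
            class = "csnnBaseline")
}

#' Predict from a fitted baseline
#'
#' @param object result of [fitBaseline()]
#' @param x feature matrix
#' @param ... unused
#' @return character class labels (classification) or numeric predictions
#' @export
predict.csnnBaseline <- function(object, x, ...) {
  .predictOne(object$model, x, object$family, object$task, object$levels)
}
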