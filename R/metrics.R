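#' Per-class and weighted classification metrics
#'
#' Computes per-class precision, recall and F1 from the confusion matrix,
#' plus the support-weighted F1: each class is weighted by its proportion of
#' true instances, so classes with zero true and zero predicted instances
#' receive weight 0 and the weights of the remaining classes sum to 1. A
#' class with zero predicted (or zero true) instances has precision (or
#' recall) defined as 0. Abstentions (`NA` predictions) are excluded by
#' default or counted as errors.
#'
#' @param truth integer class indices (1-based)
#' @param pred integer class indices; `NA` marks an abstention
#' @param nClasses number of classes
#' @param abstain `"exclude"` drops abstained pairs (reporting the count);
#'   `"error"` counts them as a wrong prediction of an artificial class
#' @return list with `perClass` data frame (precision, recall, f1, support),
#'   `weightedF1`, `confusion`, `nAbstained`
#' @export
classificationMetrics <- function(truth, pred, nClasses,
                                  abstain = c("exclude", "error")) {
  abstain <- match.arg(abstain)
  stopifnot(length(truth) == length(pred))
  nAb <- sum(is.na(pred))
  if (abstain == "exclude") {
    keep <- !is.na(pred)
    truth <- truth[keep]; pred <- pred[keep]
    k <- nClasses
  } else {
    k <- nClasses + 1L
    pred[is.na(pred)] <- k
  }
  conf <- table(factor(truth, levels = seq_len(k)),
                factor(pred, levels = seq_len(k)))
  tp <- diag(conf)
  predTot <- colSums(conf)
  trueTot <- rowSums(conf)
  precision <- ifelse(predTot > 0, tp / predTot, 0)
  recall <- ifelse(trueTot > 0, tp / trueTot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- if (sum(trueTot) > 0) trueTot / sum(trueTot) else trueTot
  per <- data.frame(class = seq_len(k), precision = as.numeric(precision),
                    recall = as.numeric(recall), f1 = as.numeric(f1),
                    support = as.numeric(trueTot))
  per <- per[seq_len(nClasses), , drop = FALSE]
  list(perClass = per,
       weightedF1 = sum(w[seq_len(nClasses)] * f1[seq_len(nClasses)]),
       confusion = conf[seq_len(nClasses), , drop = FALSE],
       nAbstained = nAb)
}

#' Regression metrics
#'
#' MSE, MAE and the Pearson, Spearman and Kendall correlations between true
#' and predicted values. Abstained (`NA`) predictions are excluded and
#' counted. Zero-variance inputs leave the correlations `NA` (undefined),
#' reported as such.
#'
#' @param truth numeric true values
#' @param pred numeric predictions (`NA` = abstain)
#' @return list with `mse`, `mae`, `pearson`, `spearman`, `kendall`, `n`,
#'   `nAbstained`
#' @export
regressionMetrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  keep <- !is.na(pred) & !is.na(truth)
  nAb <- sum(!keep)
  truth <- truth[keep]; pred <- pred[keep]
  corSafe <- function(method) {
    if (length(truth) < 2 || stats::sd(truth) == 0 || stats::sd(pred) == 0)
      return(NA_real_)
    stats::cor(truth, pred, method = method)
  }
  list(mse = mean((truth - pred)^2), mae = mean(abs(truth - pred)),
       pearson = corSafe("pearson"), spearman = corSafe("spearman"),
       kendall = corSafe("kendall"), n = length(truth), nAbstained = nAb)
}

#' Homophily-performance correlation across receptors
#'
#' Correlates, across receptors, a model's per-receptor performance with the
#' per-receptor performance of the training-free neighbourhood-mean
#' predictor (the homophily proxy: where the mean is a good prediction, the
#' neighbourhood is homophilous). Returns the Pearson correlation with its
#' two-sided t-test p-value.
#'
#' @param homophilyProxy numeric vector, e.g. per-receptor Pearson of the
#'   neighbourhood-mean predictor
#' @param modelMetric numeric vector, per-receptor metric of the model under
#'   study
#' @return list with `correlation`, `pValue`, `n`, and the paired `data`
#' @export
homophilyPerformance <- function(homophilyProxy, modelMetric) {
  stopifnot(length(homophilyProxy) == length(modelMetric))
  keep <- !is.na(homophilyProxy) & !is.na(modelMetric)
  x <- homophilyProxy[keep]; y <- modelMetric[keep]
  if (length(x) < 3) stop("need at least 3 receptors")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(correlation = unname(ct$estimate), pValue = ct$p.value,
       n = length(x), data = data.frame(homophilyProxy = x,
                                        modelMetric = y))
}

#' Hit enrichment of predicted versus experimental screens
#'
#' An experimental hit is a Z-score strictly above `zThreshold`; a predicted
#' hit requires (1) a predicted class other than the no-effect class and (2)
#' a predicted affinity tighter than `kiThresholdNm` (i.e. -log10(Ki)
#' above `-log10(kiThresholdNm * 1e-9)`; 100 nM corresponds to 7). Reports
#' the 2x2 confusion, specificity, precision, the baseline hit rate and the
#' enriched hit rate among predicted hits. Keys present in only one table
#' are reported, never silently dropped.
#'
#' @param predicted data frame with `compound_id`, `receptor_id`,
#'   `predicted_class` (character; `NA` = abstain) and `predicted_pki`
#' @param experimental data frame with `compound_id`, `receptor_id`, `z`
#' @param kiThresholdNm predicted-affinity cutoff in nM (default 100)
#' @param zThreshold experimental hit threshold (default 3, positive tail)
#' @param noEffectClass name of the no-effect class
#' @param abstainAsNegative treat abstentions as negative predictions
#'   (`TRUE`, default) or drop them (`FALSE`); both conventions are
#'   reported via this flag
#' @return list with `confusion` (2x2), `specificity`, `precision`,
#'   `baselineHitRate`, `enrichedHitRate`, `nMatched`, `unmatched`
#' @export
enrichment <- function(predicted, experimental, kiThresholdNm = 100,
                       zThreshold = 3, noEffectClass = "No effect",
                       abstainAsNegative = TRUE) {
  key <- function(d) paste(d$compound_id, d$receptor_id, sep = "\r")
  kp <- key(predicted); ke <- key(experimental)
  common <- intersect(kp, ke)
  unmatched <- list(predictedOnly = setdiff(kp, ke),
                    experimentalOnly = setdiff(ke, kp))
  p <- predicted[match(common, kp), , drop = FALSE]
  e <- experimental[match(common, ke), , drop = FALSE]
  pkiCut <- -log10(kiThresholdNm * 1e-9)
  predHit <- !is.na(p$predicted_class) & p$predicted_class != noEffectClass &
    !is.na(p$predicted_pki) & p$predicted_pki > pkiCut
  if (!abstainAsNegative) {
    keep <- !is.na(p$predicted_class)
    p <- p[keep, , drop = FALSE]; e <- e[keep, , drop = FALSE]
    predHit <- predHit[keep]
  }
  expHit <- e$z > zThreshold
  tp <- sum(predHit & expHit); fp <- sum(predHit & !expHit)
  fn <- sum(!predHit & expHit); tn <- sum(!predHit & !expHit)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(predicted = c("hit", "no-hit"),
                                 experimental = c("hit", "no-hit")))
  list(confusion = conf,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       baselineHitRate = if (length(expHit)) mean(expHit) else NA_real_,
       enrichedHitRate = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       nMatched = length(expHit), unmatched = unmatched)
}

# bias-corrected Cramer's V (Bergsma correction with clamping at 0)
.cramersV <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  r <- nrow(tab); k <- ncol(tab)
  if (r < 2 && k < 2) return(if (all(a == b)) 1 else 0)
  if (r < 2 || k < 2) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  phi2 <- as.numeric(chi2) / n
  phi2c <- max(0, phi2 - (r - 1) * (k - 1) / (n - 1))
  rc <- r - (r - 1)^2 / (n - 1)
  kc <- k - (k - 1)^2 / (n - 1)
  den <- min(rc - 1, kc - 1)
  if (den <= 0) return(0)
  sqrt(phi2c / den)
}

#' Distance between receptors from shared labels or embeddings
#'
#' `cramers_v`: restricts both receptors' class labels to co-occurring
#' compounds and returns `1 - V` with `V` the bias-corrected Cramer's V;
#' with fewer than 5 co-occurring compounds the distance is set to its
#' maximum (1). `cosine`: `1 -` cosine similarity of the receptor
#' embeddings (range \[0, 2\]).
#'
#' @param labelsI,labelsJ named class vectors (names = compound ids) for
#'   the two receptors, or embedding vectors for `metric = "cosine"`
#' @param metric `"cramers_v"` or `"cosine"`
#' @param minCooccurring minimum co-occurring compounds (default 5)
#' @return distance
#' @export
receptorDistance <- function(labelsI, labelsJ,
                             metric = c("cramers_v", "cosine"),
                             minCooccurring = 5L) {
  metric <- match.arg(metric)
  if (metric == "cosine") {
    return(1 - sum(labelsI * labelsJ) /
             (sqrt(sum(labelsI^2)) * sqrt(sum(labelsJ^2))))
  }
  common <- intersect(names(labelsI), names(labelsJ))
  if (length(common) < minCooccurring) return(1)
  1 - .cramersV(as.character(labelsI[common]), as.character(labelsJ[common]))
}
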