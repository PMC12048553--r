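#' Default bioactivity class scheme
#'
#' Six mode-of-action classes plus a reserved "no data" index used by the
#' multi-receptor encoding (index `nClasses + 1`). The class set is
#' configurable; orderings are significant (ties in argmax prediction break
#' toward the lowest index).
#'
#' @param classNames ordered character vector of class names
#' @return list with `classNames`, `nClasses`, `noDataIndex`
#' @export
bioactivityClasses <- function(classNames = c("Agonist", "Partial agonist",
                                              "Antagonist", "Inverse agonist",
                                              "Allosteric modulator",
                                              "No effect")) {
  if (anyDuplicated(classNames)) stop("class names must be unique")
  list(classNames = classNames, nClasses = length(classNames),
       noDataIndex = length(classNames) + 1L)
}

# class label lookup for one receptor: named integer vector id -> class index
.labelLookup <- function(dti, receptorId, scheme) {
  d <- dti[dti$receptor_id == receptorId & !is.na(dti$class), , drop = FALSE]
  idx <- match(d$class, scheme$classNames)
  if (anyNA(idx))
    stop("unknown class name(s): ",
         paste(unique(d$class[is.na(idx)]), collapse = ", "))
  stats::setNames(idx, d$compound_id)
}

#' Label frequency vector of a neighbourhood
#'
#' Counts the bioactivity classes of the query's labelled neighbours on one
#' receptor and normalises by the number of labelled neighbours, so the
#' result is a proper frequency distribution (neighbours without a label on
#' this receptor are skipped). With zero labelled neighbours the vector is
#' all zero and `support` is 0. The result does not depend on neighbour
#' order.
#'
#' @param neighbours data frame with column `compound_id` (e.g. from
#'   [queryNeighbours()])
#' @param labels named integer vector mapping compound ids to class indices
#'   for one receptor, or a DTI data frame (then `receptorId` selects the
#'   receptor)
#' @param scheme a [bioactivityClasses()] scheme
#' @param receptorId receptor id, required when `labels` is a DTI frame
#' @return list with `freqs` (named numeric, one entry per class) and
#'   `support` (number of labelled neighbours)
#' @export
labelFrequency <- function(neighbours, labels, scheme = bioactivityClasses(),
                           receptorId = NULL) {
  if (is.data.frame(labels)) {
    stopifnot(!is.null(receptorId))
    labels <- .labelLookup(labels, receptorId, scheme)
  }
  cls <- labels[match(neighbours$compound_id, names(labels))]
  cls <- cls[!is.na(cls)]
  freqs <- stats::setNames(numeric(scheme$nClasses), scheme$classNames)
  if (length(cls)) {
    tab <- tabulate(cls, nbins = scheme$nClasses)
    freqs[] <- tab / length(cls)
  }
  list(freqs = freqs, support = length(cls))
}

#' Training-free argmax class prediction
#'
#' Predicts the most frequent class among the labelled neighbours. Zero
#' support yields an abstention (`NA` class) -- the out-of-distribution
#' guard. Exact frequency ties are broken toward the lowest class index and
#' flagged.
#'
#' @param freq result of [labelFrequency()]
#' @return list with `class` (integer index or `NA` for abstain), `className`,
#'   `tie` (logical), `freqs`, `support`
#' @export
argmaxPredict <- function(freq) {
  if (freq$support == 0)
    return(list(class = NA_integer_, className = NA_character_, tie = FALSE,
                freqs = freq$freqs, support = 0L))
  k <- which.max(freq$freqs)
  tie <- sum(abs(freq$freqs - freq$freqs[k]) < 1e-12) > 1L
  list(class = as.integer(k), className = names(freq$freqs)[k], tie = tie,
       freqs = freq$freqs, support = freq$support)
}

#' Neighbourhood-aggregate affinity regression
#'
#' Training-free regression on the -log10(Ki) scale: aggregates the affinity
#' values of the labelled neighbours with one of `mean`, `max`, `min` or
#' `weighted` (Tanimoto-similarity-weighted mean). With no valued neighbour
#' the prediction abstains (`NA`). Results do not depend on neighbour order.
#'
#' @param neighbours data frame with columns `compound_id`, `similarity`
#' @param values named numeric vector mapping compound ids to affinity values
#' @param method aggregation method
#' @return predicted value, or `NA` (abstain)
#' @export
aggregateRegression <- function(neighbours, values,
                                method = c("mean", "max", "min", "weighted")) {
  method <- match.arg(method)
  v <- values[match(neighbours$compound_id, names(values))]
  keep <- !is.na(v)
  if (!any(keep)) return(NA_real_)
  v <- as.numeric(v[keep])
  switch(method,
         mean = mean(v),
         max = max(v),
         min = min(v),
         weighted = {
           w <- neighbours$similarity[keep]
           sum(w * v) / sum(w)
         })
}

#' Filter experimental hits for novelty
#'
#' Retains screen hits that are both significant (|Z| strictly greater than
#' `zThreshold`) and novel: the compound has no labelled neighbour for that
#' receptor in the chemical space network, so no prior art exists in the
#' chemical neighbourhood.
#'
#' @param hits data frame with columns `compound_id`, `receptor_id`, `z`
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param dti DTI data frame with columns `compound_id`, `receptor_id`,
#'   `class`
#' @param scheme a [bioactivityClasses()] scheme
#' @param zThreshold significance threshold (default 3, strict)
#' @param maxNeighbours neighbourhood cap used in the lookup (default 40)
#' @return the retained subset of `hits`
#' @export
noveltyFilter <- function(hits, csn, dti, scheme = bioactivityClasses(),
                          zThreshold = 3, maxNeighbours = 40L) {
  keep <- vapply(seq_len(nrow(hits)), function(r) {
    if (abs(hits$z[r]) <= zThreshold) return(FALSE)
    if (!hits$compound_id[r] %in% nodeIds(csn)) return(TRUE)
    nb <- queryNeighbours(csn, hits$compound_id[r],
                          maxNeighbours = maxNeighbours)
    lf <- labelFrequency(nb, dti, scheme, receptorId = hits$receptor_id[r])
    lf$support == 0
  }, logical(1))
  hits[keep, , drop = FALSE]
}
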