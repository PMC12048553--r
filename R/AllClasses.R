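#' FingerprintSet: packed bit fingerprints for a compound library
#'
#' Stores one packed fingerprint per compound as a row of byte values
#' (integers in \[0, 255\]), MSB-first within each byte, together with the
#' unpacked bit length. Packing is lossless: `unpackFingerprint()` recovers
#' the original bits exactly, and Tanimoto similarity is computed directly on
#' the packed bytes by popcount, so packed and unpacked similarities are
#' identical.
#'
#' @slot bytes integer matrix, one compound per row, `ceiling(nbits/8)`
#'   columns; rownames are compound ids.
#' @slot nbits integer, number of meaningful bits (remaining pad bits are 0).
#' @export
setClass("FingerprintSet",
  representation(bytes = "matrix", nbits = "integer")
)

setValidity("FingerprintSet", function(object) {
  msg <- character(0)
  b <- object@bytes
  if (!is.integer(b)) msg <- c(msg, "bytes must be an integer matrix")
  if (length(object@nbits) != 1L || is.na(object@nbits) || object@nbits < 1L)
    msg <- c(msg, "nbits must be a single positive integer")
  if (ncol(b) != ceiling(object@nbits / 8))
    msg <- c(msg, sprintf("expected %d byte columns for %d bits, got %d",
                          ceiling(object@nbits / 8), object@nbits, ncol(b)))
  if (length(b) && (min(b) < 0L || max(b) > 255L))
    msg <- c(msg, "byte values must lie in [0, 255]")
  if (is.null(rownames(b)) && nrow(b) > 0)
    msg <- c(msg, "bytes must carry compound ids as rownames")
  if (anyDuplicated(rownames(b)))
    msg <- c(msg, sprintf("duplicate compound ids: %s",
                          paste(unique(rownames(b)[duplicated(rownames(b))]),
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ChemicalSpaceNetwork: sparse epsilon-thresholded Tanimoto network
#'
#' An undirected chemical space network over a compound library. Edges connect
#' pairs whose Tanimoto similarity strictly exceeds `epsilon`; the adjacency
#' is stored symmetrically (both directions of every upper-triangular hit)
#' with the similarity as edge weight, and carries no self loops. The
#' library's packed fingerprints are retained so that external (one-vs-all)
#' queries can be answered against the same network.
#'
#' @slot adjacency symmetric sparse `dgCMatrix` of similarities; dimnames are
#'   compound ids.
#' @slot epsilon numeric similarity threshold (default 0.4, strict).
#' @slot fingerprints the [FingerprintSet-class] the network was built from.
#' @export
setClass("ChemicalSpaceNetwork",
  representation(adjacency = "dgCMatrix", epsilon = "numeric",
                 fingerprints = "FingerprintSet")
)

setValidity("ChemicalSpaceNetwork", function(object) {
  msg <- character(0)
  A <- object@adjacency
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (is.null(rownames(A))) msg <- c(msg, "adjacency must carry compound ids")
  if (!isTRUE(all.equal(A, Matrix::t(A), tolerance = 0)))
    msg <- c(msg, "adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) msg <- c(msg, "self loops are not allowed")
  w <- A@x
  if (length(w) && (min(w) <= object@epsilon || max(w) > 1))
    msg <- c(msg, sprintf("edge weights must lie in (%g, 1]", object@epsilon))
  if (!identical(rownames(A), rownames(object@fingerprints@bytes)))
    msg <- c(msg, "adjacency ids must match fingerprint ids")
  if (length(msg)) msg else TRUE
})

#' NeighbourhoodGraph: one-hop directed graph with LaF edge features
#'
#' The per-query graph fed to the neighbourhood neural networks. All edges are
#' directed at the query node (row 1 of `nodeFeatures`); each edge carries the
#' neighbour's label information as its feature. In single-receptor mode the
#' edge feature is the 6-class one-hot of the neighbour's bioactivity on that
#' receptor plus the Tanimoto similarity (width 7). In multi-receptor mode it
#' is the flattened `nReceptors x 7` one-hot of the neighbour's class-or-no-
#' data across all receptors (width 896 for 128 receptors); similarities then
#' live only in the `similarities` slot.
#'
#' @slot queryId character, the query compound id.
#' @slot receptorId character, receptor id (`NA` in multi-receptor mode).
#' @slot mode `"single"` or `"multi"`.
#' @slot nodeFeatures numeric matrix `|V| x d`, query first, then neighbours.
#' @slot edgeFeatures numeric matrix `|E| x 7` or `|E| x (nReceptors*7)`.
#' @slot similarities numeric, Tanimoto similarity per edge.
#' @slot neighbourIds character, neighbour compound ids (one per edge).
#' @slot targetEmbedding numeric receptor embedding (length 0 in multi mode).
#' @slot label numeric one-hot length-6 vector (single mode; all `NA` when the
#'   query is unlabelled) or integer class-index vector of length `nReceptors`
#'   with `NA` no-data markers (multi mode).
#' @slot ood logical, `TRUE` when the graph has no labelled neighbour (the
#'   "no neighbourhood, no prediction" out-of-distribution guard).
#' @export
setClass("NeighbourhoodGraph",
  representation(queryId = "character", receptorId = "character",
                 mode = "character", nodeFeatures = "matrix",
                 edgeFeatures = "matrix", similarities = "numeric",
                 neighbourIds = "character", targetEmbedding = "numeric",
                 label = "numeric", ood = "logical")
)

setValidity("NeighbourhoodGraph", function(object) {
  msg <- character(0)
  nE <- length(object@neighbourIds)
  if (!object@mode %in% c("single", "multi"))
    msg <- c(msg, "mode must be 'single' or 'multi'")
  if (nrow(object@edgeFeatures) != nE || length(object@similarities) != nE)
    msg <- c(msg, "edge features, similarities and neighbour ids must agree")
  if (nrow(object@nodeFeatures) != nE + 1L)
    msg <- c(msg, "nodeFeatures must hold the query plus one row per edge")
  if (nE > 0) {
    w <- ncol(object@edgeFeatures)
    if (object@mode == "single") {
      if (w < 2) msg <- c(msg, "single-mode edge features need >= 2 columns")
      else {
        oh <- object@edgeFeatures[, -w, drop = FALSE]
        if (any(abs(rowSums(oh) - 1) > 1e-9))
          msg <- c(msg, "one-hot class block must sum to 1 per edge")
      }
    } else {
      if (w %% 7L != 0L)
        msg <- c(msg, "multi-mode edge feature width must be a multiple of 7")
      else {
        blockSums <- vapply(seq_len(w %/% 7L), function(b)
          rowSums(object@edgeFeatures[, (b - 1L) * 7L + 1:7, drop = FALSE]),
          numeric(nE))
        if (any(abs(blockSums - 1) > 1e-9))
          msg <- c(msg, "each 7-wide one-hot block must sum to 1")
      }
    }
  }
  if (object@ood && nE > 0)
    msg <- c(msg, "ood graphs must have zero edges")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet with %d compounds, %d bits (%d packed bytes)\n",
              nrow(object@bytes), object@nbits, ncol(object@bytes)))
  if (nrow(object@bytes)) {
    ids <- rownames(object@bytes)
    cat("  ids:", paste(head(ids, 5), collapse = ", "),
        if (length(ids) > 5) "..." else "", "\n")
  }
})

setMethod("show", "ChemicalSpaceNetwork", function(object) {
  ne <- length(object@adjacency@x) / 2
  cat(sprintf(
    "ChemicalSpaceNetwork: %d compounds, %d edges (Tanimoto > %g)\n",
    nrow(object@adjacency), ne, object@epsilon))
})

setMethod("show", "NeighbourhoodGraph", function(object) {
  cat(sprintf(
    "NeighbourhoodGraph [%s]: query %s%s, %d labelled neighbour(s)%s\n",
    object@mode, object@queryId,
    if (!is.na(object@receptorId)) paste0(" on ", object@receptorId) else "",
    length(object@neighbourIds), if (object@ood) " (OOD)" else ""))
})

#' @describeIn FingerprintSet-class number of compounds
#' @param x a `FingerprintSet`
#' @export
setMethod("length", "FingerprintSet", function(x) nrow(x@bytes))

#' Accessors for the core containers
#'
#' `fpIds()` returns compound ids; `nBits()` the unpacked bit length;
#' `packedBytes()` the packed byte matrix; `nodeIds()` the network's compound
#' ids; `epsilonSim()` the similarity threshold; `edgeTable()` the network's
#' undirected edge list as a three-column data frame.
#'
#' @param x a [FingerprintSet-class] or [ChemicalSpaceNetwork-class]
#' @return see details per accessor
#' @rdname accessors
#' @export
fpIds <- function(x) {
  if (is(x, "FingerprintSet")) rownames(x@bytes)
  else stop("fpIds() expects a FingerprintSet")
}

#' @rdname accessors
#' @export
nBits <- function(x) x@nbits

#' @rdname accessors
#' @export
packedBytes <- function(x) x@bytes

#' @rdname accessors
#' @export
nodeIds <- function(x) rownames(x@adjacency)

#' @rdname accessors
#' @export
epsilonSim <- function(x) x@epsilon

#' @rdname accessors
#' @export
csnFingerprints <- function(x) x@fingerprints

#' @rdname accessors
#' @export
edgeTable <- function(x) {
  stopifnot(is(x, "ChemicalSpaceNetwork"))
  A <- x@adjacency
  S <- Matrix::summary(Matrix::triu(A, k = 1))
  ids <- rownames(A)
  data.frame(id_i = ids[S$i], id_j = ids[S$j], similarity = S$x,
             stringsAsFactors = FALSE)
}

#' Subset a FingerprintSet by compound id or index
#' @param x a `FingerprintSet`
#' @param i character ids or numeric/logical indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = FALSE) {
  b <- x@bytes[i, , drop = FALSE]
  new("FingerprintSet", bytes = b, nbits = x@nbits)
})
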