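# deterministic per-string seed derived from a base seed
.stringSeed <- function(s, seed) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Dense compound representations (pluggable encoder)
#'
#' Maps packed fingerprints to fixed-length dense vectors. The default
#' encoder is a deterministic seeded random projection of the unpacked bits
#' to `dim` dimensions -- a stand-in with the same contract (deterministic,
#' fixed length, distinct fingerprints map to distinct vectors almost
#' surely) as a pretrained message-passing encoder, whose output table can
#' be supplied instead via `table`.
#'
#' @param fps a [FingerprintSet-class]
#' @param dim representation width (default 300)
#' @param seed projection seed
#' @param table optional precomputed matrix (rownames = compound ids) that
#'   overrides the projection for the ids it covers
#' @return numeric matrix, one row per compound, `dim` columns
#' @export
denseRepresentation <- function(fps, dim = 300L, seed = 1L, table = NULL) {
  nb <- fps@nbits
  withr::local_seed(.stringSeed("dense-encoder", seed))
  proj <- matrix(stats::rnorm(nb * dim), nb, dim) / sqrt(nb)
  bits <- t(apply(fps@bytes, 1, unpackFingerprint, nbits = nb))
  if (length(fps) == 1L) bits <- matrix(bits, nrow = 1)
  out <- bits %*% proj
  rownames(out) <- fpIds(fps)
  if (!is.null(table)) {
    hit <- intersect(rownames(out), rownames(table))
    out[hit, ] <- table[hit, seq_len(dim)]
  }
  out
}

#' Receptor embeddings (pluggable provider)
#'
#' Returns one fixed-length embedding per receptor. The default provider
#' draws a deterministic per-receptor seeded Gaussian vector (stable across
#' sessions and call order); a file-backed table of real protein-language-
#' model embeddings can be supplied instead.
#'
#' @param receptorIds character vector of receptor ids
#' @param dim embedding width (default 320)
#' @param seed base seed
#' @param table optional matrix (rownames = receptor ids) overriding the
#'   generated vectors; unknown receptors fall back to the generator
#' @return numeric matrix, one row per receptor, `dim` columns
#' @export
targetEmbedding <- function(receptorIds, dim = 320L, seed = 1L,
                            table = NULL) {
  out <- t(vapply(receptorIds, function(r) {
    if (!is.null(table) && r %in% rownames(table))
      return(as.numeric(table[r, seq_len(dim)]))
    withr::local_seed(.stringSeed(r, seed))
    stats::rnorm(dim)
  }, numeric(dim)))
  rownames(out) <- receptorIds
  out
}

#' Neighbour-source policy for transductive inference
#'
#' Under the admissible transductive protocol, training graphs draw their
#' neighbours from training compounds only (training data may refer to each
#' other), and evaluation graphs for test/validation queries also draw
#' neighbours from training compounds only. The query's own label never
#' appears among its edge features (the builders always exclude the query).
#'
#' @param split a split assignment frame from [scaffoldSplit()] or
#'   [iidSplit()]
#' @param mode `"train"` or `"eval"`
#' @return character vector of compound ids allowed as neighbours
#' @export
neighbourPolicy <- function(split, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  split$compound_id[split$partition == "train"]
}

#' Audit a set of graphs against the neighbour policy
#'
#' Verifies that every neighbour of every graph is an allowed source and
#' that no query appears in its own neighbour list. A violation is an error
#' (the policy is a correctness constraint, not a preference).
#'
#' @param graphs list of [NeighbourhoodGraph-class]
#' @param allowed character vector of allowed neighbour ids
#' @return invisibly `TRUE`; errors on violation
#' @export
auditPolicy <- function(graphs, allowed) {
  for (g in graphs) {
    bad <- setdiff(g@neighbourIds, allowed)
    if (length(bad))
      stop("policy violation for query ", g@queryId, ": disallowed ",
           paste(bad, collapse = ", "))
    if (g@queryId %in% g@neighbourIds)
      stop("policy violation: query ", g@queryId,
           " appears in its own neighbourhood")
  }
  invisible(TRUE)
}

# neighbours of queryId restricted to an allowed source set
.policyNeighbours <- function(csn, queryId, allowed, maxNeighbours) {
  nb <- queryNeighbours(csn, queryId, maxNeighbours = maxNeighbours)
  nb <- nb[nb$compound_id != queryId, , drop = FALSE]
  if (!is.null(allowed))
    nb <- nb[nb$compound_id %in% allowed, , drop = FALSE]
  nb
}

#' Build a single-receptor neighbourhood graph
#'
#' Assembles the one-hop directed graph for one (query, receptor) pair: one
#' edge per neighbour labelled on that receptor, each carrying the 6-class
#' one-hot of the neighbour's bioactivity plus the Tanimoto similarity
#' (width 7). Neighbours without a label on this receptor are dropped.
#' Zero labelled neighbours produce a valid single-node graph flagged OOD.
#'
#' @param queryId query compound id
#' @param receptorId receptor id
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param dti DTI frame (`compound_id`, `receptor_id`, `class`, optional
#'   `value`)
#' @param nodeRepr dense representation matrix from [denseRepresentation()]
#' @param targetEmb receptor embedding matrix from [targetEmbedding()]
#' @param scheme a [bioactivityClasses()] scheme
#' @param allowed optional allowed neighbour ids (see [neighbourPolicy()])
#' @param maxNeighbours neighbourhood cap (default 40)
#' @return a [NeighbourhoodGraph-class]
#' @export
buildGraphSingle <- function(queryId, receptorId, csn, dti, nodeRepr,
                             targetEmb, scheme = bioactivityClasses(),
                             allowed = NULL, maxNeighbours = 40L) {
  nb <- .policyNeighbours(csn, queryId, allowed, maxNeighbours)
  labels <- .labelLookup(dti, receptorId, scheme)
  cls <- labels[match(nb$compound_id, names(labels))]
  keep <- !is.na(cls)
  nb <- nb[keep, , drop = FALSE]
  cls <- as.integer(cls[keep])
  nE <- nrow(nb)
  ef <- matrix(0, nE, scheme$nClasses + 1L)
  if (nE) {
    ef[cbind(seq_len(nE), cls)] <- 1
    ef[, scheme$nClasses + 1L] <- nb$similarity
  }
  qlab <- rep(NA_real_, scheme$nClasses)
  own <- labels[queryId]
  if (!is.na(own)) { qlab[] <- 0; qlab[own] <- 1 }
  new("NeighbourhoodGraph",
      queryId = queryId, receptorId = receptorId, mode = "single",
      nodeFeatures = nodeRepr[c(queryId, nb$compound_id), , drop = FALSE],
      edgeFeatures = ef, similarities = nb$similarity,
      neighbourIds = nb$compound_id,
      targetEmbedding = as.numeric(targetEmb[receptorId, ]),
      label = qlab, ood = nE == 0L)
}

#' Build a multi-receptor neighbourhood graph
#'
#' One graph per query covering all receptors at once. Neighbours labelled
#' on any receptor contribute an edge whose feature is the flattened
#' `nReceptors x (nClasses + 1)` one-hot block: for each receptor, the
#' neighbour's class where data exist, the reserved no-data index otherwise
#' (width `128 x 7 = 896` at the defaults). The query label is the integer
#' class vector across receptors with `NA` no-data markers.
#'
#' @inheritParams buildGraphSingle
#' @param receptorIds ordered character vector of all receptors (its length
#'   sets the block count; default padding to `nReceptors`)
#' @param nReceptors total receptor slots (default 128); receptors beyond
#'   `length(receptorIds)` are constant no-data blocks
#' @return a [NeighbourhoodGraph-class]
#' @export
buildGraphMulti <- function(queryId, csn, dti, nodeRepr, receptorIds,
                            scheme = bioactivityClasses(),
                            nReceptors = 128L, allowed = NULL,
                            maxNeighbours = 40L) {
  stopifnot(length(receptorIds) <= nReceptors)
  nb <- .policyNeighbours(csn, queryId, allowed, maxNeighbours)
  width <- scheme$noDataIndex  # classes + no-data
  # per-compound class index across receptors (NA = no data)
  classOf <- function(cid) {
    d <- dti[dti$compound_id == cid, , drop = FALSE]
    idx <- rep(NA_integer_, nReceptors)
    ri <- match(d$receptor_id, receptorIds)
    ci <- match(d$class, scheme$classNames)
    ok <- !is.na(ri) & !is.na(ci)
    idx[ri[ok]] <- ci[ok]
    idx
  }
  nbClasses <- lapply(nb$compound_id, classOf)
  keep <- vapply(nbClasses, function(x) any(!is.na(x)), logical(1))
  nb <- nb[keep, , drop = FALSE]
  nbClasses <- nbClasses[keep]
  nE <- nrow(nb)
  ef <- matrix(0, nE, nReceptors * width)
  for (e in seq_len(nE)) {
    idx <- nbClasses[[e]]
    idx[is.na(idx)] <- scheme$noDataIndex
    ef[e, (seq_len(nReceptors) - 1L) * width + idx] <- 1
  }
  new("NeighbourhoodGraph",
      queryId = queryId, receptorId = NA_character_, mode = "multi",
      nodeFeatures = nodeRepr[c(queryId, nb$compound_id), , drop = FALSE],
      edgeFeatures = ef, similarities = nb$similarity,
      neighbourIds = nb$compound_id, targetEmbedding = numeric(0),
      label = as.numeric(classOf(queryId)), ood = nE == 0L)
}

# multi-receptor neighbourhood frequency vector (mean one-hot per block)
.multiEtot <- function(graph) {
  if (length(graph@neighbourIds) == 0)
    return(numeric(ncol(graph@edgeFeatures)))
  colMeans(graph@edgeFeatures)
}

#' Serialize / load neighbourhood graph datasets
#'
#' Writes a list of graphs as JSON lines at full numeric precision; reading
#' back reproduces the graphs exactly.
#'
#' @param graphs list of [NeighbourhoodGraph-class]
#' @param path output file
#' @return `writeDataset()` returns `path` invisibly; `readDataset()` the
#'   list of graphs.
#' @export
writeDataset <- function(graphs, path) {
  lines <- vapply(graphs, function(g) {
    as.character(jsonlite::toJSON(list(
      queryId = g@queryId, receptorId = g@receptorId, mode = g@mode,
      nodeFeatures = g@nodeFeatures, nodeIds = rownames(g@nodeFeatures),
      edgeFeatures = g@edgeFeatures, similarities = g@similarities,
      neighbourIds = g@neighbourIds, targetEmbedding = g@targetEmbedding,
      edgeWidth = ncol(g@edgeFeatures),
      label = g@label, ood = g@ood), digits = I(17), auto_unbox = TRUE,
      na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    asMat <- function(m, nr, nc) {
      m <- if (is.matrix(m)) m else matrix(as.numeric(unlist(m)), nr, nc)
      storage.mode(m) <- "double"
      m
    }
    nf <- asMat(x$nodeFeatures, length(x$nodeIds),
                length(unlist(x$nodeFeatures)) / length(x$nodeIds))
    rownames(nf) <- x$nodeIds
    nE <- length(x$neighbourIds)
    ef <- asMat(x$edgeFeatures, nE, x$edgeWidth)
    if (nE == 0) ef <- matrix(0, 0, x$edgeWidth)
    lab <- as.numeric(x$label)
    new("NeighbourhoodGraph", queryId = x$queryId,
        receptorId = if (is.null(x$receptorId)) NA_character_
                     else x$receptorId,
        mode = x$mode, nodeFeatures = nf, edgeFeatures = ef,
        similarities = as.numeric(unlist(x$similarities)),
        neighbourIds = as.character(unlist(x$neighbourIds)),
        targetEmbedding = as.numeric(unlist(x$targetEmbedding)),
        label = lab, ood = x$ood)
  })
}
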