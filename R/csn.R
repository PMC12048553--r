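#' Build a thresholded all-vs-all chemical space network
#'
#' Computes the full pairwise Tanimoto similarity over the library and keeps
#' exactly the pairs whose similarity strictly exceeds `epsilon` (values
#' \eqn{\le \epsilon} are set to zero to keep the adjacency sparse). The
#' adjacency is stored symmetrically with no self loops; construction is
#' deterministic.
#'
#' @param fps a [FingerprintSet-class] for the library
#' @param epsilon similarity threshold (default 0.4; edges require
#'   similarity strictly greater)
#' @return a [ChemicalSpaceNetwork-class]
#' @examples
#' sp <- generateSpace(syntheticSpec(nClusters = 4, compoundsPerCluster = 5,
#'                                   seed = 1))
#' csn <- buildCSN(sp$fingerprints)
#' csn
#' @export
buildCSN <- function(fps, epsilon = 0.4) {
  stopifnot(is(fps, "FingerprintSet"))
  n <- length(fps)
  if (n == 0) stop("library is empty")
  ids <- fpIds(fps)
  sim <- .tanimotoMatrix(fps@bytes, fps@nbits)
  diag(sim) <- 0
  sim[sim <= epsilon] <- 0
  A <- methods::as(methods::as(Matrix::Matrix(sim, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(A) <- list(ids, ids)
  new("ChemicalSpaceNetwork", adjacency = A, epsilon = epsilon,
      fingerprints = fps)
}

# order a (id, similarity) frame: similarity desc, ties by ascending id
.orderNeighbours <- function(df) df[order(-df$similarity, df$compound_id), ,
                                    drop = FALSE]

#' Query the neighbourhood of a member compound
#'
#' For `hops = 1` returns the direct neighbours sorted by descending
#' similarity (ties broken by ascending compound id), truncated to
#' `maxNeighbours`. For `hops > 1` returns every node within graph distance
#' `hops` (breadth-first search), annotated with its hop distance and its
#' direct Tanimoto similarity to the query; multi-hop queries serve
#' visualisation and leakage scans, not model input.
#'
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param queryId a compound id present in the network
#' @param hops neighbourhood radius (default 1)
#' @param maxNeighbours cap on returned neighbours (default 40)
#' @return data frame with columns `compound_id`, `similarity` and (for
#'   `hops > 1`) `hop`
#' @export
queryNeighbours <- function(csn, queryId, hops = 1L, maxNeighbours = 40L) {
  ids <- nodeIds(csn)
  if (!queryId %in% ids) stop("unknown compound id: ", queryId)
  A <- csn@adjacency
  if (hops == 1L) {
    col <- A[, queryId]
    nz <- which(col > 0)
    df <- data.frame(compound_id = ids[nz], similarity = col[nz],
                     stringsAsFactors = FALSE, row.names = NULL)
    df <- .orderNeighbours(df)
    return(utils::head(df, maxNeighbours))
  }
  # BFS out to `hops`
  dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  dist[queryId] <- 0L
  frontier <- queryId
  for (h in seq_len(hops)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- ids[which(A[, v] > 0)]
      new <- nb[is.na(dist[nb])]
      dist[new] <- h
      nxt <- c(nxt, new)
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  reached <- names(dist)[!is.na(dist) & dist > 0L]
  qfp <- csn@fingerprints@bytes[queryId, ]
  sims <- vapply(reached, function(i)
    tanimoto(qfp, csn@fingerprints@bytes[i, ]), numeric(1))
  df <- data.frame(compound_id = reached, similarity = unname(sims),
                   hop = unname(dist[reached]), stringsAsFactors = FALSE,
                   row.names = NULL)
  df <- df[order(-df$similarity, df$compound_id), , drop = FALSE]
  utils::head(df, maxNeighbours)
}

#' One-vs-all external query against a chemical space network
#'
#' The inference-time lookup: a query compound (not necessarily a member) is
#' scanned against every node, thresholded at the network's epsilon and
#' capped by similarity rank. A query with no neighbour above the threshold
#' returns an empty frame -- the out-of-distribution guard ("no
#' neighbourhood" implies no prediction).
#'
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param queryBytes packed fingerprint of the query (same packing/length as
#'   the network's library)
#' @param maxNeighbours cap on returned neighbours (default 40)
#' @return data frame with columns `compound_id`, `similarity`
#' @export
queryExternal <- function(csn, queryBytes, maxNeighbours = 40L) {
  fps <- csn@fingerprints
  if (length(queryBytes) != ncol(fps@bytes))
    stop("query fingerprint length does not match the library")
  qb <- matrix(as.integer(queryBytes), nrow = 1,
               dimnames = list("query", NULL))
  sims <- .tanimotoMatrix(qb, fps@nbits, fps@bytes)[1, ]
  keep <- which(sims > csn@epsilon)
  df <- data.frame(compound_id = fpIds(fps)[keep],
                   similarity = unname(sims[keep]),
                   stringsAsFactors = FALSE, row.names = NULL)
  utils::head(.orderNeighbours(df), maxNeighbours)
}

#' Serialize / load a chemical space network
#'
#' Writes the undirected edge list as a three-column table
#' `(id_i, id_j, similarity)` plus a JSON sidecar with the threshold,
#' fingerprint bit length, library hash and node ids, and the packed
#' fingerprints alongside.
#'
#' @param csn a [ChemicalSpaceNetwork-class]
#' @param dir output directory (created if missing)
#' @return `writeCSN()` returns `dir` invisibly; `readCSN()` the network.
#' @export
writeCSN <- function(csn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- edgeTable(csn)
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  writeFingerprints(csn@fingerprints, file.path(dir, "fingerprints.tsv"))
  meta <- list(format = "csnn-csn", version = 1L, epsilon = csn@epsilon,
               nbits = csn@fingerprints@nbits,
               n_nodes = length(nodeIds(csn)),
               library_hash = unname(tools::md5sum(
                 file.path(dir, "fingerprints.tsv"))),
               node_ids = nodeIds(csn))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)),
             file.path(dir, "csn.json"))
  invisible(dir)
}

#' @rdname writeCSN
#' @export
readCSN <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "csn.json"))
  if (!identical(meta$format, "csnn-csn")) stop("not a csnn network: ", dir)
  hash <- unname(tools::md5sum(file.path(dir, "fingerprints.tsv")))
  if (!identical(hash, meta$library_hash))
    stop("checksum mismatch: fingerprint library in ", dir,
         " does not match the recorded hash")
  fps <- readFingerprints(file.path(dir, "fingerprints.tsv"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"),
                           stringsAsFactors = FALSE)
  ids <- meta$node_ids
  i <- match(edges$id_i, ids)
  j <- match(edges$id_j, ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$similarity, 2),
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids))
  A <- methods::as(A, "CsparseMatrix")
  new("ChemicalSpaceNetwork", adjacency = A, epsilon = meta$epsilon,
      fingerprints = fps)
}
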