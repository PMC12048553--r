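#' Murcko-type scaffold of a molecule
#'
#' Computes the ring-framework scaffold by iteratively pruning terminal
#' (degree-1) heavy atoms from the molecular graph until only ring systems
#' and their linkers remain, then canonicalising the remaining substructure
#' as SMILES. Acyclic molecules have an empty scaffold and map to the
#' empty-string group. This graph-framework variant prunes all exocyclic
#' substituents (including double-bonded ones); what the splitter needs is a
#' consistent grouping key, which canonical SMILES provides.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules)
#' @export
murckoScaffold <- function(smiles) {
  vapply(smiles, function(s) {
    sdfset <- ChemmineR::smiles2sdf(stats::setNames(s, "q"))
    sdf <- sdfset[[1]]
    bb <- ChemmineR::bondblock(sdf)
    natoms <- nrow(ChemmineR::atomblock(sdf))
    if (is.null(bb) || nrow(bb) == 0) return("")
    edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    keep <- rep(TRUE, natoms)
    repeat {
      sube <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
      deg <- tabulate(c(sube), nbins = natoms)
      term <- keep & deg == 1L
      if (!any(term)) {
        keep <- keep & deg >= 2L  # drop isolated leftovers; rings survive
        break
      }
      keep[term] <- FALSE
    }
    if (!any(keep)) return("")
    sub <- ChemmineR::atomsubset(sdf, which(keep))
    scaf <- as.character(ChemmineR::sdf2smiles(
      new("SDFset", SDF = list(sub), ID = "scaffold")))
    scaf <- sub("\\s.*$", "", scaf)
    can <- tryCatch(ChemmineOB::convertFormat("SMILES", "CAN", scaf),
                    error = function(e) scaf)
    sub("\\s.*$", "", can)
  }, character(1), USE.NAMES = FALSE)
}

# greedy balanced assignment of groups to partitions
.assignGroups <- function(groupSizes, fractions, seed) {
  parts <- names(fractions)
  n <- sum(groupSizes)
  withr::local_seed(seed)
  ord <- order(-groupSizes, stats::runif(length(groupSizes)))
  filled <- stats::setNames(numeric(length(parts)), parts)
  assign <- character(length(groupSizes))
  for (g in ord) {
    deficit <- fractions * n - filled
    p <- parts[which.max(deficit)]
    assign[g] <- p
    filled[p] <- filled[p] + groupSizes[g]
  }
  assign
}

#' Scaffold-based train/test/validation split
#'
#' Groups compounds by scaffold and assigns whole scaffolds to partitions so
#' that no scaffold spans two partitions. Scaffolds are taken in order of
#' decreasing size (ties shuffled under the seed) and each is assigned
#' greedily to the partition with the largest remaining deficit relative to
#' its target fraction, approximating the requested fractions at compound
#' granularity. Deterministic under `seed`.
#'
#' @param compoundIds character vector of compound ids
#' @param scaffoldIds parallel vector of scaffold keys (e.g. from
#'   [murckoScaffold()], or synthetic cluster ids)
#' @param fractions named numeric fractions summing to 1
#'   (default `c(train = 0.8, test = 0.1, val = 0.1)`)
#' @param seed integer seed
#' @return data frame with columns `compound_id`, `scaffold_id`, `partition`
#' @export
scaffoldSplit <- function(compoundIds, scaffoldIds,
                          fractions = c(train = 0.8, test = 0.1, val = 0.1),
                          seed = 1L) {
  stopifnot(length(compoundIds) == length(scaffoldIds),
            abs(sum(fractions) - 1) < 1e-9, !is.null(names(fractions)))
  groups <- split(compoundIds, scaffoldIds)
  sizes <- lengths(groups)
  assign <- .assignGroups(sizes, fractions, seed)
  out <- data.frame(
    compound_id = unlist(groups, use.names = FALSE),
    scaffold_id = rep(names(groups), sizes),
    partition = rep(assign, sizes),
    stringsAsFactors = FALSE, row.names = NULL)
  out[match(compoundIds, out$compound_id), , drop = FALSE]
}

#' Record-level i.i.d. split
#'
#' Assigns compounds to partitions independently at the requested fractions,
#' ignoring scaffold structure.
#'
#' @inheritParams scaffoldSplit
#' @return data frame with columns `compound_id`, `partition`
#' @export
iidSplit <- function(compoundIds,
                     fractions = c(train = 0.8, test = 0.1, val = 0.1),
                     seed = 1L) {
  withr::local_seed(seed)
  n <- length(compoundIds)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  partition <- sample(rep(names(fractions), counts))
  data.frame(compound_id = compoundIds, partition = partition,
             stringsAsFactors = FALSE)
}

#' Remove compounds chemically close to a held-out set
#'
#' Drops every dataset compound whose Tanimoto similarity to any held-out
#' compound strictly exceeds `threshold` (default 0.65), preventing data
#' leakage between the modelling data and an experimental validation
#' library. Similarity exactly at the threshold is retained.
#'
#' @param fps a [FingerprintSet-class] covering both sets
#' @param datasetIds compound ids of the modelling dataset
#' @param heldOutIds compound ids of the held-out (validation) library
#' @param threshold leakage similarity threshold (default 0.65, strict
#'   "over")
#' @return character vector of retained dataset ids; the dropped ids are
#'   attached as `attr(, "removed")`
#' @export
leakageFilter <- function(fps, datasetIds, heldOutIds, threshold = 0.65) {
  stopifnot(all(datasetIds %in% fpIds(fps)),
            all(heldOutIds %in% fpIds(fps)))
  if (!length(heldOutIds) || !length(datasetIds)) {
    out <- datasetIds
    attr(out, "removed") <- character(0)
    return(out)
  }
  sim <- .tanimotoMatrix(fps@bytes[datasetIds, , drop = FALSE], fps@nbits,
                         fps@bytes[heldOutIds, , drop = FALSE])
  leaky <- apply(sim, 1, max) > threshold
  out <- datasetIds[!leaky]
  attr(out, "removed") <- datasetIds[leaky]
  out
}
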