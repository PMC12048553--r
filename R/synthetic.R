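#' Specification for a synthetic homophilous chemical space
#'
#' The generator emulates the structural premise of homophilous DTI data:
#' compounds fall into chemical clusters (prototype bit vectors mutated at a
#' small per-bit flip rate, so within-cluster Tanimoto similarity is high),
#' and each (cluster, receptor) pair carries a latent bioactivity class and
#' latent affinity. A compound inherits its cluster's class on a receptor
#' with probability `homophily` (otherwise a uniformly random other class),
#' its affinity is the latent value plus Gaussian noise, and each
#' (compound, receptor) label is retained i.i.d. with probability
#' `1 - labelSparsity`. Everything is reproducible under `seed`.
#'
#' @param nClusters number of chemical clusters (default 20)
#' @param compoundsPerCluster compounds per cluster (default 10)
#' @param fingerprintLength toy fingerprint bits (default 512)
#' @param prototypeDensity fraction of set bits in prototypes (default 0.1)
#' @param flipRate per-bit mutation probability for members (default 0.01)
#' @param nReceptors number of receptors (default 8)
#' @param homophily probability of inheriting the cluster class
#'   (default 0.9)
#' @param labelSparsity fraction of (compound, receptor) labels dropped
#'   (default 0.5)
#' @param regressionNoiseSd sd of affinity noise on the -log10(Ki) scale
#'   (default 0.3)
#' @param nClasses number of bioactivity classes (default 6)
#' @param affinityRange latent affinity range on -log10(Ki)
#'   (default c(4, 9))
#' @param seed master seed
#' @return list of class `syntheticSpec`
#' @export
syntheticSpec <- function(nClusters = 20L, compoundsPerCluster = 10L,
                          fingerprintLength = 512L, prototypeDensity = 0.1,
                          flipRate = 0.01, nReceptors = 8L, homophily = 0.9,
                          labelSparsity = 0.5, regressionNoiseSd = 0.3,
                          nClasses = 6L, affinityRange = c(4, 9),
                          seed = 1L) {
  stopifnot(nClusters >= 1, compoundsPerCluster >= 1,
            prototypeDensity >= 0, prototypeDensity <= 1,
            flipRate >= 0, flipRate <= 1,
            homophily >= 0, homophily <= 1,
            labelSparsity >= 0, labelSparsity <= 1,
            regressionNoiseSd >= 0)
  structure(as.list(environment()), class = "syntheticSpec")
}

#' Generate a synthetic homophilous chemical space
#'
#' @param spec a [syntheticSpec()]
#' @return list with:
#'   * `fingerprints`: [FingerprintSet-class] of the toy compounds;
#'   * `compounds`: data frame `compound_id`, `cluster` (ground truth);
#'   * `dti`: retained labels, columns `compound_id`, `receptor_id`,
#'     `class`, `value`;
#'   * `dtiFull`: the same before sparsification (for audits);
#'   * `truth`: per (cluster, receptor) latent class and affinity;
#'   * `scheme`: the [bioactivityClasses()] scheme used;
#'   * `receptorIds`: receptor ids.
#' @export
generateSpace <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withr::local_seed(spec$seed)
  scheme <- bioactivityClasses()
  stopifnot(spec$nClasses == scheme$nClasses)
  nCmp <- spec$nClusters * spec$compoundsPerCluster
  ids <- sprintf("CPD%04d", seq_len(nCmp))
  cluster <- rep(seq_len(spec$nClusters), each = spec$compoundsPerCluster)
  receptorIds <- sprintf("REC%03d", seq_len(spec$nReceptors))
  bits <- matrix(0L, nCmp, spec$fingerprintLength)
  for (k in seq_len(spec$nClusters)) {
    proto <- stats::rbinom(spec$fingerprintLength, 1L, spec$prototypeDensity)
    if (sum(proto) == 0) proto[k] <- 1L  # never an empty prototype
    members <- which(cluster == k)
    for (m in members) {
      flips <- stats::rbinom(spec$fingerprintLength, 1L, spec$flipRate)
      bits[m, ] <- bitwXor(proto, flips)
    }
  }
  rownames(bits) <- ids
  truth <- expand.grid(cluster = seq_len(spec$nClusters),
                       receptor_id = receptorIds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$class_idx <- sample.int(scheme$nClasses, nrow(truth), replace = TRUE)
  truth$affinity <- stats::runif(nrow(truth), spec$affinityRange[1],
                                 spec$affinityRange[2])
  full <- expand.grid(compound_id = ids, receptor_id = receptorIds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full$cluster <- cluster[match(full$compound_id, ids)]
  ti <- match(paste(full$cluster, full$receptor_id),
              paste(truth$cluster, truth$receptor_id))
  latentClass <- truth$class_idx[ti]
  inherit <- stats::runif(nrow(full)) < spec$homophily
  other <- vapply(latentClass, function(c0)
    sample(setdiff(seq_len(scheme$nClasses), c0), 1L), integer(1))
  full$class_idx <- ifelse(inherit, latentClass, other)
  full$class <- scheme$classNames[full$class_idx]
  full$value <- truth$affinity[ti] +
    stats::rnorm(nrow(full), 0, spec$regressionNoiseSd)
  keep <- stats::runif(nrow(full)) >= spec$labelSparsity
  dti <- full[keep, c("compound_id", "receptor_id", "class", "value")]
  rownames(dti) <- NULL
  list(fingerprints = fingerprintSet(bits),
       compounds = data.frame(compound_id = ids, cluster = cluster,
                              stringsAsFactors = FALSE),
       dti = dti,
       dtiFull = full[, c("compound_id", "receptor_id", "class", "value",
                          "cluster", "class_idx")],
       truth = truth, scheme = scheme, receptorIds = receptorIds)
}

#' Simulate a single-point luminescence screen
#'
#' Inactive (compound, receptor) pairs draw log10 RLU from a per-receptor
#' Gaussian baseline; active pairs are shifted upward by `effectSize`
#' standard deviations. With `effectSize = 0` the hit rate at threshold 3
#' equals the Gaussian tail mass; at 6 sd essentially every active pair is
#' called.
#'
#' @param truth data frame with columns `compound_id`, `receptor_id`,
#'   `active` (logical)
#' @param effectSize shift of active pairs in units of the baseline sd
#'   (default 6)
#' @param baselineMean,baselineSd per-receptor log10 RLU baseline
#'   parameters (defaults 4 and 0.25)
#' @param seed seed
#' @return data frame `compound_id`, `receptor_id`, `rlu`, `active`
#' @export
generateScreen <- function(truth, effectSize = 6, baselineMean = 4,
                           baselineSd = 0.25, seed = 1L) {
  withr::local_seed(seed)
  x <- stats::rnorm(nrow(truth), baselineMean, baselineSd) +
    ifelse(truth$active, effectSize * baselineSd, 0)
  data.frame(compound_id = truth$compound_id,
             receptor_id = truth$receptor_id,
             rlu = 10^x, active = truth$active, stringsAsFactors = FALSE)
}
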