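#' Read a drug-target interaction table
#'
#' Reads a CSV/TSV with columns `compound_id`, `receptor_id`, `class` and
#' optionally `value` (-log10 Ki), normalised to one row per unique DTI.
#' Class names are validated against the scheme; duplicated
#' (compound, receptor) pairs with conflicting classes are an error listing
#' the conflicts, and consistent duplicates are collapsed.
#'
#' @param path file path (separator inferred from the extension: `.tsv` ->
#'   tab, otherwise comma)
#' @param scheme a [bioactivityClasses()] scheme
#' @return data frame with columns `compound_id`, `receptor_id`, `class`,
#'   `value`
#' @export
readDTITable <- function(path, scheme = bioactivityClasses()) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("compound_id", "receptor_id", "class")
  if (!all(need %in% names(d)))
    stop("DTI table must have columns: ", paste(need, collapse = ", "))
  if (!"value" %in% names(d)) d$value <- NA_real_
  bad <- !is.na(d$class) & !d$class %in% scheme$classNames
  if (any(bad))
    stop("unknown class name(s) in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(d$class[bad]), collapse = ", "))
  key <- paste(d$compound_id, d$receptor_id, sep = "\r")
  dupKeys <- unique(key[duplicated(key)])
  conflicts <- Filter(function(k)
    length(unique(d$class[key == k])) > 1, dupKeys)
  if (length(conflicts)) {
    pretty <- vapply(strsplit(conflicts, "\r", fixed = TRUE),
                     paste, "", collapse = "/")
    stop("conflicting duplicate DTIs: ", paste(pretty, collapse = ", "))
  }
  d <- d[!duplicated(key), c("compound_id", "receptor_id", "class", "value")]
  rownames(d) <- NULL
  d
}

#' Read a compound table
#'
#' @param path CSV/TSV with columns `compound_id`, `smiles`
#' @return data frame
#' @export
readCompoundTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("compound_id", "smiles") %in% names(d)))
    stop("compound table must have columns compound_id, smiles")
  if (anyDuplicated(d$compound_id))
    stop("duplicate compound ids: ",
         paste(unique(d$compound_id[duplicated(d$compound_id)]),
               collapse = ", "))
  d
}

#' Annotation coverage arithmetic
#'
#' Size of the full compound-by-receptor interaction matrix and the
#' percentage of it that carries annotations.
#'
#' @param nCompounds number of unique compounds
#' @param nReceptors number of receptors
#' @param nAnnotated number of annotated (compound, receptor) pairs
#' @return list with `possible`, `coveragePct`
#' @export
coverageStats <- function(nCompounds, nReceptors, nAnnotated) {
  possible <- as.numeric(nCompounds) * as.numeric(nReceptors)
  list(possible = possible, coveragePct = 100 * nAnnotated / possible)
}

#' Pipeline configuration
#'
#' One place for every threshold and seed so that a run is fully
#' reproducible: the CSN similarity threshold, leakage threshold,
#' prediction-confidence threshold, Z-score threshold and Ki cutoff appear
#' here and nowhere else.
#'
#' @param seed master seed
#' @param space a [syntheticSpec()] describing the simulated library
#' @param epsilon CSN similarity threshold (default 0.4)
#' @param leakageThreshold leakage similarity threshold (default 0.65)
#' @param confidenceThreshold prediction confidence cutoff (default 0.8)
#' @param zThreshold hit-calling threshold (default 3)
#' @param kiThresholdNm predicted-hit Ki cutoff in nM (default 100)
#' @param maxNeighbours neighbourhood cap (default 40)
#' @param train a [csnnConfig()] for the single-receptor model (or `NULL`
#'   to skip training)
#' @return list of class `runConfig`
#' @export
runConfig <- function(seed = 1L, space = syntheticSpec(seed = seed),
                      epsilon = 0.4, leakageThreshold = 0.65,
                      confidenceThreshold = 0.8, zThreshold = 3,
                      kiThresholdNm = 100, maxNeighbours = 40L,
                      train = NULL) {
  structure(list(seed = as.integer(seed), space = space, epsilon = epsilon,
                 leakageThreshold = leakageThreshold,
                 confidenceThreshold = confidenceThreshold,
                 zThreshold = zThreshold, kiThresholdNm = kiThresholdNm,
                 maxNeighbours = as.integer(maxNeighbours), train = train),
            class = "runConfig")
}

# stable hash of a config (serialised to a temp file, md5)
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(
    rapply(unclass(config), unclass, how = "replace"),
    auto_unbox = TRUE, digits = I(17), force = TRUE)), f)
  unname(tools::md5sum(f))
}

#' Run the simulated end-to-end pipeline
#'
#' Generates a synthetic homophilous space, builds the CSN, splits the
#' compounds (clusters act as scaffold groups), evaluates the training-free
#' argmax predictor and the neighbourhood-mean regressor on the evaluation
#' partition under the transductive neighbour policy, simulates a screen
#' with Z-score hit calling and enrichment, and (optionally) trains the
#' single-receptor neighbourhood network. Identical configs give identical
#' reports; every artifact carries the config hash.
#'
#' @param config a [runConfig()]
#' @param outDir optional directory to write artifacts (edge table, metrics
#'   JSON)
#' @return list of stage results, with `configHash`
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  hash <- .configHash(config)
  sp <- generateSpace(config$space)
  csn <- buildCSN(sp$fingerprints, epsilon = config$epsilon)
  split <- scaffoldSplit(sp$compounds$compound_id,
                         as.character(sp$compounds$cluster),
                         seed = config$seed)
  evalIds <- split$compound_id[split$partition != "train"]
  labelled <- sp$dti[sp$dti$compound_id %in% evalIds, , drop = FALSE]
  truth <- integer(0); pred <- integer(0)
  truthV <- numeric(0); predV <- numeric(0)
  # training-free LaF predictions are transductive: any compound except the
  # query itself may serve as a neighbour
  for (r in seq_len(nrow(labelled))) {
    q <- labelled$compound_id[r]; rec <- labelled$receptor_id[r]
    nb <- .policyNeighbours(csn, q, NULL, config$maxNeighbours)
    lf <- labelFrequency(nb, sp$dti, sp$scheme, receptorId = rec)
    ap <- argmaxPredict(lf)
    truth <- c(truth, match(labelled$class[r], sp$scheme$classNames))
    pred <- c(pred, ap$class)
    vals <- sp$dti[sp$dti$receptor_id == rec, ]
    lookup <- stats::setNames(vals$value, vals$compound_id)
    truthV <- c(truthV, labelled$value[r])
    predV <- c(predV, aggregateRegression(nb, lookup, "mean"))
  }
  cls <- classificationMetrics(truth, pred, sp$scheme$nClasses)
  reg <- regressionMetrics(truthV, predV)
  # simulated screen: agonism is what the reporter assay detects
  active <- sp$dtiFull$class == "Agonist"
  screenTruth <- data.frame(compound_id = sp$dtiFull$compound_id,
                            receptor_id = sp$dtiFull$receptor_id,
                            active = active)
  screen <- generateScreen(screenTruth, seed = config$seed + 7L)
  zs <- zScore(screen)
  zs$hit <- callHits(zs$z, config$zThreshold)
  fit <- NULL
  if (!is.null(config$train)) {
    nodeRepr <- denseRepresentation(sp$fingerprints, seed = config$seed)
    targetEmb <- targetEmbedding(sp$receptorIds, seed = config$seed)
    trainIds <- split$compound_id[split$partition == "train"]
    trainDti <- sp$dti[sp$dti$compound_id %in% trainIds, , drop = FALSE]
    graphs <- lapply(seq_len(nrow(trainDti)), function(i)
      buildGraphSingle(trainDti$compound_id[i], trainDti$receptor_id[i],
                       csn, trainDti, nodeRepr, targetEmb, sp$scheme,
                       allowed = setdiff(trainIds, trainDti$compound_id[i]),
                       maxNeighbours = config$maxNeighbours))
    fit <- csnnTrain(graphs, config$train)
  }
  out <- list(configHash = hash, space = sp, csn = csn, split = split,
              argmaxMetrics = cls, regressionMetrics = reg,
              screen = zs, model = fit)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCSN(csn, file.path(outDir, "csn"))
    report <- list(config_hash = hash, seed = config$seed,
                   argmax_weighted_f1 = cls$weightedF1,
                   mean_regression_mse = reg$mse,
                   screen_hit_rate = mean(zs$hit))
    writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                             digits = I(17))),
               file.path(outDir, "report.json"))
  }
  out
}
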