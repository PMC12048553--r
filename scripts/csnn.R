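#!/usr/bin/env Rscript
# Thin command-line front end over the csnn package.
#
#   Rscript scripts/csnn.R simulate --seed 1 --out fixtures/
#   Rscript scripts/csnn.R build-csn --library compounds.csv --epsilon 0.4 --out csn/
#   Rscript scripts/csnn.R predict-argmax --csn csn/ --labels dti.csv \
#       --queries queries.csv --receptor REC001 --out preds.csv
#   Rscript scripts/csnn.R zscore --screen plate.csv --threshold 3 \
#       --mode plain|modified --out hits.csv

suppressPackageStartupMessages(library(csnn))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: csnn.R <simulate|build-csn|predict-argmax|zscore> ...")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}

if (cmd == "simulate") {
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "fixtures")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sp <- generateSpace(syntheticSpec(seed = seed))
  writeFingerprints(sp$fingerprints, file.path(out, "fingerprints.tsv"))
  write.csv(sp$dti, file.path(out, "dti.csv"), row.names = FALSE)
  write.csv(sp$compounds, file.path(out, "compounds.csv"), row.names = FALSE)
  cat("simulated", length(sp$fingerprints), "compounds,",
      nrow(sp$dti), "DTIs ->", out, "\n")

} else if (cmd == "build-csn") {
  lib <- opt("--library")
  fpPath <- opt("--fingerprints")
  eps <- as.numeric(opt("--epsilon", "0.4"))
  out <- opt("--out", "csn")
  fps <- if (!is.null(fpPath)) readFingerprints(fpPath)
         else encodeLibrary(readCompoundTable(lib))
  csn <- buildCSN(fps, epsilon = eps)
  writeCSN(csn, out)
  cat("built network:", length(nodeIds(csn)), "nodes,",
      nrow(edgeTable(csn)), "edges ->", out, "\n")

} else if (cmd == "predict-argmax") {
  csn <- readCSN(opt("--csn", "csn"))
  dti <- readDTITable(opt("--labels"))
  queries <- read.csv(opt("--queries"), stringsAsFactors = FALSE)
  receptor <- opt("--receptor")
  scheme <- bioactivityClasses()
  rows <- lapply(queries$compound_id, function(q) {
    nb <- queryNeighbours(csn, q)
    lf <- labelFrequency(nb, dti, scheme, receptorId = receptor)
    p <- argmaxPredict(lf)
    cbind(data.frame(compound_id = q, receptor_id = receptor,
                     predicted_class = ifelse(is.na(p$class), "ABSTAIN",
                                              p$className),
                     support = p$support, tie_flag = p$tie),
          as.data.frame(as.list(p$freqs), check.names = FALSE))
  })
  out <- opt("--out", "predictions.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  cat("wrote", length(rows), "predictions ->", out, "\n")

} else if (cmd == "zscore") {
  screen <- read.csv(opt("--screen"), stringsAsFactors = FALSE)
  threshold <- as.numeric(opt("--threshold", "3"))
  mode <- opt("--mode", "plain")
  excl <- opt("--exclude")
  exclude <- if (is.null(excl)) character(0)
             else read.csv(excl, stringsAsFactors = FALSE)$compound_id
  res <- if (mode == "modified") {
    r <- modifiedZScore(screen, exclude = exclude)
    r$hit <- callHits(r$z_mod, threshold)
    r
  } else {
    r <- zScore(screen, exclude = exclude)
    r$hit <- callHits(r$z, threshold)
    r
  }
  out <- opt("--out", "zscores.csv")
  write.csv(res, out, row.names = FALSE)
  cat("wrote", nrow(res), "rows (", sum(res$hit), "hits ) ->", out, "\n")

} else {
  stop("unknown subcommand: ", cmd)
}
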