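test_that("network construction matches the naive all-pairs oracle", {
  B <- toyBits(50, seed = 11)
  csn <- buildCSN(fingerprintSet(B), 0.4)
  got <- edgeTable(csn)
  want <- bruteForceEdges(B, 0.4)
  expect_identical(edgeKey(got), edgeKey(want))
})

test_that("the similarity threshold is strict and duplicates give unit edges", {
  # bits chosen so tanimoto is exactly 0.4: |a & b| = 2, |a | b| = 5
  bits <- rbind(a = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
                b = c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L))
  csn <- buildCSN(fingerprintSet(bits), 0.4)
  expect_equal(nrow(edgeTable(csn)), 0)
  # same compound under two ids connects at similarity 1
  dup <- rbind(x = c(1L, 0L, 1L, 0L), y = c(1L, 0L, 1L, 0L))
  csn2 <- buildCSN(fingerprintSet(dup), 0.4)
  et <- edgeTable(csn2)
  expect_equal(et$similarity, 1)
})

test_that("raising the threshold never adds edges", {
  B <- toyBits(40, seed = 5)
  fps <- fingerprintSet(B)
  e1 <- edgeKey(edgeTable(buildCSN(fps, 0.3)))
  e2 <- edgeKey(edgeTable(buildCSN(fps, 0.5)))
  expect_true(all(vapply(strsplit(e2, " "), function(x) TRUE, logical(1))))
  # every 0.5-edge key appears among the 0.3-edge keys
  expect_true(all(e2 %in% e1))
  expect_lte(length(e2), length(e1))
})

test_that("neighbour queries sort, cap and break ties deterministically", {
  sp <- smallSpace()
  csn <- buildCSN(sp$fingerprints)
  nb <- queryNeighbours(csn, "CPD0001")
  expect_true(all(diff(nb$similarity) <= 0))
  expect_lte(nrow(nb), 40)
  expect_error(queryNeighbours(csn, "nope"), "unknown")
  # isolated node: a compound nothing else resembles
  bits <- rbind(toyBits(3, nbits = 32, seed = 2),
                iso = c(rep(1L, 16), rep(0L, 16)) * 0L + rep(c(0L, 1L), 16))
  rownames(bits)[4] <- "iso"
  # make iso orthogonal to the others
  bits["iso", ] <- 0L; bits["iso", 31:32] <- 1L
  csn2 <- buildCSN(fingerprintSet(bits), 0.4)
  expect_equal(nrow(queryNeighbours(csn2, "iso")), 0)
})

test_that("a 45-neighbour star truncates to the 40 most similar", {
  # query shares decreasing bit overlap with 45 neighbours
  n <- 45
  nbits <- 200
  B <- matrix(0L, n + 1, nbits)
  B[1, 1:100] <- 1L  # query
  for (i in seq_len(n)) B[i + 1, 1:(100 - i)] <- 1L  # overlap shrinks with i
  rownames(B) <- c("query", sprintf("n%02d", seq_len(n)))
  csn <- buildCSN(fingerprintSet(B), 0.4)
  nb <- queryNeighbours(csn, "query", maxNeighbours = 40)
  full <- queryNeighbours(csn, "query", maxNeighbours = n + 1)
  expect_gt(nrow(full), 40)
  expect_equal(nrow(nb), 40)
  expect_identical(nb$compound_id, full$compound_id[1:40])
})

test_that("multi-hop queries follow graph distance", {
  # chain a-b-c: a ~ b ~ c but a !~ c
  B <- rbind(a = c(rep(1L, 8), rep(0L, 8)),
             b = c(rep(0L, 4), rep(1L, 8), rep(0L, 4)),
             c = c(rep(0L, 8), rep(1L, 8)))
  csn <- buildCSN(fingerprintSet(B), 0.3)
  expect_identical(sort(queryNeighbours(csn, "a", hops = 1)$compound_id),
                   "b")
  two <- queryNeighbours(csn, "a", hops = 2)
  expect_identical(sort(two$compound_id), c("b", "c"))
  expect_equal(two$hop[two$compound_id == "c"], 2)
})

test_that("external one-vs-all queries equal a brute-force scan", {
  B <- toyBits(20, seed = 9)
  fps <- fingerprintSet(B)
  csn <- buildCSN(fps, 0.4)
  # a member as external query: itself first at similarity 1
  hits <- queryExternal(csn, packedBytes(fps)["c003", ])
  expect_equal(hits$compound_id[1], "c003")
  expect_equal(hits$similarity[1], 1)
  # brute-force oracle for an external compound
  q <- withr::with_seed(77, as.integer(rbinom(64, 1, 0.3)))
  want <- vapply(seq_len(20), function(i) bitTanimoto(q, B[i, ]), numeric(1))
  got <- queryExternal(csn, packFingerprint(q))
  keep <- which(want > 0.4)
  expect_setequal(got$compound_id, rownames(B)[keep])
  # a query dissimilar to everything abstains (empty neighbourhood)
  far <- integer(64); far[64] <- 1L
  expect_equal(nrow(queryExternal(csn, packFingerprint(far))), 0)
})

test_that("networks serialize, verify their checksum and reload exactly", {
  sp <- smallSpace()
  csn <- buildCSN(sp$fingerprints)
  dir <- withr::local_tempdir()
  writeCSN(csn, dir)
  back <- readCSN(dir)
  expect_identical(edgeKey(edgeTable(back)), edgeKey(edgeTable(csn)))
  expect_equal(epsilonSim(back), epsilonSim(csn))
  # tampering with the stored library is detected
  cat("tamper\n", file = file.path(dir, "fingerprints.tsv"), append = TRUE)
  expect_error(readCSN(dir), "checksum")
})
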