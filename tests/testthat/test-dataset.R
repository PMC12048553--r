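sp <- smallSpace()
csn <- buildCSN(sp$fingerprints)
nodeRepr <- denseRepresentation(sp$fingerprints, dim = 12, seed = 2)
targetEmb <- targetEmbedding(sp$receptorIds, dim = 8, seed = 2)

test_that("encoders are deterministic, dimensioned and discriminative", {
  again <- denseRepresentation(sp$fingerprints, dim = 12, seed = 2)
  expect_identical(nodeRepr, again)
  wide <- denseRepresentation(sp$fingerprints[1:3], seed = 2)
  expect_equal(ncol(wide), 300)
  # distinct fingerprints map to distinct vectors on a 10-compound fixture
  expect_equal(nrow(unique(round(nodeRepr[1:10, ], 10))), 10)
  # receptor embeddings: deterministic, per-receptor, order-independent
  t1 <- targetEmbedding(c("REC001", "REC002"), dim = 320, seed = 5)
  t2 <- targetEmbedding(c("REC002", "REC001"), dim = 320, seed = 5)
  expect_equal(ncol(t1), 320)
  expect_identical(t1["REC001", ], t2["REC001", ])
  expect_false(identical(t1["REC001", ], t1["REC002", ]))
  # file-backed table overrides the generator
  tab <- matrix(1, 1, 8, dimnames = list("REC001", NULL))
  t3 <- targetEmbedding(c("REC001", "REC002"), dim = 8, table = tab)
  expect_equal(unname(t3["REC001", ]), rep(1, 8))
})

test_that("single-receptor graphs carry one-hot + similarity edge features", {
  g <- buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr,
                        targetEmb, sp$scheme)
  expect_s4_class(g, "NeighbourhoodGraph")
  expect_equal(ncol(g@edgeFeatures), 7)
  nE <- length(g@neighbourIds)
  expect_gt(nE, 0)
  # one-hot block sums to 1 and the similarity column equals the network's
  expect_equal(unname(rowSums(g@edgeFeatures[, 1:6, drop = FALSE])),
               rep(1, nE))
  nb <- queryNeighbours(csn, "CPD0001")
  expect_equal(g@edgeFeatures[, 7],
               nb$similarity[match(g@neighbourIds, nb$compound_id)])
  expect_equal(nrow(g@nodeFeatures), nE + 1)
  expect_length(g@targetEmbedding, 8)
  # zero labelled neighbours -> valid single-node OOD graph
  noLabels <- sp$dti[0, ]
  g0 <- buildGraphSingle("CPD0001", "REC001", csn, noLabels, nodeRepr,
                         targetEmb, sp$scheme)
  expect_true(g0@ood)
  expect_equal(length(g0@neighbourIds), 0)
  expect_equal(nrow(g0@nodeFeatures), 1)
})

test_that("multi-receptor graphs expand class-or-no-data blocks per receptor", {
  g <- buildGraphMulti("CPD0001", csn, sp$dti, nodeRepr, sp$receptorIds,
                       sp$scheme, nReceptors = 8)
  expect_equal(ncol(g@edgeFeatures), 8 * 7)
  expect_length(g@label, 8)
  # a neighbour labelled on exactly 2 of 8 receptors has 6 no-data blocks
  nbId <- g@neighbourIds[1]
  dti2 <- sp$dti[!(sp$dti$compound_id == nbId &
                     !sp$dti$receptor_id %in% c("REC001", "REC002")), ]
  # ensure the neighbour is labelled on both kept receptors
  add <- data.frame(compound_id = nbId, receptor_id = c("REC001", "REC002"),
                    class = "Agonist", value = 5)
  dti2 <- unique(rbind(dti2[, names(add)], add))
  g2 <- buildGraphMulti("CPD0001", csn, dti2, nodeRepr, sp$receptorIds,
                        sp$scheme, nReceptors = 8)
  e <- g2@edgeFeatures[match(nbId, g2@neighbourIds), ]
  blocks <- matrix(e, ncol = 7, byrow = TRUE)
  expect_equal(sum(blocks[, 7]), 6)  # no-data marker on 6 of 8 receptors
  expect_equal(unname(rowSums(blocks)), rep(1, 8))
  # single- and multi-mode graphs agree on node features and similarities
  gs <- buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr,
                         targetEmb, sp$scheme)
  common <- intersect(gs@neighbourIds, g@neighbourIds)
  expect_gt(length(common), 0)
  expect_equal(g@similarities[match(common, g@neighbourIds)],
               gs@similarities[match(common, gs@neighbourIds)])
  expect_equal(g@nodeFeatures[common, ], gs@nodeFeatures[common, ])
})

test_that("the transductive neighbour policy is enforced and auditable", {
  split <- scaffoldSplit(sp$compounds$compound_id,
                         as.character(sp$compounds$cluster), seed = 4)
  allowed <- neighbourPolicy(split, "eval")
  expect_setequal(allowed, split$compound_id[split$partition == "train"])
  testIds <- split$compound_id[split$partition == "test"]
  graphs <- lapply(testIds, function(q)
    buildGraphSingle(q, "REC001", csn, sp$dti, nodeRepr, targetEmb,
                     sp$scheme, allowed = allowed))
  expect_silent(auditPolicy(graphs, allowed))
  # clusters are chemically tight, so an eval-mode test query whose only
  # neighbours are test compounds is forced OOD
  expect_true(all(vapply(graphs, function(g) g@ood, logical(1))))
  # a query never appears in its own neighbour list
  gAll <- buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr,
                           targetEmb, sp$scheme)
  expect_false("CPD0001" %in% gAll@neighbourIds)
  # violations are detected (an unrestricted graph has forbidden sources)
  expect_error(auditPolicy(list(gAll), character(0)), "policy violation")
})

test_that("graph datasets round-trip through serialization exactly", {
  graphs <- list(
    buildGraphSingle("CPD0001", "REC001", csn, sp$dti, nodeRepr, targetEmb,
                     sp$scheme),
    buildGraphSingle("CPD0013", "REC002", csn, sp$dti[0, ], nodeRepr,
                     targetEmb, sp$scheme),  # OOD graph
    buildGraphMulti("CPD0007", csn, sp$dti, nodeRepr, sp$receptorIds,
                    sp$scheme, nReceptors = 8))
  path <- withr::local_tempfile()
  writeDataset(graphs, path)
  back <- readDataset(path)
  for (i in seq_along(graphs)) {
    for (slot in c("queryId", "mode", "nodeFeatures", "edgeFeatures",
                   "similarities", "neighbourIds", "targetEmbedding",
                   "label", "ood")) {
      expect_identical(methods::slot(back[[i]], slot),
                       methods::slot(graphs[[i]], slot),
                       info = paste("graph", i, slot))
    }
  }
})
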