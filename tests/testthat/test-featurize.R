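test_that("molecular graphs are hydrogen-suppressed with one edge per bond", {
  g1 <- buildMolGraph("C")
  expect_equal(nrow(adjacency(g1)), 1L)
  expect_equal(sum(adjacency(g1)), 0)

  g2 <- buildMolGraph("CCO")
  expect_equal(length(degrees(g2)), 3L)
  expect_equal(sum(adjacency(g2)) / 2, 2)
  expect_false("H" %in% atomSymbols(g2))

  g3 <- buildMolGraph("c1ccccc1")
  expect_equal(length(degrees(g3)), 6L)
  expect_equal(sum(adjacency(g3)) / 2, 6)
  expect_equal(degrees(g3), rep(2L, 6))

  # disconnected fragments (salt) stay in one graph unless restricted
  gs <- buildMolGraph("CC(=O)[O-].[Na+]")
  expect_equal(length(degrees(gs)), 5L)
  gl <- buildMolGraph("CC(=O)[O-].[Na+]", largestFragment = TRUE)
  expect_equal(length(degrees(gl)), 4L)

  expect_error(buildMolGraph("not_a_molecule"), "parsed")
})

test_that("atom features have the pinned 75-slot layout with clean one-hot blocks", {
  expect_length(atomFeatureLayout(), 75L)
  for (smi in c("CCO", "c1ccncc1", "CC(=O)OC", "C[N+](C)(C)C",
                "FP(F)(F)(F)F")) {
    f <- atomFeatures(smi)
    expect_equal(ncol(f), 75L)
    expect_true(all(rowSums(f[, 1:44, drop = FALSE]) == 1))    # element
    expect_true(all(rowSums(f[, 45:55, drop = FALSE]) == 1))   # degree
    expect_true(all(rowSums(f[, 56:62, drop = FALSE]) == 1))   # impl. val.
    expect_true(all(rowSums(f[, 65:69, drop = FALSE]) == 1))   # hybrid
    expect_true(all(rowSums(f[, 71:75, drop = FALSE]) == 1))   # total H
  }
  f <- atomFeatures("CC")
  expect_identical(f[1, ], f[2, ])
  # unknown elements land in the reserved "other" slot, not an error
  fx <- atomFeatures("[U]")
  expect_equal(unname(fx[1, 44]), 1)
})

test_that("graph featurization is invariant to SMILES atom order", {
  forms <- c("CC(C)CO", "OCC(C)C", "C(O)C(C)C")
  ref <- buildMolGraph(forms[1])
  sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
  for (s in forms[-1]) {
    g <- buildMolGraph(s)
    expect_equal(sort(degrees(g)), sort(degrees(ref)))
    expect_equal(sortRows(nodeFeatures(g)), sortRows(nodeFeatures(ref)),
                 ignore_attr = TRUE)
  }
})

test_that("circular fingerprints count environments with folding", {
  expect_length(circularFingerprint("CCO"), 2048L)
  expect_equal(sum(circularFingerprint("C")), 1)
  fp <- circularFingerprint("CC")
  expect_equal(sum(fp), 4)                 # 2 atoms x radii {0, 1}
  expect_equal(sort(fp[fp > 0]), c(2L, 2L))  # both atoms equivalent
  expect_length(circularFingerprint("CCO", bins = 64L), 64L)
  expect_error(circularFingerprint("not_a_molecule"), "parsed")
})

test_that("fingerprint totals match brute-force environment enumeration", {
  mols <- c("C", "CC", "CCO", "CC(C)C", "c1ccccc1", "C1CC1", "N#CC",
            "CC(=O)OCC", "c1ccncc1", "OCC(O)CO", "CC(C)(C)C",
            "C[N+](C)(C)C")
  for (smi in mols) {
    expect_equal(sum(circularFingerprint(smi)),
                 bruteEnvironmentTotal(smi, radius = 2),
                 info = smi)
  }
  # radius-0-only fingerprints count one environment per heavy atom
  for (smi in c("CCO", "c1ccccc1", "CC(C)C")) {
    g <- buildMolGraph(smi)
    expect_equal(sum(circularFingerprint(smi, radius = 0L)),
                 length(degrees(g)), info = smi)
  }
})

test_that("expert descriptors follow the pinned 200-name registry", {
  reg <- descriptorRegistry()
  expect_length(reg, 200L)
  expect_false(anyDuplicated(reg) > 0)
  # the shipped registry asset matches the in-code registry
  asset <- system.file("extdata", "expert_descriptor_registry_v1.txt",
                       package = "LipidTE")
  expect_identical(readLines(asset), reg)

  d <- expertDescriptors("CCO")
  expect_length(d, 200L)
  expect_identical(names(d), reg)
  expect_true(all(is.finite(d)))
  expect_error(expertDescriptors("CCO", registry = reg[1:50]), "mismatch")
  expect_error(expertDescriptors("CCO", registry = c(reg[-1], "NotADescriptor")),
               "NotADescriptor")
})

test_that("descriptor values are chemically sensible and deterministic", {
  d <- expertDescriptors("C")
  expect_equal(unname(d["MolWt"]), 16.043, tolerance = 1e-6)
  expect_equal(unname(d["HeavyAtomCount"]), 1)
  expect_identical(expertDescriptors("OCC"), expertDescriptors("CCO"))
  expect_identical(expertDescriptors("CCO"), expertDescriptors("CCO"))

  db <- expertDescriptors("c1ccccc1")
  expect_equal(unname(db["NumAromaticAtoms"]), 6)
  expect_equal(unname(db["NumRingBonds"]), 6)
  expect_equal(unname(db["Count_C"]), 6)
  expect_equal(unname(db["MolWt"]), 6 * 12.011 + 6 * 1.008,
               tolerance = 1e-6)
})

test_that("external embeddings import by id and reject malformed files", {
  f <- tempfile(fileext = ".csv")
  set.seed(9)
  tab <- data.frame(id = paste0("L", 5:1),
                    matrix(round(stats::rnorm(40), 4), 5, 8))
  names(tab) <- c("id", paste0("e", 1:8))
  utils::write.table(tab, f, sep = ",", row.names = FALSE, quote = FALSE)
  e <- importExternalEmbeddings(f)
  expect_s4_class(e, "EmbeddingMatrix")
  expect_equal(dim(e), c(5L, 8L))
  expect_match(embeddingMethod(e), "^external:")

  # keyed join reproduces an arbitrary table order
  ids <- paste0("L", c(3, 1, 5, 2, 4))
  V <- LipidTE:::.alignEmbedding(e, ids)
  expect_equal(unname(V[, 1]),
               tab[[2]][match(ids, tab$id)])

  # duplicated ids are an error
  tab$id[2] <- "L5"
  utils::write.table(tab, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(importExternalEmbeddings(f), "duplicate")

  # export/import round trip
  lib <- head(generateLipidLibrary(synthConfig(perFamily = 1, seed = 2)), 3)
  emb <- computeEmbeddings(lib, "cfp")
  f2 <- tempfile(fileext = ".csv")
  exportEmbeddings(emb, f2)
  back <- importExternalEmbeddings(f2)
  expect_equal(recordIds(back), recordIds(emb))
  expect_equal(unname(embeddingValues(back)), unname(embeddingValues(emb)))
})

test_that("embedding matrices enforce their dimension contracts", {
  expect_error(EmbeddingMatrix(matrix(0, 2, 10), ids = c("a", "b"),
                               method = "cfp"), "2048")
  expect_error(EmbeddingMatrix(matrix(0, 2, 10), ids = c("a", "a"),
                               method = "external:x"), "duplicate")
  expect_error(EmbeddingMatrix(matrix(c(1, NA), 1, 2), ids = "a",
                               method = "external:x"), "finite")
  e <- EmbeddingMatrix(matrix(0, 2, 200), ids = c("a", "b"),
                       method = "expert")
  expect_equal(dim(e), c(2L, 200L))
})
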