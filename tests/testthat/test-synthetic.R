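test_that("the generator emits the configured family structure deterministically", {
  cfg <- synthConfig(nFamilies = 7L, perFamily = 20L, seed = 21)
  lib <- generateLipidLibrary(cfg)
  expect_equal(nrow(lib), 140L)
  expect_equal(sort(unique(lib$family)), 0:6)
  expect_equal(unname(table(lib$family)), rep(20L, 7), ignore_attr = TRUE)
  expect_false(anyDuplicated(lib$id) > 0)
  expect_true(all(lib$rlu > 0))
  expect_true(all(lib$multiclass_label %in% 0:3))

  # same config -> identical library
  expect_identical(generateLipidLibrary(cfg), lib)

  # labels are consistent with the scheme
  expect_equal(lib$binary_label, assignBinaryLabel(lib$rlu))
  expect_equal(lib$multiclass_label, assignMulticlassLabel(lib$rlu))
})

test_that("generated SMILES parse and survive canonicalization round trips", {
  lib <- generateLipidLibrary(synthConfig(perFamily = 2, seed = 22))
  for (s in lib$smiles) {
    canon <- canonicalizeSmiles(s)
    expect_identical(canonicalizeSmiles(canon), canon)
    g <- buildMolGraph(s, canonicalize = FALSE)
    expect_gte(length(degrees(g)), 5L)
  }
  # family structure is reflected in composition: ester carbonyl count
  # equals the family's tail count
  nC_dbl_O <- vapply(lib$smiles, function(s) {
    lengths(regmatches(s, gregexpr("C(=O)", s, fixed = TRUE)))
  }, integer(1))
  expect_equal(unname(nC_dbl_O), lib$family + 1L)
})

test_that("zwitterion arms carry the expected charges", {
  lib <- generateLipidLibrary(synthConfig(perFamily = 1, seed = 23))
  d6 <- expertDescriptors(lib$smiles[7], canonicalize = FALSE)
  ft <- synthConfig()$familyTable
  expect_equal(unname(d6["NumPosCharged"]), ft$zwitterions[7])
  expect_equal(unname(d6["NumNegCharged"]), ft$zwitterions[7])
  expect_equal(unname(d6["Count_P"]), ft$zwitterions[7])
})

test_that("k-means on fingerprints separates families under a strong signal", {
  # strong-signal configuration: distinct tail counts per family (the
  # default family table) and a tight tail-length spread, so family
  # identity dominates the fingerprint-count geometry
  cfg <- synthConfig(perFamily = 8L, noiseSd = 0, tailLengths = 9:12,
                     seed = 24)
  lib <- generateLipidLibrary(cfg)
  emb <- computeEmbeddings(lib, "cfp")
  ca <- kmeansCluster(emb, k = 7L, seed = 1)
  nmi <- normalizedMutualInfo(clusterLabels(ca), lib$family)
  expect_gte(nmi, 0.8)
})

test_that("recovered AUC is monotone in the planted effect size", {
  aucs <- vapply(c(0.05, 0.3, 0.55), function(beta) {
    eff <- c(intercept = 2.5, tail = beta, len = 0.05, zwit = 0.3)
    cfg <- synthConfig(perFamily = 8L, effect = eff, noiseSd = 0.6,
                       seed = 25)
    lib <- generateLipidLibrary(cfg)
    emb <- computeEmbeddings(lib, "cfp")
    res <- plantedSignalCheck(lib, list(cfp = emb), seed = 25,
                              config = gbtConfig(depth = 4L,
                                                 learningRate = 0.1,
                                                 iterations = 100L,
                                                 loss = "binary",
                                                 seed = 25))
    res$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("a zero-variance effect collapses to a single class and aborts", {
  cfg <- synthConfig(perFamily = 4L,
                     effect = c(intercept = 2, tail = 0, len = 0,
                                zwit = 0),
                     noiseSd = 0, seed = 26)
  lib <- generateLipidLibrary(cfg)
  expect_equal(length(unique(lib$binary_label)), 1L)
  V <- matrix(stats::rnorm(nrow(lib) * 3), ncol = 3)
  embs <- list(x = EmbeddingMatrix(V, ids = lib$id, method = "external:x"))
  expect_error(plantedSignalCheck(lib, embs), "degenerate")
})
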