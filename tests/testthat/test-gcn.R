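test_that("normalized propagation matches the closed form with self-loops", {
  expect_equal(normalizedPropagation(buildMolGraph("C")),
               matrix(1), ignore_attr = TRUE)
  expect_equal(normalizedPropagation(buildMolGraph("CC")),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  # dense brute-force oracle on random graphs
  for (seed in 1:10) {
    g <- randomMolGraph(8, seed)
    A <- adjacency(g)
    Ah <- A + diag(8)
    Dm <- diag(1 / sqrt(rowSums(Ah)))
    expect_equal(normalizedPropagation(g), Dm %*% Ah %*% Dm,
                 tolerance = 1e-12)
  }
  P <- normalizedPropagation(buildMolGraph("CCOC(=O)CC"))
  expect_true(isSymmetric(P))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("a conv layer reduces to ReLU(x W1) on a single node and respects symmetry", {
  cfg <- gcnConfig(hiddenDim = 8L, seed = 5)
  m <- randomGCNModel(cfg, seed = 5)
  g1 <- buildMolGraph("C")
  out <- gcnLayerForward(nodeFeatures(g1), g1, m@convWeights[[1]])
  expect_equal(out,
               pmax(nodeFeatures(g1) %*% m@convWeights[[1]][[1]], 0),
               ignore_attr = TRUE)
  g2 <- buildMolGraph("CC")
  out2 <- gcnLayerForward(nodeFeatures(g2), g2, m@convWeights[[1]])
  expect_equal(out2[1, ], out2[2, ])
})

test_that("the full forward pass matches a naive message-passing oracle", {
  cfg <- gcnConfig(hiddenDim = 6L, nClasses = 3L)
  for (seed in 1:50) {
    n <- 2L + (seed %% 7L)        # graph sizes 2..8
    g <- randomMolGraph(n, seed)
    m <- randomGCNModel(cfg, seed = 1000 + seed)
    got <- gcnForward(g, m)
    want <- naiveGCNForward(g, m)
    expect_equal(got$embedding, want$embedding, tolerance = 1e-6)
    expect_equal(got$logits, want$logits, tolerance = 1e-6)
  }
})

test_that("pooled embeddings are invariant to node permutation", {
  cfg <- gcnConfig(hiddenDim = 8L)
  m <- randomGCNModel(cfg, seed = 2)
  for (seed in 1:20) {
    g <- randomMolGraph(7, seed)
    perm <- sample(7)
    gp <- new("MolGraph",
              nodeFeatures = nodeFeatures(g)[perm, , drop = FALSE],
              adjacency = adjacency(g)[perm, perm],
              degrees = degrees(g)[perm],
              atomSymbols = atomSymbols(g)[perm],
              smiles = "random")
    expect_equal(gcnForward(g, m)$embedding, gcnForward(gp, m)$embedding,
                 tolerance = 1e-10)
  }
  # all-zero features propagate to the dense bias image
  g0 <- randomMolGraph(5, 99)
  g0@nodeFeatures[] <- 0
  f0 <- gcnForward(g0, m)
  expect_equal(f0$embedding, m@denseB)
  expect_equal(f0$logits, as.numeric(m@denseB %*% m@headW) + m@headB)
})

test_that("cross-entropy loss matches its closed forms", {
  expect_equal(crossEntropyLoss(0, c(0.5, 0.5)), log(2), tolerance = 1e-6)
  expect_equal(crossEntropyLoss(0, c(1, 0)), 0, tolerance = 1e-9)
  expect_equal(crossEntropyLoss(1, c(0.2, 0.8)), -log(0.8),
               tolerance = 1e-6)
  # batch loss is the mean
  p <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(crossEntropyLoss(c(0, 1), p),
               mean(c(log(2), -log(0.8))), tolerance = 1e-9)
  expect_error(crossEntropyLoss(0, c(0.9, 0.4)), "sum to 1")
})

test_that("training is seeded-deterministic and fits a separable toy task", {
  smi0 <- vapply(3:12, function(k) paste(rep("C", k), collapse = ""),
                 character(1))
  smi1 <- paste0("N", smi0)
  graphs <- lapply(c(smi0, smi1), buildMolGraph)
  labs <- rep(0:1, each = 10)
  cfg <- gcnConfig(hiddenDim = 16L, maxEpochs = 300L, patience = 300L,
                   seed = 3, learningRate = 5e-3)
  m1 <- trainGCN(graphs, labs, graphs, labs, cfg)
  m2 <- trainGCN(graphs, labs, graphs, labs, cfg)
  expect_identical(trainHistory(m1), trainHistory(m2))
  h <- trainHistory(m1)
  expect_lte(h$stoppedEpoch, cfg$maxEpochs)
  expect_lte(h$bestEpoch, h$stoppedEpoch)
  expect_lt(min(h$trainLoss), 0.1)
  expect_lt(min(h$valLoss), h$valLoss[1])
  # the toy signal is genuinely separable: a logistic fit on the
  # nitrogen-count feature classifies it perfectly
  nN <- vapply(graphs, function(g) sum(atomSymbols(g) == "N"), numeric(1))
  glmfit <- suppressWarnings(
    stats::glm(labs ~ nN, family = stats::binomial()))
  expect_equal(as.integer(stats::fitted(glmfit) > 0.5), labs)

  expect_error(trainGCN(graphs[1:5], rep(0, 5), graphs[1:5], rep(0, 5),
                        cfg), "single class")
})

test_that("early stopping halts after patience epochs without improvement", {
  graphs <- lapply(rep("CCC", 8), buildMolGraph)
  labs <- rep(0:1, 4)    # conflicting labels on identical graphs
  cfg <- gcnConfig(hiddenDim = 4L, maxEpochs = 2000L, patience = 25L,
                   seed = 8, learningRate = 1e-2)
  m <- trainGCN(graphs, labs, graphs, labs, cfg)
  h <- trainHistory(m)
  expect_lt(h$stoppedEpoch, cfg$maxEpochs)
  expect_equal(h$stoppedEpoch, h$bestEpoch + cfg$patience)
})

test_that("every degree-binned weight matrix is exercised by the test battery", {
  battery <- c("C",                 # isolated node -> bin 1 (clamped)
               "CC",                # degree 1
               "CCC",               # degree 2
               "CC(C)C",            # degree 3
               "CC(C)(C)C",         # degree 4
               "FP(F)(F)(F)F")      # degree 5
  graphs <- lapply(battery, buildMolGraph)
  bins <- sort(unique(unlist(lapply(graphs, function(g)
    LipidTE:::.degreeBins(degrees(g), 5L)))))
  expect_equal(bins, 1:5)
  # degrees above the bin count clamp to the top bin
  expect_equal(LipidTE:::.degreeBins(c(0L, 6L, 9L), 5L), c(1L, 5L, 5L))
})

test_that("embedding extraction is deterministic and duplicates map to equal rows", {
  graphs <- lapply(c("CCO", "CCN", "CCO"), buildMolGraph)
  cfg <- gcnConfig(hiddenDim = 8L, maxEpochs = 30L, patience = 30L,
                   seed = 4)
  m <- trainGCN(graphs[1:2], c(0, 1), graphs[1:2], c(0, 1), cfg)
  e1 <- extractEmbeddings(m, graphs, c("a", "b", "c"))
  e2 <- extractEmbeddings(m, graphs, c("a", "b", "c"))
  expect_identical(embeddingValues(e1), embeddingValues(e2))
  expect_equal(dim(e1), c(3L, 32L))
  expect_equal(embeddingValues(e1)["a", ], embeddingValues(e1)["c", ])
  expect_identical(embeddingMethod(e1), "gcn")
})

test_that("GCN checkpoints round-trip through JSON", {
  graphs <- lapply(c("CCO", "CCN", "CCC", "CCCl"), buildMolGraph)
  cfg <- gcnConfig(hiddenDim = 8L, maxEpochs = 20L, patience = 20L,
                   seed = 6)
  m <- trainGCN(graphs, c(0, 1, 0, 1), graphs, c(0, 1, 0, 1), cfg)
  f <- tempfile(fileext = ".json")
  saveGCNModel(m, f)
  m2 <- loadGCNModel(f)
  for (g in graphs) {
    expect_equal(gcnForward(g, m)$embedding, gcnForward(g, m2)$embedding,
                 tolerance = 1e-12)
  }
  expect_equal(m2@config$embedDim, 32L)
  expect_length(m2@convWeights[[1]], 5L)
})
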