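# Independent oracles and shared fixtures.  Oracles are written as plain
# loops over definitions, deliberately avoiding the package's own code
# paths.

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# noiseless strong-signal synthetic library + its embeddings (shared by
# the synthetic-module and recovery tests)
noiselessLibrary <- function() {
  fixture("lib0", function() generateLipidLibrary(synthConfig(noiseSd = 0)))
}
noiselessCfp <- function() {
  fixture("cfp0", function() computeEmbeddings(noiselessLibrary(), "cfp"))
}
noiselessGraphs <- function() {
  fixture("graphs0", function() {
    lapply(noiselessLibrary()$smiles, buildMolGraph, canonicalize = FALSE)
  })
}

# random MolGraph with arbitrary (non-chemical) node features
randomMolGraph <- function(n, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  if (n > 1) {
    for (i in 2:n) {                     # random tree keeps it connected
      j <- sample.int(i - 1, 1)
      adj[i, j] <- adj[j, i] <- 1
    }
    extra <- which(upper.tri(adj) & adj == 0)
    if (length(extra)) {
      add <- extra[stats::runif(length(extra)) < 0.3]
      adj[add] <- 1
      adj <- pmax(adj, t(adj))
    }
  }
  feats <- matrix(stats::rnorm(n * 75), n, 75)
  new("MolGraph", nodeFeatures = feats, adjacency = adj,
      degrees = as.integer(rowSums(adj)), atomSymbols = rep("C", n),
      smiles = "random")
}

randomGCNModel <- function(cfg, seed) {
  set.seed(seed)
  w <- LipidTE:::.initWeights(cfg)
  new("GCNModel", convWeights = w$conv, denseW = w$denseW,
      denseB = w$denseB, headW = w$headW, headB = w$headB,
      config = unclass(cfg), history = list())
}

# naive per-node message-passing forward pass (loop-based oracle)
naiveGCNForward <- function(graph, model) {
  A <- adjacency(graph)
  n <- nrow(A)
  Ah <- A + diag(n)
  dg <- rowSums(Ah)
  H <- nodeFeatures(graph)
  cfg <- model@config
  for (l in seq_len(cfg$nConvLayers)) {
    W <- model@convWeights[[l]]
    Hn <- matrix(0, n, ncol(W[[1]]))
    for (v in seq_len(n)) {
      msg <- rep(0, ncol(H))
      for (u in seq_len(n)) {
        if (Ah[v, u] > 0) msg <- msg + H[u, ] / sqrt(dg[v] * dg[u])
      }
      b <- min(max(sum(A[v, ]), 1), cfg$nDegreeBins)
      Hn[v, ] <- pmax(as.numeric(msg %*% W[[b]]), 0)
    }
    H <- Hn
  }
  pooled <- rep(0, ncol(H))
  for (v in seq_len(n)) pooled <- pooled + H[v, ]
  emb <- as.numeric(pooled %*% model@denseW) + model@denseB
  list(embedding = emb,
       logits = as.numeric(emb %*% model@headW) + model@headB)
}

# brute-force circular-environment count: one environment per atom and
# realizable radius (igraph shortest paths as the independent distance
# computation)
bruteEnvironmentTotal <- function(smiles, radius = 2) {
  g <- buildMolGraph(smiles)
  d <- igraph::distances(
    igraph::graph_from_adjacency_matrix(adjacency(g), mode = "undirected"))
  total <- 0
  for (i in seq_len(nrow(d))) {
    for (r in 0:radius) {
      if (r == 0 || any(is.finite(d[i, ]) & d[i, ] == r)) total <- total + 1
    }
  }
  total
}

# pair-counting AUC (Mann-Whitney), loop-based
bruteAUC <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# confusion-matrix metric oracle, written as explicit per-class loops
oracleMetricSuite <- function(y, p) {
  classes <- colnames(p)
  pred <- classes[apply(p, 1, which.max)]
  y <- as.character(y)
  M <- length(classes)
  recall <- prec <- f1 <- sup <- numeric(M)
  for (k in seq_len(M)) {
    cl <- classes[k]
    tp <- sum(y == cl & pred == cl)
    fn <- sum(y == cl & pred != cl)
    fp <- sum(y != cl & pred == cl)
    sup[k] <- tp + fn
    recall[k] <- if (sup[k] > 0) tp / (tp + fn) else NA
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[k] <- if (!is.na(recall[k]) && prec[k] + recall[k] > 0)
      2 * prec[k] * recall[k] / (prec[k] + recall[k]) else 0
  }
  ba <- mean(recall[sup > 0])
  wf1 <- sum(f1[sup > 0] * sup[sup > 0]) / sum(sup)
  # generalized MCC
  cm <- matrix(0, M, M)
  for (i in seq_along(y)) {
    cm[match(y[i], classes), match(pred[i], classes)] <-
      cm[match(y[i], classes), match(pred[i], classes)] + 1
  }
  s <- sum(cm); cc <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den == 0) 0 else (cc * s - sum(pk * tk)) / den
  # one-vs-rest AUC by pair counting; NA unless every class has both
  # positives and negatives
  auc <- NA_real_
  if (all(sup > 0) && any(sup < length(y))) {
    per <- numeric(M)
    for (k in seq_len(M)) {
      per[k] <- bruteAUC(p[y == classes[k], k], p[y != classes[k], k])
    }
    auc <- if (M == 2) per[2] else mean(per)
  }
  c(auc = auc, balanced_accuracy = ba, weighted_f1 = wf1, mcc = mcc)
}

# contingency-table NMI oracle (arithmetic-mean normalizer), loop-based
oracleNMI <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  ha <- 0
  for (x in ua) { px <- sum(a == x) / n; ha <- ha - px * log(px) }
  hb <- 0
  for (x in ub) { px <- sum(b == x) / n; hb <- hb - px * log(px) }
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (x in ua) for (yv in ub) {
    pxy <- sum(a == x & b == yv) / n
    if (pxy > 0) {
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == yv) / n)))
    }
  }
  mi / ((ha + hb) / 2)
}

# random probability matrix with rows summing to 1
randomProbs <- function(n, M, seed) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * M), n, M)
  p <- p / rowSums(p)
  colnames(p) <- as.character(seq_len(M) - 1L)
  p
}

writeToyTable <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}
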