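#' Configuration of the graph convolutional embedder
#'
#' Assembles and validates the hyperparameters of the GCN: two
#' degree-binned convolutional layers, a linear dense layer producing the
#' 32-dimensional molecule embedding, a softmax classification head, a
#' dropout rate of 0.3 on the convolutional outputs, and early stopping on
#' validation cross-entropy with a patience of 500 epochs within a budget
#' of 5000.
#'
#' @param nConvLayers number of convolutional layers (default 2).
#' @param hiddenDim width of each convolutional layer (default 64).
#' @param embedDim molecule embedding dimension (default 32).
#' @param nDegreeBins number of degree-binned weight matrices per layer
#'   (default 5); a node of degree d uses matrix \code{min(max(d, 1), 5)}.
#' @param dropout dropout rate on convolutional outputs during training
#'   (default 0.3).
#' @param maxEpochs training budget (default 5000).
#' @param patience early-stopping patience in epochs (default 500).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed integer seed controlling initialization and dropout.
#' @param nClasses number of target classes M (default 2).
#' @return a validated list of class \code{gcnConfig}.
#' @export
gcnConfig <- function(nConvLayers = 2L, hiddenDim = 64L, embedDim = 32L,
                      nDegreeBins = 5L, dropout = 0.3, maxEpochs = 5000L,
                      patience = 500L, learningRate = 1e-3, seed = 1L,
                      nClasses = 2L) {
  cfg <- list(nConvLayers = as.integer(nConvLayers),
              hiddenDim = as.integer(hiddenDim),
              embedDim = as.integer(embedDim),
              nDegreeBins = as.integer(nDegreeBins),
              dropout = dropout, maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience),
              learningRate = learningRate, seed = as.integer(seed),
              nClasses = as.integer(nClasses))
  stopifnot(cfg$nConvLayers >= 1L, cfg$nDegreeBins >= 1L,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$patience <= cfg$maxEpochs, cfg$learningRate > 0,
            cfg$nClasses >= 2L)
  class(cfg) <- "gcnConfig"
  cfg
}

#' Symmetric-normalized propagation matrix
#'
#' Computes the propagation operator of the graph convolution,
#' \eqn{\tilde D^{-1/2} \hat A \tilde D^{-1/2}}, where
#' \eqn{\hat A = A + I} is the adjacency with added self-connections and
#' \eqn{\tilde D} its diagonal degree matrix.  Self-loops guarantee
#' strictly positive degrees, so the operator is always defined; it is
#' symmetric with entries in [0, 1].
#'
#' @param graph a [MolGraph-class].
#' @return an n x n numeric matrix.
#' @examples
#' normalizedPropagation(buildMolGraph("C"))    # 1x1 matrix: 1
#' normalizedPropagation(buildMolGraph("CC"))   # all entries 0.5
#' @export
normalizedPropagation <- function(graph) {
  stopifnot(is(graph, "MolGraph"))
  ahat <- graph@adjacency + diag(nrow(graph@adjacency))
  dinv <- 1 / sqrt(rowSums(ahat))
  dinv * ahat * rep(dinv, each = nrow(ahat))
}

# degree bin of each node: clamp(degree, 1, nBins)
.degreeBins <- function(deg, nBins) pmin(pmax(deg, 1L), nBins)

# A[v, ] <- Z[v, ] %*% W[[bin(v)]], vectorized over bins
.perBinMultiply <- function(Z, weights, bins) {
  out <- matrix(0, nrow(Z), ncol(weights[[1]]))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    out[idx, ] <- Z[idx, , drop = FALSE] %*% weights[[b]]
  }
  out
}

#' One graph-convolution layer
#'
#' Forward pass of a single degree-binned convolutional layer: node
#' features are propagated through [normalizedPropagation()], then each
#' node's row is transformed by the weight matrix of its degree bin
#' (degrees above the number of bins are clamped to the top bin, degree-0
#' nodes use bin 1) and passed through ReLU.  In training mode, inverted
#' dropout is applied to the output rows.
#'
#' @param hPrev numeric matrix n x d_in of node representations.
#' @param graph the [MolGraph-class] the rows belong to.
#' @param weights list of \code{nDegreeBins} weight matrices
#'   (d_in x d_out).
#' @param training logical; apply dropout (draws from the R RNG).
#' @param dropout dropout rate used when \code{training} is TRUE.
#' @return numeric matrix n x d_out.
#' @export
gcnLayerForward <- function(hPrev, graph, weights, training = FALSE,
                            dropout = 0.3) {
  stopifnot(is(graph, "MolGraph"),
            nrow(hPrev) == nrow(graph@adjacency),
            ncol(hPrev) == nrow(weights[[1]]))
  P <- normalizedPropagation(graph)
  bins <- .degreeBins(graph@degrees, length(weights))
  H <- pmax(.perBinMultiply(P %*% hPrev, weights, bins), 0)
  if (training && length(weights) > 0) {
    p <- dropout
    if (p > 0) {
      mask <- matrix(stats::rbinom(length(H), 1L, 1 - p), nrow(H)) / (1 - p)
      H <- H * mask
    }
  }
  H
}

#' Full forward pass of the graph convolutional embedder
#'
#' Runs a molecule graph through the trained convolutional stack,
#' sum-pools the node representations into a single vector, applies the
#' linear dense layer to obtain the molecule embedding, and the
#' linear-softmax head to obtain class logits.  Sum pooling makes the
#' output invariant to node order.
#'
#' @param graph a [MolGraph-class].
#' @param model a [GCNModel-class].
#' @param training logical; apply dropout in the conv layers.
#' @return list with \code{embedding} (length \code{embedDim}) and
#'   \code{logits} (length \code{nClasses}).
#' @export
gcnForward <- function(graph, model, training = FALSE) {
  stopifnot(is(graph, "MolGraph"), is(model, "GCNModel"))
  cfg <- model@config
  H <- graph@nodeFeatures
  for (l in seq_len(cfg$nConvLayers)) {
    H <- gcnLayerForward(H, graph, model@convWeights[[l]],
                         training = training, dropout = cfg$dropout)
  }
  pooled <- colSums(H)
  embedding <- as.numeric(pooled %*% model@denseW) + model@denseB
  logits <- as.numeric(embedding %*% model@headW) + model@headB
  list(embedding = embedding, logits = logits)
}

#' Cross-entropy loss
#'
#' Multiclass cross-entropy between one-hot targets and predicted class
#' probabilities; the batch loss is the mean per-observation loss.
#' Probabilities are clipped to \code{[eps, 1]} before the logarithm.
#'
#' @param yTrue integer class labels in 0..M-1, or a one-hot matrix.
#' @param pPred numeric matrix n x M of probabilities (rows must sum to 1
#'   within \code{tol}); a single observation may be passed as a vector.
#' @param eps clipping floor (default 1e-12).
#' @param tol row-normalization tolerance (default 1e-6).
#' @return nonnegative scalar, the mean cross-entropy.
#' @examples
#' crossEntropyLoss(0, c(0.5, 0.5))   # log(2)
#' @export
crossEntropyLoss <- function(yTrue, pPred, eps = 1e-12, tol = 1e-6) {
  if (is.vector(pPred)) pPred <- matrix(pPred, nrow = 1)
  M <- ncol(pPred)
  if (!is.matrix(yTrue)) {
    y <- matrix(0, length(yTrue), M)
    y[cbind(seq_along(yTrue), as.integer(yTrue) + 1L)] <- 1
  } else y <- yTrue
  stopifnot(nrow(y) == nrow(pPred), ncol(y) == M)
  if (any(abs(rowSums(pPred) - 1) > tol)) {
    stop("predicted probabilities do not sum to 1", call. = FALSE)
  }
  p <- pmin(pmax(pPred, eps), 1)
  mean(-rowSums(y * log(p)))
}

.softmax <- function(L) {
  m <- apply(L, 1, max)
  e <- exp(L - m)
  e / rowSums(e)
}

# Stack a list of MolGraphs into one batch: node feature matrix, sparse
# block-diagonal propagation operator, degree bins and a sparse pooling
# matrix (graphs x nodes).
.batchGraphs <- function(graphs, nBins) {
  X <- do.call(rbind, lapply(graphs, function(g) g@nodeFeatures))
  P <- Matrix::bdiag(lapply(graphs, normalizedPropagation))
  bins <- unlist(lapply(graphs, function(g)
    .degreeBins(g@degrees, nBins)))
  sizes <- vapply(graphs, function(g) nrow(g@adjacency), integer(1))
  gidx <- rep(seq_along(graphs), sizes)
  S <- Matrix::sparseMatrix(i = gidx, j = seq_len(sum(sizes)), x = 1,
                            dims = c(length(graphs), sum(sizes)))
  list(X = X, P = P, bins = bins, S = S)
}

.initWeights <- function(cfg) {
  glorot <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  conv <- vector("list", cfg$nConvLayers)
  din <- 75L
  for (l in seq_len(cfg$nConvLayers)) {
    conv[[l]] <- lapply(seq_len(cfg$nDegreeBins),
                        function(b) glorot(din, cfg$hiddenDim))
    din <- cfg$hiddenDim
  }
  list(conv = conv,
       denseW = glorot(cfg$hiddenDim, cfg$embedDim),
       denseB = numeric(cfg$embedDim),
       headW = glorot(cfg$embedDim, cfg$nClasses),
       headB = numeric(cfg$nClasses))
}

# forward over a prepared batch; returns intermediates for backprop
.batchForward <- function(batch, w, cfg, training = FALSE) {
  nl <- cfg$nConvLayers
  Z <- H <- A <- masks <- vector("list", nl)
  Hprev <- batch$X
  for (l in seq_len(nl)) {
    Z[[l]] <- as.matrix(batch$P %*% Hprev)
    A[[l]] <- .perBinMultiply(Z[[l]], w$conv[[l]], batch$bins)
    H[[l]] <- pmax(A[[l]], 0)
    if (training && cfg$dropout > 0) {
      masks[[l]] <- matrix(stats::rbinom(length(H[[l]]), 1L,
                                         1 - cfg$dropout),
                           nrow(H[[l]])) / (1 - cfg$dropout)
      H[[l]] <- H[[l]] * masks[[l]]
    }
    Hprev <- H[[l]]
  }
  pooled <- as.matrix(batch$S %*% Hprev)
  E <- sweep(pooled %*% w$denseW, 2, w$denseB, "+")
  L <- sweep(E %*% w$headW, 2, w$headB, "+")
  list(Z = Z, A = A, H = H, masks = masks, pooled = pooled, E = E, L = L,
       prob = .softmax(L))
}

.batchBackward <- function(batch, w, cfg, fw, Y) {
  G <- nrow(Y)
  dL <- (fw$prob - Y) / G
  grad <- list(
    headW = t(fw$E) %*% dL, headB = colSums(dL),
    conv = vector("list", cfg$nConvLayers))
  dE <- dL %*% t(w$headW)
  grad$denseW <- t(fw$pooled) %*% dE
  grad$denseB <- colSums(dE)
  dpooled <- dE %*% t(w$denseW)
  dH <- as.matrix(Matrix::t(batch$S) %*% dpooled)
  for (l in rev(seq_len(cfg$nConvLayers))) {
    if (!is.null(fw$masks[[l]])) dH <- dH * fw$masks[[l]]
    dA <- dH * (fw$A[[l]] > 0)
    gW <- vector("list", cfg$nDegreeBins)
    dZ <- matrix(0, nrow(dA), nrow(w$conv[[l]][[1]]))
    for (b in seq_len(cfg$nDegreeBins)) {
      idx <- which(batch$bins == b)
      if (length(idx)) {
        gW[[b]] <- t(fw$Z[[l]][idx, , drop = FALSE]) %*%
          dA[idx, , drop = FALSE]
        dZ[idx, ] <- dA[idx, , drop = FALSE] %*% t(w$conv[[l]][[b]])
      } else {
        gW[[b]] <- matrix(0, nrow(w$conv[[l]][[1]]), ncol(w$conv[[l]][[1]]))
      }
    }
    grad$conv[[l]] <- gW
    if (l > 1L) dH <- as.matrix(batch$P %*% dZ)   # P is symmetric
  }
  grad
}

# flatten/unflatten parameter lists for the Adam update
.flattenParams <- function(w) {
  c(unlist(lapply(w$conv, function(lw) lw), recursive = FALSE),
    list(w$denseW, w$denseB, w$headW, w$headB))
}

.adamStep <- function(w, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  wp <- .flattenParams(w)
  gp <- .flattenParams(list(conv = grad$conv, denseW = grad$denseW,
                            denseB = grad$denseB, headW = grad$headW,
                            headB = grad$headB))
  for (i in seq_along(wp)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gp[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gp[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    wp[[i]] <- wp[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  # unflatten
  k <- 1L
  for (l in seq_along(w$conv)) {
    for (b in seq_along(w$conv[[l]])) { w$conv[[l]][[b]] <- wp[[k]]; k <- k + 1L }
  }
  w$denseW <- wp[[k]]; w$denseB <- wp[[k + 1L]]
  w$headW <- wp[[k + 2L]]; w$headB <- wp[[k + 3L]]
  list(w = w, state = state)
}

#' Train the graph convolutional embedder
#'
#' Full-batch gradient training of the GCN on labeled molecule graphs,
#' minimizing multiclass cross-entropy with Adam.  After every epoch the
#' validation loss is evaluated (dropout off); training stops when it has
#' not improved for \code{patience} epochs or at \code{maxEpochs}, and the
#' weights from the best epoch are restored (ties keep the earliest
#' epoch).  Fully reproducible given \code{config$seed}.
#'
#' @param trainGraphs,valGraphs lists of [MolGraph-class] objects.
#' @param trainLabels,valLabels integer class labels in 0..M-1.
#' @param config a [gcnConfig()].
#' @return a trained [GCNModel-class]; its training history (per-epoch
#'   train/validation loss, best and stopped epoch) is available through
#'   [trainHistory()].
#' @export
trainGCN <- function(trainGraphs, trainLabels, valGraphs, valLabels,
                     config = gcnConfig()) {
  stopifnot(length(trainGraphs) == length(trainLabels),
            length(valGraphs) == length(valLabels),
            length(trainGraphs) > 0, length(valGraphs) > 0)
  y <- as.integer(trainLabels)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: training set contains a single class",
         call. = FALSE)
  }
  if (any(y < 0) || any(y >= config$nClasses) ||
      any(valLabels < 0) || any(valLabels >= config$nClasses)) {
    stop("labels must lie in 0..nClasses-1", call. = FALSE)
  }

  set.seed(config$seed)
  w <- .initWeights(config)
  tb <- .batchGraphs(trainGraphs, config$nDegreeBins)
  vb <- .batchGraphs(valGraphs, config$nDegreeBins)
  onehot <- function(lab) {
    Y <- matrix(0, length(lab), config$nClasses)
    Y[cbind(seq_along(lab), as.integer(lab) + 1L)] <- 1
    Y
  }
  Ytr <- onehot(y); Yval <- onehot(as.integer(valLabels))

  wp <- .flattenParams(w)
  state <- list(t = 0,
                m = lapply(wp, function(x) x * 0),
                v = lapply(wp, function(x) x * 0))
  best <- list(loss = Inf, epoch = 0L, w = w)
  trainLoss <- valLoss <- numeric(0)

  for (epoch in seq_len(config$maxEpochs)) {
    fw <- .batchForward(tb, w, config, training = TRUE)
    trainLoss[epoch] <- crossEntropyLoss(Ytr, fw$prob)
    grad <- .batchBackward(tb, w, config, fw, Ytr)
    upd <- .adamStep(w, grad, state, config$learningRate)
    w <- upd$w; state <- upd$state

    vfw <- .batchForward(vb, w, config, training = FALSE)
    valLoss[epoch] <- crossEntropyLoss(Yval, vfw$prob)
    if (valLoss[epoch] < best$loss) {
      best <- list(loss = valLoss[epoch], epoch = epoch, w = w)
    }
    if (epoch - best$epoch >= config$patience) break
  }

  hist <- list(trainLoss = trainLoss, valLoss = valLoss,
               bestEpoch = best$epoch, stoppedEpoch = length(valLoss))
  new("GCNModel", convWeights = best$w$conv, denseW = best$w$denseW,
      denseB = best$w$denseB, headW = best$w$headW, headB = best$w$headB,
      config = unclass(config), history = hist)
}

#' Extract molecule embeddings from a trained GCN
#'
#' Runs each graph through the trained model in evaluation mode (no
#' dropout) and collects the 32-dimensional embeddings; the softmax head
#' is ignored.  Repeated calls are identical.
#'
#' @param model a trained [GCNModel-class].
#' @param graphs list of [MolGraph-class] objects.
#' @param ids record identifiers, one per graph.
#' @return an [EmbeddingMatrix-class] with method tag \code{"gcn"}.
#' @export
extractEmbeddings <- function(model, graphs, ids) {
  stopifnot(is(model, "GCNModel"), length(graphs) == length(ids))
  batch <- .batchGraphs(graphs, model@config$nDegreeBins)
  w <- list(conv = model@convWeights, denseW = model@denseW,
            denseB = model@denseB, headW = model@headW,
            headB = model@headB)
  fw <- .batchForward(batch, w, model@config, training = FALSE)
  EmbeddingMatrix(fw$E, ids = as.character(ids), method = "gcn")
}
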