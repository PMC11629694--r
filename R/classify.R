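#' Gradient-boosted classifier configuration
#'
#' Hyperparameters of the gradient-boosted decision-tree head.  The
#' multiclass default is pinned to depth 5, learning rate 0.005 and 5000
#' boosting iterations; the binary task is typically tuned with
#' [gridSearch()] instead.  The backend (xgboost) is abstracted behind
#' [trainClassifier()] / [predictProba()], so any gradient-boosting
#' library satisfying that contract could serve.
#'
#' @param depth tree depth.
#' @param learningRate shrinkage per iteration.
#' @param iterations number of boosting rounds.
#' @param loss \code{"multiclass"} or \code{"binary"}.
#' @param seed integer seed.
#' @return a list of class \code{gbtConfig}.
#' @export
gbtConfig <- function(depth = 5L, learningRate = 0.005, iterations = 5000L,
                      loss = c("multiclass", "binary"), seed = 1L) {
  loss <- match.arg(loss)
  cfg <- list(depth = as.integer(depth), learningRate = learningRate,
              iterations = as.integer(iterations), loss = loss,
              seed = as.integer(seed))
  stopifnot(cfg$depth >= 1L, cfg$learningRate > 0, cfg$iterations >= 1L)
  class(cfg) <- "gbtConfig"
  cfg
}

#' Train a gradient-boosted classification head
#'
#' Fits the boosted-tree classifier on an embedding matrix.  Following the
#' single-representation input convention, features must come from exactly
#' one embedding source per experiment -- the ionizable lipid embedding
#' alone, never concatenated with formulation features.  Deterministic
#' given \code{config$seed} (single-threaded backend).
#'
#' @param X an [EmbeddingMatrix-class] or numeric matrix (rows aligned
#'   with \code{y}).
#' @param y class labels (integers 0..M-1, or any factor-coercible
#'   vector).
#' @param config a [gbtConfig()].
#' @return a \code{ClassifierModel} list: backend handle, config, class
#'   levels and feature dimension.
#' @export
trainClassifier <- function(X, y, config = gbtConfig()) {
  Xm <- if (is(X, "EmbeddingMatrix")) X@values else as.matrix(X)
  stopifnot(nrow(Xm) == length(y))
  yf <- factor(y)
  if (nlevels(yf) < 2L) {
    stop("degenerate labels: a single class cannot be fit", call. = FALSE)
  }
  small <- table(yf) < 2L
  if (any(small)) {
    warning("class(es) with fewer than 2 members: ",
            paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  M <- nlevels(yf)
  yi <- as.integer(yf) - 1L
  binary <- config$loss == "binary" && M == 2L
  params <- list(
    max_depth = config$depth,
    eta = config$learningRate,
    nthread = 1L,
    seed = config$seed,
    objective = if (binary) "binary:logistic" else "multi:softprob")
  if (!binary) params$num_class <- M
  dtrain <- xgboost::xgb.DMatrix(Xm, label = yi)
  booster <- xgboost::xgb.train(params, dtrain,
                                nrounds = config$iterations, verbose = 0)
  structure(list(booster = booster, config = config,
                 classes = levels(yf), featureDim = ncol(Xm),
                 binary = binary),
            class = "ClassifierModel")
}

#' Predict class probabilities
#'
#' @param model a \code{ClassifierModel} from [trainClassifier()].
#' @param X an [EmbeddingMatrix-class] or numeric matrix with the model's
#'   feature dimension.
#' @return numeric matrix n x M of probabilities; rows sum to 1, columns
#'   ordered and named by the model's class levels.
#' @export
predictProba <- function(model, X) {
  stopifnot(inherits(model, "ClassifierModel"))
  Xm <- if (is(X, "EmbeddingMatrix")) X@values else as.matrix(X)
  if (ncol(Xm) != model$featureDim) {
    stop("feature dimension mismatch: model expects ", model$featureDim,
         ", got ", ncol(Xm), call. = FALSE)
  }
  p <- predict(model$booster, xgboost::xgb.DMatrix(Xm))
  M <- length(model$classes)
  out <- if (model$binary) cbind(1 - p, p)
         else if (is.matrix(p)) unname(p)
         else matrix(p, ncol = M, byrow = TRUE)
  colnames(out) <- model$classes
  rownames(out) <- rownames(Xm)
  out
}

#' Grid search for the binary classifier
#'
#' Trains one model per grid point on the training split, scores each on
#' the validation split, and returns the best configuration.  The default
#' selection metric is AUC for binary tasks (balanced accuracy
#' otherwise); ties are broken by fewer iterations, then smaller depth,
#' then smaller learning rate.
#'
#' @param trainX,trainY training split (features aligned with labels).
#' @param valX,valY validation split.
#' @param grid data.frame with columns depth, learningRate, iterations
#'   (default: depth {4,5,6} x learning rate {0.005, 0.01, 0.05} x
#'   iterations {1000, 5000}).
#' @param loss passed to [gbtConfig()].
#' @param metric \code{"auc"} (default) or \code{"balanced_accuracy"}.
#' @param seed seed shared by all grid points.
#' @return the winning [gbtConfig()], with the achieved validation score
#'   in attribute \code{"score"}.
#' @export
gridSearch <- function(trainX, trainY, valX, valY,
                       grid = expand.grid(depth = c(4L, 5L, 6L),
                                          learningRate = c(0.005, 0.01, 0.05),
                                          iterations = c(1000L, 5000L)),
                       loss = "binary",
                       metric = c("auc", "balanced_accuracy"),
                       seed = 1L) {
  metric <- match.arg(metric)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- gbtConfig(depth = grid$depth[i],
                     learningRate = grid$learningRate[i],
                     iterations = grid$iterations[i], loss = loss,
                     seed = seed)
    fit <- trainClassifier(trainX, trainY, cfg)
    ms <- metricSuite(valY, predictProba(fit, valX))
    scores[i] <- if (metric == "auc") ms[["auc"]]
                 else ms[["balanced_accuracy"]]
  }
  ord <- order(-scores, grid$iterations, grid$depth, grid$learningRate)
  best <- ord[1]
  out <- gbtConfig(depth = grid$depth[best],
                   learningRate = grid$learningRate[best],
                   iterations = grid$iterations[best], loss = loss,
                   seed = seed)
  attr(out, "score") <- scores[best]
  out
}
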