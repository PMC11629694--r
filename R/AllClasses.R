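#' @import methods
NULL

#' Label scheme for transfection-efficiency classes
#'
#' Holds the RLU (relative light unit) thresholds that discretize the
#' luciferase readout into transfection-efficiency (TE) classes: a single
#' binary cut separating unsatisfying (RLU below the cut) from satisfying
#' (RLU at or above the cut) TE, and three ordered cuts defining four
#' activity classes.  The boundary convention is "at or above the cut"
#' for the higher class at every threshold.
#'
#' @slot binaryCut numeric(1), RLU threshold for the binary label
#'   (default 10000).
#' @slot multiclassCuts numeric(3), strictly increasing RLU thresholds
#'   defining classes 0..3.
#'
#' @examples
#' sc <- LabelScheme()
#' binaryCut(sc)
#' @export
setClass("LabelScheme",
  representation(binaryCut = "numeric", multiclassCuts = "numeric"),
  prototype(binaryCut = 10000, multiclassCuts = c(100, 1000, 10000)))

setValidity("LabelScheme", function(object) {
  msg <- character(0)
  if (length(object@binaryCut) != 1L || !is.finite(object@binaryCut))
    msg <- c(msg, "binaryCut must be a single finite number")
  if (length(object@multiclassCuts) != 3L)
    msg <- c(msg, "multiclassCuts must have exactly 3 thresholds")
  else if (any(diff(object@multiclassCuts) <= 0))
    msg <- c(msg, "multiclassCuts must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabelScheme-class Constructor.
#' @param binaryCut RLU threshold for the binary satisfying/unsatisfying cut.
#' @param multiclassCuts three increasing RLU thresholds for the 4-class
#'   labels.  The defaults place the cuts at RLU decades (100, 1000, 10000)
#'   so that the top multiclass cut coincides with the binary cut; override
#'   them to match any externally defined binning.
#' @export
LabelScheme <- function(binaryCut = 10000,
                        multiclassCuts = c(100, 1000, 10000)) {
  new("LabelScheme", binaryCut = binaryCut,
      multiclassCuts = as.numeric(multiclassCuts))
}

#' Hydrogen-suppressed molecular graph
#'
#' One molecule as an undirected graph over heavy atoms: nodes are
#' non-hydrogen atoms, edges are covalent bonds, and each node carries a
#' fixed-layout 75-dimensional feature vector (see [atomFeatures()]).
#' Disconnected fragments (e.g. counter-ions in salts) are retained as
#' separate components of the same graph.
#'
#' @slot nodeFeatures numeric matrix, n x 75.
#' @slot adjacency symmetric 0/1 matrix with zero diagonal, n x n.
#' @slot degrees integer vector of heavy-atom degrees (row sums of the
#'   adjacency).
#' @slot atomSymbols character vector of element symbols.
#' @slot smiles the canonical SMILES the graph was built from.
#'
#' @seealso [buildMolGraph()]
#' @export
setClass("MolGraph",
  representation(nodeFeatures = "matrix", adjacency = "matrix",
                 degrees = "integer", atomSymbols = "character",
                 smiles = "character"))

setValidity("MolGraph", function(object) {
  n <- nrow(object@adjacency)
  msg <- character(0)
  if (n < 1L) msg <- c(msg, "graph must have at least one node")
  if (ncol(object@adjacency) != n)
    msg <- c(msg, "adjacency must be square")
  else {
    if (!isTRUE(all.equal(object@adjacency, t(object@adjacency))))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(object@adjacency) != 0))
      msg <- c(msg, "adjacency must have a zero diagonal")
    if (!identical(as.integer(rowSums(object@adjacency)), object@degrees))
      msg <- c(msg, "degrees must equal adjacency row sums")
  }
  if (nrow(object@nodeFeatures) != n || ncol(object@nodeFeatures) != 75L)
    msg <- c(msg, "nodeFeatures must be n x 75")
  if (length(object@atomSymbols) != n)
    msg <- c(msg, "atomSymbols length must match node count")
  if (length(msg)) msg else TRUE
})

#' Molecule embedding matrix
#'
#' A numeric n x d matrix of per-molecule embeddings with row identifiers
#' and a tag naming the representation that produced it.  Dimension
#' contracts per method: \code{expert} 200, \code{cfp} 2048, \code{gcn} 32;
#' \code{external:<name>} matrices may have any width.
#'
#' @slot ids character record identifiers, no duplicates.
#' @slot values numeric matrix (n x d), all entries finite.
#' @slot method representation tag.
#'
#' @seealso [computeEmbeddings()], [importExternalEmbeddings()]
#' @export
setClass("EmbeddingMatrix",
  representation(ids = "character", values = "matrix", method = "character"))

.METHOD_DIMS <- c(expert = 200L, cfp = 2048L, gcn = 32L)

setValidity("EmbeddingMatrix", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate record ids")
  if (length(object@ids) != nrow(object@values))
    msg <- c(msg, "ids length must match row count")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  m <- object@method
  if (m %in% names(.METHOD_DIMS) && ncol(object@values) != .METHOD_DIMS[[m]])
    msg <- c(msg, sprintf("method '%s' requires dimension %d, got %d",
                          m, .METHOD_DIMS[[m]], ncol(object@values)))
  if (!(m %in% names(.METHOD_DIMS)) && !startsWith(m, "external:"))
    msg <- c(msg, "method must be expert, cfp, gcn or external:<name>")
  if (length(msg)) msg else TRUE
})

#' @describeIn EmbeddingMatrix-class Constructor.
#' @param values numeric matrix, one row per record.
#' @param ids record identifiers (defaults to rownames of \code{values}).
#' @param method representation tag.
#' @export
EmbeddingMatrix <- function(values, ids = rownames(values), method) {
  if (is.null(ids)) stop("ids are required (or set rownames on values)")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  new("EmbeddingMatrix", ids = as.character(ids), values = values,
      method = method)
}

#' Trained graph-convolutional embedder
#'
#' Weights of the graph convolutional network: per conv layer a list of
#' degree-binned weight matrices (one per possible neighbor count, nodes
#' select the matrix matching their degree), a linear dense layer mapping
#' the sum-pooled node representation to the molecule embedding, and a
#' linear-softmax classification head used only during training.
#'
#' @slot convWeights list over layers; each element a list of
#'   \code{nDegreeBins} weight matrices.
#' @slot denseW,denseB dense embedding layer (hidden -> embedDim).
#' @slot headW,headB softmax head (embedDim -> nClasses logits).
#' @slot config the [gcnConfig()] list used for training.
#' @slot history training history (list with trainLoss, valLoss,
#'   bestEpoch, stoppedEpoch), empty before training.
#'
#' @seealso [trainGCN()], [gcnForward()], [extractEmbeddings()]
#' @export
setClass("GCNModel",
  representation(convWeights = "list", denseW = "matrix", denseB = "numeric",
                 headW = "matrix", headB = "numeric", config = "list",
                 history = "list"))

setValidity("GCNModel", function(object) {
  cfg <- object@config
  msg <- character(0)
  if (length(object@convWeights) != cfg$nConvLayers)
    msg <- c(msg, "one weight list per conv layer required")
  for (l in seq_along(object@convWeights)) {
    if (length(object@convWeights[[l]]) != cfg$nDegreeBins)
      msg <- c(msg, sprintf("layer %d must have %d degree-binned matrices",
                            l, cfg$nDegreeBins))
  }
  if (nrow(object@denseW) != ncol(object@convWeights[[cfg$nConvLayers]][[1]]))
    msg <- c(msg, "dense layer input width must match last conv output")
  if (ncol(object@denseW) != cfg$embedDim)
    msg <- c(msg, "dense layer must map to embedDim")
  if (nrow(object@headW) != cfg$embedDim || ncol(object@headW) != cfg$nClasses)
    msg <- c(msg, "head must map embedDim to nClasses")
  if (length(msg)) msg else TRUE
})

#' Evaluation report
#'
#' Per-fold and aggregate classification metrics for one or more embedding
#' methods under a common resampling protocol, plus paired one-sided
#' t-test comparisons across folds.
#'
#' @slot perFold data.frame with columns method, fold, auc,
#'   balanced_accuracy, weighted_f1, mcc (NA marks a metric undefined on
#'   that fold, e.g. AUC on a single-class family).
#' @slot aggregate data.frame of per-method means, computed only over folds
#'   where the metric is defined.
#' @slot comparisons data.frame with columns method_a, method_b, metric,
#'   p_value (alternative: method_a better than method_b).
#' @slot protocol character tag ("cv" or "family_holdout").
#' @slot seed integer seed the report was produced under.
#' @export
setClass("EvalReport",
  representation(perFold = "data.frame", aggregate = "data.frame",
                 comparisons = "data.frame", protocol = "character",
                 seed = "integer"))

#' K-means cluster assignment of an embedding space
#'
#' @slot ids record identifiers.
#' @slot labels integer cluster labels (1..k).
#' @slot k number of clusters requested.
#' @slot inertia total within-cluster sum of squares.
#' @slot seed integer seed used.
#' @seealso [kmeansCluster()]
#' @export
setClass("ClusterAssignment",
  representation(ids = "character", labels = "integer", k = "integer",
                 inertia = "numeric", seed = "integer"))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (length(object@ids) != length(object@labels))
    msg <- c(msg, "ids and labels must have equal length")
  if (length(unique(object@labels)) > object@k)
    msg <- c(msg, "more distinct labels than k")
  if (object@inertia < 0) msg <- c(msg, "inertia must be nonnegative")
  if (length(msg)) msg else TRUE
})
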