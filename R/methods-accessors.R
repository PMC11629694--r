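#' @rdname LabelScheme-class
setMethod("binaryCut", "LabelScheme", function(object) object@binaryCut)

#' @rdname LabelScheme-class
setMethod("multiclassCuts", "LabelScheme",
          function(object) object@multiclassCuts)

#' @rdname EmbeddingMatrix-class
setMethod("recordIds", "EmbeddingMatrix", function(object) object@ids)

#' @rdname EmbeddingMatrix-class
setMethod("embeddingValues", "EmbeddingMatrix", function(object) object@values)

#' @rdname EmbeddingMatrix-class
setMethod("embeddingMethod", "EmbeddingMatrix", function(object) object@method)

#' @rdname EmbeddingMatrix-class
#' @param x an \code{EmbeddingMatrix}
setMethod("dim", "EmbeddingMatrix", function(x) dim(x@values))

#' @rdname MolGraph-class
setMethod("nodeFeatures", "MolGraph", function(object) object@nodeFeatures)

#' @rdname MolGraph-class
setMethod("adjacency", "MolGraph", function(object) object@adjacency)

#' @rdname MolGraph-class
setMethod("degrees", "MolGraph", function(object) object@degrees)

#' @rdname MolGraph-class
setMethod("atomSymbols", "MolGraph", function(object) object@atomSymbols)

#' @rdname EvalReport-class
setMethod("perFoldMetrics", "EvalReport", function(object) object@perFold)

#' @rdname EvalReport-class
setMethod("aggregateMetrics", "EvalReport", function(object) object@aggregate)

#' @rdname EvalReport-class
setMethod("methodComparisons", "EvalReport",
          function(object) object@comparisons)

#' @rdname ClusterAssignment-class
setMethod("clusterLabels", "ClusterAssignment",
          function(object) object@labels)

#' @rdname ClusterAssignment-class
setMethod("recordIds", "ClusterAssignment", function(object) object@ids)

#' @rdname GCNModel-class
setMethod("trainHistory", "GCNModel", function(object) object@history)

setMethod("show", "LabelScheme", function(object) {
  cat("LabelScheme: binary cut at RLU", format(object@binaryCut),
      "| multiclass cuts:", paste(format(object@multiclassCuts),
                                  collapse = ", "), "\n")
})

setMethod("show", "MolGraph", function(object) {
  cat("MolGraph:", nrow(object@adjacency), "heavy atoms,",
      sum(object@adjacency) / 2, "bonds |",
      object@smiles, "\n")
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix [", object@method, "]: ",
      nrow(object@values), " records x ", ncol(object@values),
      " dimensions\n", sep = "")
})

setMethod("show", "GCNModel", function(object) {
  cfg <- object@config
  cat("GCNModel:", cfg$nConvLayers, "conv layers x", cfg$nDegreeBins,
      "degree bins ->", cfg$embedDim, "dim embedding ->", cfg$nClasses,
      "classes\n")
  if (length(object@history)) {
    cat("  trained:", object@history$stoppedEpoch, "epochs, best epoch",
        object@history$bestEpoch, "(val loss",
        format(min(object@history$valLoss), digits = 4), ")\n")
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport [", object@protocol, "]: ",
      length(unique(object@perFold$method)), " method(s), ",
      length(unique(object@perFold$fold)), " fold(s)\n", sep = "")
  print(object@aggregate, row.names = FALSE)
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: k =", object@k, "on", length(object@ids),
      "records, inertia", format(object@inertia, digits = 6), "\n")
})
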