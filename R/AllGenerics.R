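#' @rdname LabelScheme-class
#' @param object a \code{LabelScheme}
#' @export
setGeneric("binaryCut", function(object) standardGeneric("binaryCut"))

#' @rdname LabelScheme-class
#' @export
setGeneric("multiclassCuts",
           function(object) standardGeneric("multiclassCuts"))

#' @rdname EmbeddingMatrix-class
#' @param object an object with record identifiers
#' @export
setGeneric("recordIds", function(object) standardGeneric("recordIds"))

#' @rdname EmbeddingMatrix-class
#' @export
setGeneric("embeddingValues",
           function(object) standardGeneric("embeddingValues"))

#' @rdname EmbeddingMatrix-class
#' @export
setGeneric("embeddingMethod",
           function(object) standardGeneric("embeddingMethod"))

#' @rdname MolGraph-class
#' @param object a \code{MolGraph}
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))

#' @rdname MolGraph-class
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname MolGraph-class
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))

#' @rdname MolGraph-class
#' @export
setGeneric("atomSymbols", function(object) standardGeneric("atomSymbols"))

#' @rdname EvalReport-class
#' @param object an \code{EvalReport}
#' @export
setGeneric("perFoldMetrics", function(object) standardGeneric("perFoldMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("aggregateMetrics",
           function(object) standardGeneric("aggregateMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("methodComparisons",
           function(object) standardGeneric("methodComparisons"))

#' @rdname ClusterAssignment-class
#' @param object a \code{ClusterAssignment}
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname GCNModel-class
#' @param object a \code{GCNModel}
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))
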