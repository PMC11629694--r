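#' K-means clustering of an embedding space
#'
#' Clusters the rows of an embedding matrix with k-means (Lloyd's
#' algorithm via \code{stats::kmeans}), taking the best of \code{nInit}
#' seeded restarts by total within-cluster sum of squares.  Deterministic
#' given \code{seed}.  A sensible default for k is the number of lipid
#' families in the data, the comparison target of the normalized mutual
#' information analysis.
#'
#' @param X an [EmbeddingMatrix-class] or numeric matrix.
#' @param k number of clusters, \code{1 <= k <= n}.
#' @param seed integer seed.
#' @param nInit number of random restarts (default 10).
#' @return a [ClusterAssignment-class].
#' @export
kmeansCluster <- function(X, k, seed = 1L, nInit = 10L) {
  Xm <- if (is(X, "EmbeddingMatrix")) X@values else as.matrix(X)
  ids <- if (is(X, "EmbeddingMatrix")) X@ids
         else if (!is.null(rownames(Xm))) rownames(Xm)
         else as.character(seq_len(nrow(Xm)))
  n <- nrow(Xm)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of records", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k == n) {
    return(new("ClusterAssignment", ids = ids, labels = seq_len(n),
               k = k, inertia = 0, seed = as.integer(seed)))
  }
  set.seed(seed)
  fit <- stats::kmeans(Xm, centers = k, nstart = nInit, iter.max = 100L)
  new("ClusterAssignment", ids = ids, labels = as.integer(fit$cluster),
      k = k, inertia = fit$tot.withinss, seed = as.integer(seed))
}

#' Normalized mutual information between two partitions
#'
#' NMI(a, b) = I(a; b) / normalizer(H(a), H(b)) computed from the
#' contingency table of the two labelings (natural logarithms).  Equal
#' partitions (up to relabeling) score 1; if either partition has zero
#' entropy (a single cluster), the score is 0 by convention.  The default
#' normalizer is the arithmetic mean of the entropies; the geometric mean
#' is available as an alternative.
#'
#' @param a,b label vectors of equal length (any atomic type; compared by
#'   value, so relabeling does not change the score).
#' @param normalizer \code{"arithmetic"} (default) or \code{"geometric"}.
#' @return NMI in [0, 1].
#' @examples
#' normalizedMutualInfo(c(0, 0, 1, 1), c(5, 5, 9, 9))   # 1
#' normalizedMutualInfo(c(0, 0, 1, 1), c(0, 1, 0, 1))   # 0
#' @export
normalizedMutualInfo <- function(a, b,
                                 normalizer = c("arithmetic", "geometric")) {
  normalizer <- match.arg(normalizer)
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  ct <- table(a, b)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  norm <- if (normalizer == "arithmetic") (ha + hb) / 2 else sqrt(ha * hb)
  max(0, min(1, mi / norm))
}

#' Two-dimensional projection of an embedding space
#'
#' Projects embeddings to 2-D for visualization.  The built-in method is
#' PCA (deterministic; component signs are fixed by forcing the largest
#' loading of each component positive).  Any external projector -- e.g. a
#' UMAP implementation -- can be plugged in as a function
#' \code{function(X, seed)} returning an n x 2 matrix.
#'
#' @param X an [EmbeddingMatrix-class] or numeric matrix with at least 2
#'   columns and 3 rows.
#' @param method \code{"pca"} or \code{"external"}.
#' @param projector the external projector function (required when
#'   \code{method = "external"}).
#' @param seed integer seed (forwarded to the external projector; PCA is
#'   deterministic).
#' @return numeric matrix n x 2 with the embedding ids as rownames.
#' @export
project2D <- function(X, method = c("pca", "external"), projector = NULL,
                      seed = 1L) {
  method <- match.arg(method)
  Xm <- if (is(X, "EmbeddingMatrix")) X@values else as.matrix(X)
  ids <- if (is(X, "EmbeddingMatrix")) X@ids else rownames(Xm)
  if (nrow(Xm) < 3L) stop("need at least 3 records", call. = FALSE)
  if (ncol(Xm) < 2L) stop("need at least 2 dimensions", call. = FALSE)
  out <- if (method == "pca") {
    pc <- stats::prcomp(Xm, center = TRUE, scale. = FALSE, rank. = 2L)
    rot <- pc$rotation
    flip <- vapply(seq_len(ncol(rot)), function(j) {
      s <- sign(rot[which.max(abs(rot[, j])), j]); if (s == 0) 1 else s
    }, numeric(1))
    sc <- pc$x[, 1:2, drop = FALSE]
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)   # rank-1 data
    sweep(sc, 2, flip[seq_len(ncol(sc))], "*")
  } else {
    if (is.null(projector)) {
      stop("method 'external' requires a projector function", call. = FALSE)
    }
    p <- projector(Xm, seed)
    stopifnot(is.matrix(p), nrow(p) == nrow(Xm), ncol(p) == 2L)
    p
  }
  rownames(out) <- ids
  colnames(out) <- c("x", "y")
  out
}

#' Embedding-space structure summary
#'
#' Convenience wrapper of the clustering analysis: k-means on each
#' embedding method (k defaulting to the number of lipid families), then
#' normalized mutual information of the clusters against the family
#' labels and against the TE class labels.
#'
#' @param records lipid table with \code{family} and label columns.
#' @param embeddings named list of [EmbeddingMatrix-class] objects.
#' @param k number of clusters; defaults to the number of families.
#' @param seed integer seed.
#' @param nInit k-means restarts.
#' @return data.frame with one row per embedding method: k, NMI versus
#'   family, NMI versus multiclass TE label.
#' @export
clusterStructureSummary <- function(records, embeddings, k = NULL,
                                    seed = 1L, nInit = 10L) {
  stopifnot(is.data.frame(records), "family" %in% names(records))
  if (is.null(k)) k <- length(unique(records$family))
  rows <- lapply(names(embeddings), function(nm) {
    V <- .alignEmbedding(embeddings[[nm]], records$id)
    ca <- kmeansCluster(V, k = k, seed = seed, nInit = nInit)
    data.frame(method = nm, k = k,
               nmi_family = normalizedMutualInfo(ca@labels,
                                                 records$family),
               nmi_te = if (all(is.na(records$multiclass_label))) NA_real_
                        else normalizedMutualInfo(ca@labels,
                                                  records$multiclass_label),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
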