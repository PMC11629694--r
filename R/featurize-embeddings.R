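#' Compute an embedding matrix for a lipid table
#'
#' Applies one of the built-in representations to every record of a lipid
#' table: \code{"expert"} (the pinned 200-descriptor vector),
#' \code{"cfp"} (count-based circular fingerprint, 2048 bins) or
#' \code{"gcn"} (requires a trained [GCNModel-class], see
#' [extractEmbeddings()], which this wraps).
#'
#' @param records data.frame with columns \code{id} and \code{smiles}
#'   (as returned by [readLnpTable()] / [generateLipidLibrary()]).
#' @param method one of \code{"expert"}, \code{"cfp"}, \code{"gcn"}.
#' @param model a trained [GCNModel-class]; required for
#'   \code{method = "gcn"}.
#' @param ... passed to the underlying featurizer
#'   (e.g. \code{radius}, \code{bins} for \code{"cfp"}).
#' @return an [EmbeddingMatrix-class].
#' @export
computeEmbeddings <- function(records, method = c("expert", "cfp", "gcn"),
                              model = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  if (method == "gcn") {
    if (is.null(model)) stop("method 'gcn' requires a trained GCNModel")
    graphs <- lapply(records$smiles, buildMolGraph, canonicalize = FALSE)
    return(extractEmbeddings(model, graphs, records$id))
  }
  fn <- switch(method,
               expert = function(s)
                 expertDescriptors(s, canonicalize = FALSE, ...),
               cfp = function(s)
                 as.numeric(circularFingerprint(s, canonicalize = FALSE,
                                                ...)))
  rows <- lapply(records$smiles, fn)
  values <- do.call(rbind, rows)
  EmbeddingMatrix(values, ids = records$id, method = method)
}

#' Import externally precomputed embeddings
#'
#' Reads a delimited numeric file with a header \code{id,e1..ed} (such as
#' embeddings exported from a pretrained graph transformer or a
#' SMILES language model) into an [EmbeddingMatrix-class] tagged
#' \code{external:<basename>}.  Row order is preserved; join by id against
#' a lipid table to align.
#'
#' @param path delimited text file; first column is the record id, the
#'   remaining columns are numeric embedding dimensions.
#' @param sep field separator (default comma).
#' @return an [EmbeddingMatrix-class].
#' @export
importExternalEmbeddings <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("embedding file needs an id column plus at ",
                           "least one numeric column", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in embedding file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values) || any(is.na(values))) {
    stop("embedding file has non-numeric or missing values (ragged rows?)",
         call. = FALSE)
  }
  tag <- paste0("external:",
                tools::file_path_sans_ext(basename(path)))
  EmbeddingMatrix(values, ids = ids, method = tag)
}

#' Export an embedding matrix
#'
#' Writes an [EmbeddingMatrix-class] in the delimited format
#' [importExternalEmbeddings()] reads back (header \code{id,e1..ed}).
#'
#' @param embedding an [EmbeddingMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportEmbeddings <- function(embedding, path) {
  stopifnot(is(embedding, "EmbeddingMatrix"))
  v <- embedding@values
  out <- data.frame(id = embedding@ids, v, check.names = FALSE)
  names(out) <- c("id", paste0("e", seq_len(ncol(v))))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Align an EmbeddingMatrix's rows with a vector of record ids.
.alignEmbedding <- function(embedding, ids) {
  idx <- match(ids, embedding@ids)
  if (any(is.na(idx))) {
    stop("embedding '", embedding@method, "' is missing ",
         sum(is.na(idx)), " record id(s)", call. = FALSE)
  }
  embedding@values[idx, , drop = FALSE]
}
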