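#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to OpenBabel's canonical form, so that any two
#' notations of the same molecule map to the same string.  Canonicalization
#' is applied at table ingest, which makes duplicate detection and the
#' descriptor/fingerprint caches well defined.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))   # identical outputs
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
    out <- sub("[\t\n].*$", "", out)
    out <- trimws(out)
    if (!nzchar(out)) {
      stop("SMILES could not be parsed: '", s, "'", call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Derive the binary transfection-efficiency label from RLU activity
#'
#' A lipid nanoparticle is labeled satisfying (1) when its luciferase
#' readout reaches the binary cut, i.e. RLU at or above the threshold
#' (default 10000), and unsatisfying (0) below it.
#'
#' @param rlu numeric vector of nonnegative RLU activities.
#' @param scheme a [LabelScheme()].
#' @return integer vector of 0/1 labels.
#' @examples
#' assignBinaryLabel(c(9999, 10000, 0))
#' @export
assignBinaryLabel <- function(rlu, scheme = LabelScheme()) {
  stopifnot(is(scheme, "LabelScheme"))
  if (any(!is.finite(rlu)) || any(rlu < 0)) {
    stop("rlu must be nonnegative and finite", call. = FALSE)
  }
  as.integer(rlu >= scheme@binaryCut)
}

#' Derive the 4-class transfection-efficiency label from RLU activity
#'
#' Bins RLU activity into four ordered classes 0..3 at the scheme's three
#' cuts.  Every cut uses the same boundary convention as the binary rule:
#' an RLU equal to a cut belongs to the higher class, so the label is
#' monotone nondecreasing in RLU and class 3 coincides with the satisfying
#' binary label whenever the binary cut equals the top multiclass cut.
#'
#' @inheritParams assignBinaryLabel
#' @return integer vector of labels in 0..3.
#' @examples
#' assignMulticlassLabel(c(50, 100, 5000, 10000))
#' @export
assignMulticlassLabel <- function(rlu, scheme = LabelScheme()) {
  stopifnot(is(scheme, "LabelScheme"))
  cuts <- scheme@multiclassCuts
  if (length(cuts) != 3L || any(diff(cuts) <= 0)) {
    stop("scheme must have 3 strictly increasing multiclass cuts",
         call. = FALSE)
  }
  if (any(!is.finite(rlu)) || any(rlu < 0)) {
    stop("rlu must be nonnegative and finite", call. = FALSE)
  }
  vapply(rlu, function(x) sum(x >= cuts), numeric(1)) |> as.integer()
}

#' Read a lipid nanoparticle table
#'
#' Reads a delimited table of ionizable-lipid records (one row per lipid),
#' canonicalizes the SMILES, and derives binary and multiclass TE labels
#' from the RLU column when present.  Rows whose SMILES cannot be parsed
#' are an error in strict mode; in lenient mode they are skipped with a
#' warning reporting how many were dropped.  Duplicate canonical SMILES
#' carrying conflicting labels are reported with a warning, never merged.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema named character vector mapping the roles
#'   \code{id}, \code{smiles}, \code{rlu}, \code{binary_label},
#'   \code{multiclass_label}, \code{family} to column names in the file;
#'   only \code{smiles} is mandatory.  A missing \code{id} role numbers the
#'   records \code{L1..Ln}.
#' @param scheme [LabelScheme()] used to derive labels from RLU.
#' @param strict if TRUE (default) an unparseable SMILES aborts with an
#'   error naming the row; if FALSE the row is skipped.
#' @param sep field separator; guessed from the file extension by default.
#' @return a data.frame with columns id, smiles (canonical), rlu,
#'   binary_label, multiclass_label, family (absent fields are NA).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(smiles = c("CCO", "CCN"), rlu = c(500, 20000)),
#'           f, row.names = FALSE)
#' readLnpTable(f)
#' @export
readLnpTable <- function(path,
                         schema = c(id = "id", smiles = "smiles",
                                    rlu = "rlu",
                                    binary_label = "binary_label",
                                    multiclass_label = "multiclass_label",
                                    family = "family"),
                         scheme = LabelScheme(),
                         strict = TRUE,
                         sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t"
           else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (nrow(tab) == 0L) stop("empty input table: ", path, call. = FALSE)
  if (!("smiles" %in% names(schema)) || !(schema[["smiles"]] %in% names(tab)))
    stop("schema error: SMILES column '",
         if ("smiles" %in% names(schema)) schema[["smiles"]] else "<unset>",
         "' not found in ", path, call. = FALSE)
  for (role in setdiff(names(schema), "smiles")) {
    if (!(schema[[role]] %in% names(tab))) schema <- schema[names(schema) != role]
  }

  getcol <- function(role, as = identity) {
    if (role %in% names(schema)) as(tab[[schema[[role]]]]) else rep(NA, nrow(tab))
  }
  rec <- data.frame(
    id = if ("id" %in% names(schema)) as.character(tab[[schema[["id"]]]])
         else sprintf("L%d", seq_len(nrow(tab))),
    smiles = as.character(tab[[schema[["smiles"]]]]),
    rlu = getcol("rlu", as.numeric),
    binary_label = getcol("binary_label", as.integer),
    multiclass_label = getcol("multiclass_label", as.integer),
    family = getcol("family", as.integer),
    stringsAsFactors = FALSE
  )

  canon <- rep(NA_character_, nrow(rec))
  bad <- integer(0)
  for (i in seq_len(nrow(rec))) {
    canon[i] <- tryCatch(canonicalizeSmiles(rec$smiles[i]),
                         error = function(e) NA_character_)
    if (is.na(canon[i])) {
      if (strict) stop("row ", i, " (id '", rec$id[i],
                       "'): unparseable SMILES '", rec$smiles[i], "'",
                       call. = FALSE)
      bad <- c(bad, i)
    }
  }
  if (length(bad)) {
    warning(length(bad), " row(s) with unparseable SMILES skipped",
            call. = FALSE)
    rec <- rec[-bad, , drop = FALSE]
    canon <- canon[-bad]
  }
  rec$smiles <- canon

  if (any(!is.na(rec$rlu))) {
    has <- !is.na(rec$rlu)
    derived_bin <- assignBinaryLabel(rec$rlu[has], scheme)
    if (any(!is.na(rec$binary_label[has])) &&
        any(rec$binary_label[has] != derived_bin, na.rm = TRUE)) {
      warning("provided binary labels disagree with thresholded RLU; ",
              "derived labels kept", call. = FALSE)
    }
    rec$binary_label[has] <- derived_bin
    mc <- rec$multiclass_label
    rec$multiclass_label[has] <- assignMulticlassLabel(rec$rlu[has], scheme)
    if (any(!is.na(mc[has])) &&
        any(mc[has] != rec$multiclass_label[has], na.rm = TRUE)) {
      warning("provided multiclass labels disagree with thresholded RLU; ",
              "derived labels kept", call. = FALSE)
    }
  }
  if (any(!is.na(rec$multiclass_label)) &&
      !all(rec$multiclass_label %in% c(NA, 0:3))) {
    stop("multiclass labels must be in 0..3", call. = FALSE)
  }

  dup <- split(seq_len(nrow(rec)), rec$smiles)
  for (grp in dup) {
    if (length(grp) > 1L) {
      labs <- unique(stats::na.omit(rec$binary_label[grp]))
      mlabs <- unique(stats::na.omit(rec$multiclass_label[grp]))
      if (length(labs) > 1L || length(mlabs) > 1L) {
        warning("duplicate canonical SMILES '", rec$smiles[grp[1]],
                "' with conflicting labels (ids: ",
                paste(rec$id[grp], collapse = ", "), ")", call. = FALSE)
      }
    }
  }
  rec
}

#' Write a lipid nanoparticle table
#'
#' Writes records in the same tabular format [readLnpTable()] consumes,
#' with canonical SMILES and any derived label columns, so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param records data.frame as returned by [readLnpTable()] or
#'   [generateLipidLibrary()].
#' @param path output file path (CSV; TSV when the extension is .tsv).
#' @return \code{path}, invisibly.
#' @export
writeLnpTable <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
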