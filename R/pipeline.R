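#' Default pipeline run configuration
#'
#' Assembles the configuration consumed by [runCommand()]: input/output
#' locations, the embedding methods to compare, the label task, and the
#' sub-configurations of the synthetic generator, the GCN and the
#' boosted-tree head.  Can be loaded from a JSON document with
#' \code{jsonlite::read_json(path, simplifyVector = TRUE)} and amended
#' programmatically; every output artifact records the seed it was
#' produced under.
#'
#' @param outputDir directory for artifacts (created if missing).
#' @param input path of the lipid table CSV (written by
#'   \code{simulate}, consumed by the other commands).
#' @param methods embedding methods to compare (subset of
#'   \code{"expert"}, \code{"cfp"}, \code{"gcn"}).
#' @param label \code{"multiclass"} or \code{"binary"}.
#' @param k cross-validation folds.
#' @param seed master seed for the run.
#' @param synth,gcn,gbt optional overrides: [synthConfig()],
#'   [gcnConfig()], [gbtConfig()] (defaults derived from \code{seed}).
#' @return a list of class \code{runConfig}.
#' @export
runConfig <- function(outputDir = "lipidte_run",
                      input = file.path(outputDir, "library.csv"),
                      methods = c("expert", "cfp", "gcn"),
                      label = "multiclass",
                      k = 5L, seed = 1L,
                      synth = NULL, gcn = NULL, gbt = NULL) {
  bad <- setdiff(methods, c("expert", "cfp", "gcn"))
  if (length(bad)) {
    stop("unknown embedding method(s): ", paste(bad, collapse = ", "),
         "; valid methods are expert, cfp, gcn", call. = FALSE)
  }
  stopifnot(label %in% c("multiclass", "binary"))
  cfg <- list(outputDir = outputDir, input = input, methods = methods,
              label = label, k = as.integer(k), seed = as.integer(seed),
              synth = if (is.null(synth)) synthConfig(seed = seed) else synth,
              gcn = if (is.null(gcn)) gcnConfig(seed = seed) else gcn,
              gbt = if (is.null(gbt)) gbtConfig(seed = seed) else gbt)
  class(cfg) <- "runConfig"
  cfg
}

.writeManifest <- function(config, command, artifacts) {
  manifest <- list(
    command = command,
    seed = config$seed,
    config_hash = .configHash(config),
    package_version = as.character(utils::packageVersion("LipidTE")),
    artifacts = artifacts)
  path <- file.path(config$outputDir,
                    paste0("manifest_", gsub("-", "_", command), ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

.configHash <- function(config) {
  ser <- jsonlite::toJSON(config[setdiff(names(config), "outputDir")],
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  # small deterministic digest; collision resistance is not a goal here
  sum(utf8ToInt(as.character(ser)) *
        (seq_len(nchar(as.character(ser))) %% 97 + 1)) %% 100000000
}

.loadEmbeddingsFor <- function(config, records) {
  embs <- list()
  for (m in config$methods) {
    f <- file.path(config$outputDir, paste0("embeddings_", m, ".csv"))
    if (!file.exists(f)) {
      stop("embeddings for method '", m, "' not found at ", f,
           "; run the featurize/train-gcn commands first", call. = FALSE)
    }
    e <- importExternalEmbeddings(f)
    e@method <- if (m %in% names(.METHOD_DIMS)) m else e@method
    validObject(e)
    embs[[m]] <- e
  }
  embs
}

#' Run one pipeline command
#'
#' Command-line style orchestration of the full workflow; each command
#' reads and writes plain-text artifacts under \code{config$outputDir}
#' and records a manifest (command, seed, config hash, artifact list),
#' so a rerun with the same configuration reproduces the artifacts
#' bit for bit.
#'
#' \describe{
#'   \item{simulate}{generate the synthetic lipid library CSV.}
#'   \item{featurize}{compute expert/cfp embeddings of the input table.}
#'   \item{train-gcn}{train the GCN on a stratified 80/20 train/val
#'     split of the input table, checkpoint it, and export its
#'     embeddings.}
#'   \item{train}{fit the boosted head on the first configured
#'     embedding and export its predicted probabilities.}
#'   \item{evaluate}{stratified k-fold cross-validation report.}
#'   \item{holdout}{lipid-family holdout report.}
#'   \item{cluster}{k-means + NMI summary and 2-D PCA projection.}
#' }
#'
#' @param command one of \code{"simulate"}, \code{"featurize"},
#'   \code{"train-gcn"}, \code{"train"}, \code{"evaluate"},
#'   \code{"holdout"}, \code{"cluster"}.
#' @param config a [runConfig()].
#' @return invisibly, the list of artifact paths written.
#' @export
runCommand <- function(command = c("simulate", "featurize", "train-gcn",
                                   "train", "evaluate", "holdout",
                                   "cluster"),
                       config = runConfig()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  if (command == "simulate") {
    lib <- generateLipidLibrary(config$synth)
    out$library <- writeLnpTable(lib, config$input)
  } else {
    records <- readLnpTable(config$input,
                            scheme = config$synth$scheme %||% LabelScheme())
    if (command == "featurize") {
      for (m in intersect(config$methods, c("expert", "cfp"))) {
        e <- computeEmbeddings(records, m)
        f <- file.path(config$outputDir, paste0("embeddings_", m, ".csv"))
        out[[paste0("embeddings_", m)]] <- exportEmbeddings(e, f)
      }
    } else if (command == "train-gcn") {
      col <- paste0(config$label, "_label")
      y <- records[[col]]
      gcfg <- config$gcn
      gcfg$nClasses <- max(length(unique(y)), 2L)
      folds <- stratifiedKFold(y, k = 5L, seed = config$seed)
      val_idx <- sort(folds[[1]])
      tr_idx <- setdiff(seq_len(nrow(records)), val_idx)
      graphs <- lapply(records$smiles, buildMolGraph)
      model <- trainGCN(graphs[tr_idx], y[tr_idx], graphs[val_idx],
                        y[val_idx], gcfg)
      out$gcn_model <- saveGCNModel(
        model, file.path(config$outputDir, "gcn_model.json"))
      e <- extractEmbeddings(model, graphs, records$id)
      out$embeddings_gcn <- exportEmbeddings(
        e, file.path(config$outputDir, "embeddings_gcn.csv"))
    } else if (command == "train") {
      embs <- .loadEmbeddingsFor(config, records)
      col <- paste0(config$label, "_label")
      m <- config$methods[1]
      V <- .alignEmbedding(embs[[m]], records$id)
      fit <- trainClassifier(V, records[[col]], config$gbt)
      p <- predictProba(fit, V)
      pred <- data.frame(id = records$id, p, check.names = FALSE)
      names(pred) <- c("id", paste0("p_class", colnames(p)))
      f <- file.path(config$outputDir,
                     paste0("predictions_", m, ".csv"))
      utils::write.csv(pred, f, row.names = FALSE)
      out$predictions <- f
    } else if (command %in% c("evaluate", "holdout")) {
      embs <- .loadEmbeddingsFor(config, records)
      rep <- if (command == "evaluate") {
        crossvalExperiment(records, embs, label = config$label,
                           k = config$k, seed = config$seed,
                           config = config$gbt)
      } else {
        familyHoldoutExperiment(records, embs, label = config$label,
                                seed = config$seed, config = config$gbt)
      }
      tag <- if (command == "evaluate") "cv" else "holdout"
      jf <- file.path(config$outputDir, paste0("eval_", tag, ".json"))
      cf <- file.path(config$outputDir, paste0("eval_", tag, ".csv"))
      writeEvalReport(rep, jf, cf)
      out$report_json <- jf; out$report_csv <- cf
    } else if (command == "cluster") {
      embs <- .loadEmbeddingsFor(config, records)
      summ <- clusterStructureSummary(records, embs, seed = config$seed)
      f <- file.path(config$outputDir, "cluster_nmi.csv")
      utils::write.csv(summ, f, row.names = FALSE)
      out$cluster_nmi <- f
      for (m in names(embs)) {
        pr <- project2D(embs[[m]])
        pf <- file.path(config$outputDir,
                        paste0("projection_", m, ".csv"))
        utils::write.csv(data.frame(id = rownames(pr), pr), pf,
                         row.names = FALSE)
        out[[paste0("projection_", m)]] <- pf
      }
    }
  }
  out$manifest <- .writeManifest(config, command,
                                 artifacts = unlist(out, use.names = FALSE))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
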