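#' Classification metric suite
#'
#' Computes the four imbalance-aware metrics used throughout the
#' evaluation protocols: area under the ROC curve (standard for binary
#' targets, macro-averaged one-vs-rest for multiclass), balanced accuracy
#' (mean per-class recall), support-weighted F1, and the (generalized,
#' for multiclass) Matthews correlation coefficient.  Predicted classes
#' are the probability argmax, ties resolved toward the first column.
#' AUC is reported as NA whenever some class has zero positives or zero
#' negatives in \code{yTrue} -- the situation that arises when an entire
#' held-out lipid family carries fewer than two distinct classes.
#'
#' @param yTrue vector of true labels; values must appear in
#'   \code{colnames(pPred)} (or be integer indices 0..M-1 for unnamed
#'   columns).
#' @param pPred numeric matrix n x M of class probabilities, rows summing
#'   to 1 within 1e-6.
#' @return named numeric vector with elements \code{auc},
#'   \code{balanced_accuracy}, \code{weighted_f1}, \code{mcc}.
#' @export
metricSuite <- function(yTrue, pPred) {
  if (is.vector(pPred)) pPred <- matrix(pPred, ncol = length(pPred))
  stopifnot(length(yTrue) == nrow(pPred), ncol(pPred) >= 2L)
  if (any(abs(rowSums(pPred) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  classes <- colnames(pPred)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(pPred)) - 1L)
  yTrue <- as.character(yTrue)
  if (!all(yTrue %in% classes)) {
    stop("labels outside the prediction class list", call. = FALSE)
  }
  M <- length(classes)
  pred <- classes[max.col(pPred, ties.method = "first")]

  # confusion matrix over the full class list
  cm <- table(factor(yTrue, classes), factor(pred, classes))

  support <- rowSums(cm)
  present <- support > 0
  recall <- diag(cm) / support
  prec_den <- colSums(cm)
  precision <- ifelse(prec_den > 0, diag(cm) / prec_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  f1[!is.finite(f1)] <- 0

  balanced_accuracy <- mean(recall[present])
  weighted_f1 <- sum(f1[present] * support[present]) / sum(support)

  # generalized (multiclass) MCC from the confusion matrix
  s <- sum(cm); c_ok <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c_ok * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  # AUC: NA when any class lacks positives or negatives
  auc <- NA_real_
  if (all(present) && M >= 2L) {
    if (M == 2L) {
      r <- pROC::roc(response = factor(yTrue, classes),
                     predictor = pPred[, 2], levels = classes,
                     direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(r))
    } else {
      per_class <- vapply(seq_len(M), function(k) {
        yk <- factor(as.integer(yTrue == classes[k]), c(0, 1))
        r <- pROC::roc(response = yk, predictor = pPred[, k],
                       levels = c("0", "1"), direction = "<", quiet = TRUE)
        as.numeric(pROC::auc(r))
      }, numeric(1))
      auc <- mean(per_class)
    }
  }
  c(auc = auc, balanced_accuracy = balanced_accuracy,
    weighted_f1 = weighted_f1, mcc = mcc)
}

#' Stratified k-fold partition
#'
#' Splits record indices into k disjoint folds stratified by class: within
#' each class, shuffled members are dealt round-robin over the folds
#' starting from a rotating offset, so each fold's class count differs
#' from exact proportionality by at most 1.  Deterministic given
#' \code{seed}.  Classes with fewer than k members are spread over as
#' many folds as they have members, with a warning.
#'
#' @param labels class label per record.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k integer vectors of record indices (a partition of
#'   \code{seq_along(labels)}).
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (length(labels) < k) stop("fewer records than folds", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    warning("class(es) with fewer than k members: ",
            paste(names(tab)[tab < k], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  folds <- vector("list", k)
  offset <- 0L
  for (cl in names(tab)) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' Paired one-sided t-test across folds
#'
#' Tests whether metric a exceeds metric b on average across matched
#' cross-validation folds (alternative: mean of a - b > 0, k - 1 degrees
#' of freedom).  Degenerate cases follow the limits of the statistic:
#' identical vectors give p = 1; zero-variance differences give p equal
#' to the machine floor when positive and 1 when negative.
#'
#' @param metricA,metricB numeric vectors of equal length k >= 2, one
#'   value per fold.
#' @return the p-value.
#' @examples
#' pairedOneSidedTTest(c(0.6, 0.7, 0.8, 0.9, 1.0),
#'                     c(0.5, 0.5, 0.5, 0.5, 0.5))
#' @export
pairedOneSidedTTest <- function(metricA, metricB) {
  if (length(metricA) != length(metricB)) {
    stop("fold metric vectors must have equal length", call. = FALSE)
  }
  if (length(metricA) < 2L) stop("need at least 2 folds", call. = FALSE)
  d <- metricA - metricB
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (isTRUE(all.equal(mean(d), 0))) return(1)
    return(if (mean(d) > 0) .Machine$double.xmin else 1)
  }
  stats::t.test(metricA, metricB, paired = TRUE,
                alternative = "greater")$p.value
}

.emptyMetrics <- c(auc = NA_real_, balanced_accuracy = NA_real_,
                   weighted_f1 = NA_real_, mcc = NA_real_)

.aggregateReport <- function(perFold) {
  metrics <- c("auc", "balanced_accuracy", "weighted_f1", "mcc")
  agg <- do.call(rbind, lapply(split(perFold, perFold$method), function(df) {
    means <- vapply(metrics, function(m) mean(df[[m]], na.rm = TRUE),
                    numeric(1))
    means[vapply(metrics, function(m) all(is.na(df[[m]])), logical(1))] <- NA
    data.frame(method = df$method[1], t(means), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

.pairwiseComparisons <- function(perFold) {
  metrics <- c("auc", "balanced_accuracy", "weighted_f1", "mcc")
  methods <- unique(perFold$method)
  out <- list()
  for (a in methods) for (b in methods) {
    if (a == b) next
    for (m in metrics) {
      va <- perFold[[m]][perFold$method == a]
      vb <- perFold[[m]][perFold$method == b]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) >= 2L) {
        out[[length(out) + 1L]] <- data.frame(
          method_a = a, method_b = b, metric = m,
          p_value = pairedOneSidedTTest(va[ok], vb[ok]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(method_a = character(0), method_b = character(0),
                  metric = character(0), p_value = numeric(0))
}

# shared inner loop: train on train_idx, evaluate on test_idx, for every
# embedding method under identical seeds
.evalSplit <- function(y, embeddings, ids, train_idx, test_idx, config,
                       fold_id) {
  classes_all <- sort(unique(as.character(y)))
  rows <- lapply(names(embeddings), function(nm) {
    V <- .alignEmbedding(embeddings[[nm]], ids)
    fit <- trainClassifier(V[train_idx, , drop = FALSE], y[train_idx],
                           config)
    p <- predictProba(fit, V[test_idx, , drop = FALSE])
    # classes absent from the training split get probability-0 columns so
    # a held-out family with unseen classes can still be scored
    missing <- setdiff(classes_all, colnames(p))
    if (length(missing)) {
      pad <- matrix(0, nrow(p), length(missing),
                    dimnames = list(NULL, missing))
      p <- cbind(p, pad)[, classes_all, drop = FALSE]
    }
    ms <- metricSuite(y[test_idx], p)
    data.frame(method = nm, fold = fold_id, t(ms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-validated embedding comparison
#'
#' The stratified k-fold protocol: folds are drawn once, stratified by
#' class, and reused unchanged for every embedding method; per fold, a
#' gradient-boosted head with identical hyperparameters and seed is
#' trained on the remaining k-1 folds and scored on the held-out fold
#' with [metricSuite()].  Fold-wise paired one-sided t-tests compare every
#' ordered method pair on every metric.
#'
#' @param records lipid table (data.frame with \code{id} and the label
#'   column).
#' @param embeddings named list of [EmbeddingMatrix-class] objects, each
#'   covering every record id.
#' @param label which label to use: \code{"multiclass"} (default) or
#'   \code{"binary"}.
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment and classifier training.
#' @param config [gbtConfig()] shared by all methods and folds.
#' @return an [EvalReport-class] with protocol \code{"cv"}.
#' @export
crossvalExperiment <- function(records, embeddings,
                               label = c("multiclass", "binary"),
                               k = 5L, seed = 1L,
                               config = gbtConfig(seed = seed)) {
  label <- match.arg(label)
  col <- paste0(label, "_label")
  stopifnot(is.data.frame(records), col %in% names(records))
  y <- records[[col]]
  if (any(is.na(y))) stop("missing ", col, " values", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: a single class cannot be evaluated",
         call. = FALSE)
  }
  folds <- stratifiedKFold(y, k = k, seed = seed)
  perFold <- do.call(rbind, lapply(seq_len(k), function(f) {
    .evalSplit(y, embeddings, records$id,
               train_idx = sort(unlist(folds[-f])),
               test_idx = sort(folds[[f]]), config,
               fold_id = as.character(f))
  }))
  new("EvalReport", perFold = perFold,
      aggregate = .aggregateReport(perFold),
      comparisons = .pairwiseComparisons(perFold),
      protocol = "cv", seed = as.integer(seed))
}

#' Lipid-family holdout evaluation
#'
#' Generalization to unseen chemotypes: for each lipid family, the whole
#' family is held out as the test set and the head is trained on all
#' remaining families, so train and test families are disjoint in every
#' run.  When a held-out family contains fewer than two distinct classes,
#' its AUC is reported absent (NA) -- mirroring the exclusion of families
#' without any satisfying lipid -- while the remaining metrics are still
#' computed.  Aggregate means are taken only over folds where a metric is
#' defined.
#'
#' @inheritParams crossvalExperiment
#' @param records lipid table; must carry a \code{family} column.
#' @return an [EvalReport-class] with protocol \code{"family_holdout"};
#'   fold ids are the family ids.
#' @export
familyHoldoutExperiment <- function(records, embeddings,
                                    label = c("multiclass", "binary"),
                                    seed = 1L,
                                    config = gbtConfig(seed = seed)) {
  label <- match.arg(label)
  col <- paste0(label, "_label")
  stopifnot(is.data.frame(records), col %in% names(records))
  if (!("family" %in% names(records)) || all(is.na(records$family))) {
    stop("records carry no family column", call. = FALSE)
  }
  y <- records[[col]]
  fams <- sort(unique(records$family))
  if (length(fams) < 2L) stop("need at least 2 families", call. = FALSE)
  perFold <- do.call(rbind, lapply(fams, function(fam) {
    test_idx <- which(records$family == fam)
    train_idx <- which(records$family != fam)
    res <- .evalSplit(y, embeddings, records$id, train_idx, test_idx,
                      config, fold_id = as.character(fam))
    res
  }))
  new("EvalReport", perFold = perFold,
      aggregate = .aggregateReport(perFold),
      comparisons = .pairwiseComparisons(perFold),
      protocol = "family_holdout", seed = as.integer(seed))
}

#' Serialize an evaluation report
#'
#' Writes an [EvalReport-class] as JSON (per-fold table, aggregate table,
#' significance table, protocol, seed) and, optionally, as a flat CSV of
#' one row per fold x method.
#'
#' @param report an [EvalReport-class].
#' @param jsonPath output JSON path.
#' @param csvPath optional flat CSV path.
#' @return \code{jsonPath}, invisibly.
#' @export
writeEvalReport <- function(report, jsonPath, csvPath = NULL) {
  stopifnot(is(report, "EvalReport"))
  jsonlite::write_json(
    list(protocol = report@protocol, seed = report@seed,
         per_fold = report@perFold, aggregate = report@aggregate,
         comparisons = report@comparisons),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csvPath)) {
    utils::write.csv(report@perFold, csvPath, row.names = FALSE)
  }
  invisible(jsonPath)
}
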