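test_that("the metric suite reproduces closed-form confusion-matrix cases", {
  # perfect binary predictions
  y <- c(0, 0, 1, 1)
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.1, 0.9), c(0.2, 0.8))
  colnames(p) <- c("0", "1")
  ms <- metricSuite(y, p)
  expect_equal(unname(ms), c(1, 1, 1, 1))

  # TP=4 TN=4 FP=1 FN=1 -> MCC = 15/25 = 0.6
  y2 <- c(rep(1, 5), rep(0, 5))
  pr <- c(rep(0.9, 4), 0.1, rep(0.1, 4), 0.9)
  p2 <- cbind("0" = 1 - pr, "1" = pr)
  ms2 <- metricSuite(y2, p2)
  expect_equal(unname(ms2["mcc"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(ms2["balanced_accuracy"]), 0.8)

  # all-majority predictor on an imbalanced set: chance level
  y3 <- c(rep(0, 8), rep(1, 2))
  p3 <- cbind("0" = rep(0.9, 10), "1" = rep(0.1, 10))
  ms3 <- metricSuite(y3, p3)
  expect_equal(unname(ms3["balanced_accuracy"]), 0.5)
  expect_equal(unname(ms3["mcc"]), 0)

  # AUC is absent when a class has no positives or no negatives
  y4 <- rep(0, 4)
  expect_true(is.na(metricSuite(y4, p)["auc"]))
  expect_error(metricSuite(y, p * 2), "sum to 1")
})

test_that("the metric suite agrees with an independent oracle on random cases", {
  for (i in 1:50) {
    M <- 2L + (i %% 3L)
    n <- 30L
    p <- randomProbs(n, M, seed = i)
    set.seed(1000 + i)
    y <- sample(seq_len(M) - 1L, n, replace = TRUE)
    if (length(unique(y)) < 2L) next
    ms <- metricSuite(y, p)
    want <- oracleMetricSuite(y, p)
    for (m in names(want)) {
      if (is.na(want[[m]])) expect_true(is.na(ms[[m]]))
      else expect_equal(unname(ms[[m]]), unname(want[[m]]),
                        tolerance = 1e-9, info = paste(i, m))
    }
  }
})

test_that("stratified folds are disjoint, exhaustive and proportional within 1", {
  y <- rep(c(0, 1), c(60, 40))
  folds <- stratifiedKFold(y, k = 5, seed = 3)
  expect_length(folds, 5L)
  expect_equal(sort(unlist(folds)), seq_along(y))   # partition
  for (f in folds) {
    expect_equal(sum(y[f] == 0), 12)
    expect_equal(sum(y[f] == 1), 8)
  }
  expect_identical(stratifiedKFold(y, k = 5, seed = 3), folds)
  expect_false(identical(stratifiedKFold(y, k = 5, seed = 4), folds))
  expect_error(stratifiedKFold(y, k = 1), "at least 2")
  expect_warning(stratifiedKFold(c(0, 0, 0, 0, 0, 1), k = 3, seed = 1),
                 "fewer than k")

  # uneven class sizes still deviate from proportionality by at most 1
  set.seed(4)
  y2 <- sample(0:3, 83, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  folds2 <- stratifiedKFold(y2, k = 5, seed = 9)
  expect_equal(sort(unlist(folds2)), seq_along(y2))
  for (cl in unique(y2)) {
    cnt <- vapply(folds2, function(f) sum(y2[f] == cl), numeric(1))
    expect_lte(max(cnt) - min(cnt), 1)
  }
})

test_that("the paired one-sided t-test matches its closed form and degenerate limits", {
  a <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  b <- a - c(0.1, 0.2, 0.3, 0.4, 0.5)
  # closed form: t = mean(d) / (sd(d)/sqrt(k)), df = 4
  d <- a - b
  tstat <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(tstat, 4.2426, tolerance = 1e-4)
  expect_equal(pairedOneSidedTTest(a, b),
               stats::pt(tstat, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pairedOneSidedTTest(a, b), 0.0066, tolerance = 1e-2)

  expect_equal(pairedOneSidedTTest(a, a), 1)
  expect_gt(pairedOneSidedTTest(a, a + 1), 0.5)
  expect_equal(pairedOneSidedTTest(a + 1, a), .Machine$double.xmin)
  expect_error(pairedOneSidedTTest(a, a[1:3]), "equal length")
})

test_that("the paired t-test is null-calibrated at the 5% level", {
  set.seed(20)
  rejections <- 0L
  n_rep <- 2000L
  for (r in seq_len(n_rep)) {
    a <- stats::rnorm(5)
    b <- stats::rnorm(5)
    if (pairedOneSidedTTest(a, b) < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("cross-validation reuses folds and seeds identically across methods", {
  set.seed(30)
  n <- 80L
  rec <- data.frame(id = sprintf("r%02d", 1:n),
                    multiclass_label = rep(0:3, each = 20))
  V <- matrix(stats::rnorm(n * 6), n, 6)
  V[, 1] <- rec$multiclass_label + 0.1 * stats::rnorm(n)
  embs <- list(copy_a = EmbeddingMatrix(V, ids = rec$id,
                                        method = "external:a"),
               copy_b = EmbeddingMatrix(V, ids = rec$id,
                                        method = "external:b"))
  rep_ <- crossvalExperiment(rec, embs, label = "multiclass", k = 5,
                             seed = 2,
                             config = gbtConfig(iterations = 40L,
                                                learningRate = 0.3,
                                                seed = 2))
  pf <- perFoldMetrics(rep_)
  a <- pf[pf$method == "copy_a", -1]
  b <- pf[pf$method == "copy_b", -1]
  expect_equal(a, b, ignore_attr = TRUE)
  # identical methods give p = 1 in every comparison
  cmp <- methodComparisons(rep_)
  expect_true(all(cmp$p_value == 1))
  # informative feature recovers the signal
  expect_gt(aggregateMetrics(rep_)$auc[1], 0.9)

  expect_error(
    crossvalExperiment(rec,
                       list(x = EmbeddingMatrix(V[1:10, ],
                                                ids = rec$id[1:10],
                                                method = "external:x")),
                       k = 5, seed = 1),
    "missing")
})

test_that("family holdout keeps families disjoint and drops AUC for single-class families", {
  set.seed(31)
  n_fam <- 7L
  per <- 12L
  rec <- data.frame(id = sprintf("f%d_%02d", rep(1:n_fam, each = per),
                                 rep(1:per, n_fam)),
                    family = rep(0:(n_fam - 1L), each = per))
  # family 0 is all class 0; others mixed
  rec$binary_label <- ifelse(rec$family == 0, 0L,
                             rep(c(0L, 1L), length.out = nrow(rec)))
  V <- matrix(stats::rnorm(nrow(rec) * 5), ncol = 5)
  V[, 1] <- rec$binary_label + 0.2 * stats::rnorm(nrow(rec))
  embs <- list(feat = EmbeddingMatrix(V, ids = rec$id,
                                      method = "external:feat"))
  rep_ <- familyHoldoutExperiment(rec, embs, label = "binary", seed = 5,
                                  config = gbtConfig(iterations = 40L,
                                                     learningRate = 0.3,
                                                     loss = "binary",
                                                     seed = 5))
  pf <- perFoldMetrics(rep_)
  expect_equal(nrow(pf), n_fam)                  # one run per family
  expect_setequal(pf$fold, as.character(0:6))
  expect_true(is.na(pf$auc[pf$fold == "0"]))     # single-class family
  expect_false(anyNA(pf$auc[pf$fold != "0"]))
  expect_false(anyNA(pf$mcc))
  # aggregate AUC averages only the defined folds
  expect_equal(aggregateMetrics(rep_)$auc,
               mean(pf$auc, na.rm = TRUE))

  expect_error(familyHoldoutExperiment(rec[, c("id", "binary_label")],
                                       embs, label = "binary"),
               "family")
})

test_that("evaluation reports serialize to JSON and CSV", {
  set.seed(33)
  rec <- data.frame(id = sprintf("r%02d", 1:40),
                    binary_label = rep(0:1, 20))
  V <- matrix(stats::rnorm(80), 40, 2)
  V[, 1] <- rec$binary_label
  embs <- list(f = EmbeddingMatrix(V, ids = rec$id, method = "external:f"))
  rep_ <- crossvalExperiment(rec, embs, label = "binary", k = 4, seed = 1,
                             config = gbtConfig(iterations = 10L,
                                                learningRate = 0.3,
                                                loss = "binary", seed = 1))
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  writeEvalReport(rep_, jf, cf)
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(parsed$protocol, "cv")
  expect_equal(nrow(parsed$per_fold), 4L)
  expect_equal(nrow(utils::read.csv(cf)), 4L)
})
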