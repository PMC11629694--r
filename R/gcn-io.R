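#' Save / load a trained GCN model
#'
#' The model checkpoint is a single self-describing JSON document holding
#' the configuration and every weight array (conv layers by degree bin,
#' dense layer, head), plus the training history.  JSON keeps the
#' checkpoint portable and diff-able; weights are written at full double
#' precision.
#'
#' @param model a [GCNModel-class].
#' @param path output path (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @export
saveGCNModel <- function(model, path) {
  stopifnot(is(model, "GCNModel"))
  ser <- list(
    config = model@config,
    conv = lapply(model@convWeights, function(lw) lapply(lw, unclass)),
    denseW = model@denseW, denseB = model@denseB,
    headW = model@headW, headB = model@headB,
    history = model@history)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveGCNModel
#' @export
loadGCNModel <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  # matrices are serialized row-wise as lists of lists; rebuild exactly
  asmat <- function(m) {
    do.call(rbind, lapply(m, function(r) as.numeric(unlist(r))))
  }
  cfg <- lapply(ser$config, function(x) {
    x <- unlist(x)
    if (is.character(x)) x else if (x == round(x)) as.integer(x) else x
  })
  conv <- lapply(ser$conv, function(lw) lapply(lw, asmat))
  hist <- if (is.null(ser$history)) list() else list(
    trainLoss = as.numeric(unlist(ser$history$trainLoss)),
    valLoss = as.numeric(unlist(ser$history$valLoss)),
    bestEpoch = as.integer(ser$history$bestEpoch),
    stoppedEpoch = as.integer(ser$history$stoppedEpoch))
  new("GCNModel", convWeights = conv, denseW = asmat(ser$denseW),
      denseB = as.numeric(unlist(ser$denseB)), headW = asmat(ser$headW),
      headB = as.numeric(unlist(ser$headB)), config = cfg,
      history = hist)
}
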