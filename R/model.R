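# R-side surface of the classifier: initialisation, inference, loss and
# thresholding. The numerical core (embedding, feature-wise batch
# normalisation, single bidirectional LSTM layer, two fully connected
# layers, backpropagation through time, Adam) lives in src/bilstm.cpp and
# runs in single precision.

#' Initialise a promoter classifier
#'
#' Layer stack: embedding (vocabSize -> embedDim) -> batch normalisation
#' over the embedding features (statistics pooled across batch and
#' positions) -> bidirectional LSTM (embedDim -> hiddenDim per direction)
#' -> flatten (seqLen * 2 * hiddenDim) -> FC1 + leaky ReLU -> FC2 +
#' sigmoid. Initialisation is deterministic given \code{seed}: embedding
#' weights are standard normal; LSTM and linear weights are uniform in
#' +/- 1/sqrt(fan).
#'
#' @param config a \code{ModelConfig}.
#' @param seed initialisation seed.
#' @return an untrained \code{TrainedPromoterModel}.
#' @export
buildModel <- function(config = ModelConfig(), seed = 1L) {
  params <- cpp_bilstm_init(config@vocabSize, config@embedDim,
                            config@hiddenDim, config@seqLen, config@fc1Dim,
                            as.integer(seed))
  new("TrainedPromoterModel", config = config, params = params,
      bestEpoch = NA_integer_,
      history = data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0)))
}

#' Forward pass: probabilities for a batch of index vectors
#'
#' Inference mode (batch normalisation uses running statistics), so the
#' output is deterministic for fixed parameters.
#'
#' @param model a \code{TrainedPromoterModel}.
#' @param batch integer matrix, n x seqLen, indices in
#'   [0, vocabSize - 1].
#' @return numeric vector of n probabilities, strictly in (0, 1).
#' @export
forwardProbs <- function(model, batch) {
  cfg <- model@config
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1)
  storage.mode(batch) <- "integer"
  if (ncol(batch) != cfg@seqLen)
    stop(sprintf("batch width %d does not match seq_len %d",
                 ncol(batch), cfg@seqLen))
  if (nrow(batch) && (min(batch) < 0L || max(batch) > cfg@vocabSize - 1L))
    stop(sprintf("indices must lie in [0, %d]", cfg@vocabSize - 1L))
  as.numeric(cpp_bilstm_forward(model@params, batch, cfg@leakySlope))
}

#' Mean binary cross-entropy loss
#'
#' Mean over samples of -(y log p + (1 - y) log(1 - p)), with
#' probabilities clipped to [eps, 1 - eps].
#'
#' @param labels binary labels.
#' @param probs predicted probabilities.
#' @param eps clipping epsilon (default 1e-7).
#' @return non-negative scalar loss.
#' @export
bceLoss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) != length(probs))
    stop("labels and probs must have equal length")
  p <- pmin(pmax(probs, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict promoter probabilities and labels
#'
#' Sequences (or a pre-encoded index matrix) are scored by the forward
#' pass and thresholded: label 1 when probability >= threshold (ties at
#' the threshold classify as positive).
#'
#' @param model a \code{TrainedPromoterModel}.
#' @param newdata a \code{DNAStringSet}/character vector of sequences of
#'   length seqLen + 2, or an integer index matrix of width seqLen.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{prob} and \code{label} (both named by
#'   sequence id when available).
#' @export
predictModel <- function(model, newdata, threshold = 0.5) {
  batch <- if (is.matrix(newdata)) newdata
           else encodeBatch(newdata, padTo = model@config@seqLen)
  prob <- forwardProbs(model, batch)
  names(prob) <- rownames(batch)
  label <- as.integer(prob >= threshold)
  names(label) <- names(prob)
  list(prob = prob, label = label)
}

#' @rdname predictModel
#' @param object a \code{TrainedPromoterModel}.
#' @param ... passed on to \code{predictModel}.
#' @export
setMethod("predict", "TrainedPromoterModel",
          function(object, newdata, ...) predictModel(object, newdata, ...))

#' Number of trainable parameters
#'
#' A pure function of the architecture configuration (batch-norm running
#' statistics are excluded); logged for audit.
#'
#' @param object a \code{TrainedPromoterModel} or \code{ModelConfig}.
#' @return integer parameter count.
#' @export
parameterCount <- function(object) {
  if (is(object, "TrainedPromoterModel")) {
    p <- object@params[!names(object@params) %in%
                         c("bn_run_mean", "bn_run_var")]
    return(sum(vapply(p, length, numeric(1))))
  }
  cfg <- object
  G <- 4L * cfg@hiddenDim
  cfg@vocabSize * cfg@embedDim +            # embedding
    2L * cfg@embedDim +                     # batchnorm gamma/beta
    2L * (G * cfg@embedDim + G * cfg@hiddenDim + G) +  # both LSTM dirs
    cfg@fc1Dim * flattenedDim(cfg) + cfg@fc1Dim +      # FC1
    cfg@fc1Dim + 1L                                    # FC2
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-contained list (architecture configuration,
#' parameter state, best epoch, training history) serialised with
#' \code{saveRDS}.
#'
#' @param model a \code{TrainedPromoterModel}.
#' @param path checkpoint path.
#' @return \code{saveModelCheckpoint}: (invisibly) the path;
#'   \code{loadModelCheckpoint}: the restored model.
#' @export
saveModelCheckpoint <- function(model, path) {
  cfg <- model@config
  saveRDS(list(
    config = list(vocabSize = cfg@vocabSize, embedDim = cfg@embedDim,
                  hiddenDim = cfg@hiddenDim, seqLen = cfg@seqLen,
                  fc1Dim = cfg@fc1Dim, leakySlope = cfg@leakySlope,
                  nLstmLayers = cfg@nLstmLayers),
    params = model@params, best_epoch = model@bestEpoch,
    history = model@history), path)
  invisible(path)
}

#' @rdname saveModelCheckpoint
#' @export
loadModelCheckpoint <- function(path) {
  ck <- readRDS(path)
  new("TrainedPromoterModel", config = do.call(ModelConfig, ck$config),
      params = ck$params, bestEpoch = as.integer(ck$best_epoch),
      history = ck$history)
}
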