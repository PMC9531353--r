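# Training loop and dataset splitting. Training always runs the full
# epoch budget and then restores the parameter state from the epoch with
# minimum validation loss (ties resolve to the earliest epoch), matching
# post-hoc model selection rather than patience-based early stopping.

#' Train the promoter classifier
#'
#' Mini-batch Adam optimisation; the training order is reshuffled every
#' epoch, the last incomplete batch is kept, and validation loss is
#' computed on the full validation set after each epoch. The returned
#' model carries the parameter state of the best epoch plus the complete
#' loss history. Deterministic given the seeds: the model initialisation
#' seed is derived from \code{tcfg@seed} and the shuffle stream is a
#' separate derived seed.
#'
#' @param config a \code{ModelConfig}.
#' @param trainSet,valSet \code{LabelledDataset}s of uniform-length
#'   sequences (seqLen + 2 nt); ids must be disjoint across the two.
#' @param tcfg a \code{TrainConfig}.
#' @param verbose print per-epoch losses.
#' @return a fitted \code{TrainedPromoterModel}.
#' @export
trainModel <- function(config = ModelConfig(), trainSet, valSet,
                       tcfg = TrainConfig(), verbose = FALSE) {
  if (!length(trainSet)) stop("training set is empty")
  if (!length(valSet)) stop("validation set is empty")
  if (length(intersect(names(sequences(trainSet)), names(sequences(valSet)))))
    stop("train and validation ids must be disjoint")
  Xtr <- encodeBatch(sequences(trainSet), padTo = config@seqLen)
  Xval <- encodeBatch(sequences(valSet), padTo = config@seqLen)
  model <- buildModel(config, seed = mixSeed(tcfg@seed, 1L))
  fit <- cpp_bilstm_train(model@params, Xtr, as.numeric(labels(trainSet)),
                          Xval, as.numeric(labels(valSet)),
                          config@leakySlope, tcfg@maxEpochs, tcfg@batchSize,
                          tcfg@learningRate, mixSeed(tcfg@seed, 2L),
                          tcfg@shuffleEachEpoch)
  history <- data.frame(epoch = seq_along(fit$train_loss),
                        train_loss = fit$train_loss,
                        val_loss = fit$val_loss)
  if (verbose) {
    for (e in seq_len(nrow(history)))
      message(sprintf("epoch %d: train %.4f  val %.4f", e,
                      history$train_loss[e], history$val_loss[e]))
  }
  new("TrainedPromoterModel", config = config, params = fit$params,
      bestEpoch = as.integer(fit$best_epoch), history = history)
}

#' Stratified holdout split of a labelled dataset
#'
#' Splits by class so a balanced input stays balanced (1:1) in every
#' split. Deterministic given \code{seed}; splits are disjoint and
#' exhaustive.
#'
#' @param dataset a \code{LabelledDataset} containing both classes.
#' @param fractions named or positional (train, validation, test)
#'   fractions, positive and summing to 1.
#' @param seed shuffle seed.
#' @return named list of three \code{LabelledDataset}s (train,
#'   validation, test).
#' @export
splitDataset <- function(dataset, fractions = c(train = 0.8,
                                                validation = 0.1,
                                                test = 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be three positive values")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop(sprintf("fractions must sum to 1 (got %.4f)", sum(fractions)))
  lab <- labels(dataset)
  if (!all(c(0L, 1L) %in% lab))
    stop("dataset must contain both classes")
  assign_split <- function(idx) {
    idx <- withSeed(mixSeed(seed, 7L), sample(idx))
    cuts <- round(cumsum(c(0, fractions)) * length(idx))
    split(idx, factor(rep(VALID_SPLIT_TAGS, diff(cuts)),
                      levels = VALID_SPLIT_TAGS))
  }
  pos <- assign_split(which(lab == 1L))
  neg <- assign_split(which(lab == 0L))
  out <- lapply(VALID_SPLIT_TAGS, function(tag) {
    idx <- sort(c(pos[[tag]], neg[[tag]]))
    sub <- sequences(dataset)[idx]
    ds <- new("LabelledDataset", sequences = sub, labels = lab[idx],
              splitTag = tag)
    if (!all(c(0L, 1L) %in% lab[idx]))
      stop(sprintf("split '%s' would lack one class; use larger fractions or more data",
                   tag))
    ds
  })
  names(out) <- VALID_SPLIT_TAGS
  out
}
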