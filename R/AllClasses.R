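#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   oligonucleotideFrequency width
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats runif predict
#' @importFrom utils read.delim write.table write.csv head tail
#'   packageVersion
#' @useDynLib promForge, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

VALID_SPLIT_TAGS <- c("train", "validation", "test")

#' Labelled promoter/non-promoter dataset
#'
#' A set of fixed-alphabet DNA sequences with binary labels (1 = promoter,
#' 0 = non-promoter) and a split tag. Record ids (the names of the
#' underlying \code{DNAStringSet}) must be unique.
#'
#' @slot sequences a \code{DNAStringSet}, uniquely named.
#' @slot labels integer vector of 0/1 labels, one per sequence.
#' @slot splitTag one of \code{"train"}, \code{"validation"}, \code{"test"}.
#' @exportClass LabelledDataset
setClass("LabelledDataset",
  representation(sequences = "DNAStringSet", labels = "integer",
                 splitTag = "character"))

setValidity("LabelledDataset", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@sequences))
    msg <- c(msg, "labels and sequences must have equal length")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be binary (0/1)")
  ids <- names(object@sequences)
  if (length(object@sequences) && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "sequence ids must be present and unique")
  if (length(object@splitTag) != 1L || !object@splitTag %in% VALID_SPLIT_TAGS)
    msg <- c(msg, "splitTag must be one of train/validation/test")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelledDataset
#'
#' @param sequences a named \code{DNAStringSet} (or named character vector).
#' @param labels binary labels, one per sequence.
#' @param splitTag split this dataset belongs to.
#' @return a \code{LabelledDataset}.
#' @export
LabelledDataset <- function(sequences, labels, splitTag = "train") {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  new("LabelledDataset", sequences = sequences,
      labels = as.integer(labels), splitTag = splitTag)
}

#' @rdname LabelledDataset
#' @param object,x a \code{LabelledDataset}.
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname LabelledDataset
#' @export
setMethod("sequences", "LabelledDataset", function(object) object@sequences)

#' @rdname LabelledDataset
#' @param ... unused.
#' @export
setMethod("labels", "LabelledDataset", function(object, ...) object@labels)

#' @rdname LabelledDataset
#' @export
setGeneric("splitTag", function(object) standardGeneric("splitTag"))

#' @rdname LabelledDataset
#' @export
setMethod("splitTag", "LabelledDataset", function(object) object@splitTag)

#' @rdname LabelledDataset
#' @export
setMethod("length", "LabelledDataset", function(x) length(x@sequences))

setMethod("show", "LabelledDataset", function(object) {
  cat(sprintf("LabelledDataset [%s]: %d records (%d positive, %d negative)\n",
              object@splitTag, length(object),
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

#' Configuration for artificial-negative construction
#'
#' Promoters are split into \code{nBlocks} blocks of \code{blockSize} nt;
#' \code{nSubstitutional} blocks are repositioned by a random permutation
#' while the remaining ("conservative") blocks stay in place. Defaults
#' (15 nt x 20 blocks, 8 substitutional) reproduce the standard scheme for
#' 300 nt promoter windows.
#'
#' @slot blockSize block length in nt.
#' @slot nBlocks number of blocks per sequence.
#' @slot nSubstitutional number of blocks selected for repositioning
#'   (0 for the identity construction, otherwise at least 2).
#' @slot forbidIdentity if TRUE, permutations reproducing the source
#'   sequence are redrawn.
#' @slot maxResample maximum permutation redraws before failing.
#' @exportClass NegativeConfig
setClass("NegativeConfig",
  representation(blockSize = "integer", nBlocks = "integer",
                 nSubstitutional = "integer", forbidIdentity = "logical",
                 maxResample = "integer"))

setValidity("NegativeConfig", function(object) {
  msg <- character()
  if (object@blockSize < 1L || object@nBlocks < 1L)
    msg <- c(msg, "blockSize and nBlocks must be positive")
  k <- object@nSubstitutional
  if (!(k == 0L || (k >= 2L && k <= object@nBlocks)))
    msg <- c(msg, "nSubstitutional must be 0 or in [2, nBlocks]")
  if (object@maxResample < 1L) msg <- c(msg, "maxResample must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname NegativeConfig-class
#' @param blockSize,nBlocks,nSubstitutional,forbidIdentity,maxResample see slots.
#' @return a \code{NegativeConfig}.
#' @export
NegativeConfig <- function(blockSize = 15L, nBlocks = 20L,
                           nSubstitutional = 8L, forbidIdentity = TRUE,
                           maxResample = 100L) {
  new("NegativeConfig", blockSize = as.integer(blockSize),
      nBlocks = as.integer(nBlocks),
      nSubstitutional = as.integer(nSubstitutional),
      forbidIdentity = forbidIdentity, maxResample = as.integer(maxResample))
}

#' A single constructed non-promoter with its construction trace
#'
#' @slot residues the recombined sequence.
#' @slot sourceId id of the template promoter.
#' @slot selectedBlocks sorted 0-based indices of the substitutional blocks.
#' @slot permutation 0-based source block index filled into each gap, in
#'   ascending gap order (gap k receives source block \code{permutation[k]}).
#' @slot seed RNG seed used for this construction.
#' @exportClass ArtificialNegative
setClass("ArtificialNegative",
  representation(residues = "character", sourceId = "character",
                 selectedBlocks = "integer", permutation = "integer",
                 seed = "integer"))

setMethod("show", "ArtificialNegative", function(object) {
  cat(sprintf("ArtificialNegative from '%s' (%d nt), %d substitutional blocks, seed %d\n",
              object@sourceId, nchar(object@residues),
              length(object@selectedBlocks), object@seed))
})

#' A set of constructed non-promoters plus their audit trace
#'
#' @slot sequences \code{DNAStringSet} of constructed negatives.
#' @slot trace data.frame with columns source_id, selected_blocks,
#'   permutation (comma-joined, 0-based) and seed.
#' @exportClass ArtificialNegativeSet
setClass("ArtificialNegativeSet",
  representation(sequences = "DNAStringSet", trace = "data.frame"))

setValidity("ArtificialNegativeSet", function(object) {
  if (nrow(object@trace) != length(object@sequences))
    return("trace must have one row per sequence")
  TRUE
})

#' @rdname ArtificialNegativeSet-class
#' @param object,x an \code{ArtificialNegativeSet}.
#' @export
setMethod("sequences", "ArtificialNegativeSet", function(object) object@sequences)

#' @rdname ArtificialNegativeSet-class
#' @export
setGeneric("negativeTrace", function(object) standardGeneric("negativeTrace"))

#' @rdname ArtificialNegativeSet-class
#' @export
setMethod("negativeTrace", "ArtificialNegativeSet", function(object) object@trace)

#' @rdname ArtificialNegativeSet-class
#' @export
setMethod("length", "ArtificialNegativeSet", function(x) length(x@sequences))

setMethod("show", "ArtificialNegativeSet", function(object) {
  cat(sprintf("ArtificialNegativeSet: %d constructed non-promoters\n",
              length(object)))
})

#' Classifier architecture configuration
#'
#' Defaults follow the reference promoter-classification architecture:
#' a 65-token vocabulary (64 triplets + index 0 for unknown/padding),
#' 64-dimensional embedding, a single bidirectional LSTM layer with 128
#' hidden units per direction over 298 positions, a 128-unit fully
#' connected layer with leaky-ReLU activation (slope 0.01) and a sigmoid
#' output unit. The flattened dimension is seqLen * 2 * hiddenDim
#' (76288 for defaults).
#'
#' @slot vocabSize,embedDim,hiddenDim,seqLen,fc1Dim integer dimensions.
#' @slot leakySlope negative-side slope of the leaky ReLU.
#' @slot nLstmLayers number of bidirectional LSTM layers (only 1 supported).
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(vocabSize = "integer", embedDim = "integer",
                 hiddenDim = "integer", seqLen = "integer",
                 fc1Dim = "integer", leakySlope = "numeric",
                 nLstmLayers = "integer"))

setValidity("ModelConfig", function(object) {
  dims <- c(object@vocabSize, object@embedDim, object@hiddenDim,
            object@seqLen, object@fc1Dim)
  msg <- character()
  if (any(dims < 1L)) msg <- c(msg, "all dimensions must be positive")
  if (object@leakySlope <= 0 || object@leakySlope >= 1)
    msg <- c(msg, "leakySlope must be in (0, 1)")
  if (object@nLstmLayers != 1L)
    msg <- c(msg, "only a single bidirectional LSTM layer is supported")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelConfig-class
#' @param vocabSize,embedDim,hiddenDim,seqLen,fc1Dim,leakySlope,nLstmLayers
#'   see slots.
#' @return a \code{ModelConfig}.
#' @export
ModelConfig <- function(vocabSize = 65L, embedDim = 64L, hiddenDim = 128L,
                        seqLen = 298L, fc1Dim = 128L, leakySlope = 0.01,
                        nLstmLayers = 1L) {
  new("ModelConfig", vocabSize = as.integer(vocabSize),
      embedDim = as.integer(embedDim), hiddenDim = as.integer(hiddenDim),
      seqLen = as.integer(seqLen), fc1Dim = as.integer(fc1Dim),
      leakySlope = leakySlope, nLstmLayers = as.integer(nLstmLayers))
}

#' @rdname ModelConfig-class
#' @param object a \code{ModelConfig}.
#' @export
setGeneric("flattenedDim", function(object) standardGeneric("flattenedDim"))

#' @rdname ModelConfig-class
#' @export
setMethod("flattenedDim", "ModelConfig", function(object)
  object@seqLen * 2L * object@hiddenDim)

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: vocab %d, embed %d, hidden %d x2 dirs, ",
                     "seq_len %d, flatten %d, fc1 %d\n"),
              object@vocabSize, object@embedDim, object@hiddenDim,
              object@seqLen, flattenedDim(object), object@fc1Dim))
})

#' Training schedule configuration
#'
#' Adam optimisation with mini-batches; the returned model is the state
#' at the epoch of minimum validation loss.
#'
#' @slot maxEpochs number of epochs to run.
#' @slot batchSize mini-batch size (the last incomplete batch is kept).
#' @slot learningRate Adam step size.
#' @slot seed master seed controlling initialisation and shuffling.
#' @slot shuffleEachEpoch reshuffle training order every epoch.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(maxEpochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer",
                 shuffleEachEpoch = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param maxEpochs,batchSize,learningRate,seed,shuffleEachEpoch see slots.
#' @return a \code{TrainConfig}.
#' @export
TrainConfig <- function(maxEpochs = 50L, batchSize = 64L,
                        learningRate = 0.001, seed = 1L,
                        shuffleEachEpoch = TRUE) {
  new("TrainConfig", maxEpochs = as.integer(maxEpochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      seed = as.integer(seed), shuffleEachEpoch = shuffleEachEpoch)
}

#' A (possibly trained) promoter classifier
#'
#' @slot config the \code{ModelConfig}.
#' @slot params named list of parameter matrices/vectors.
#' @slot bestEpoch epoch of minimum validation loss (NA before training).
#' @slot history data.frame with epoch, train_loss, val_loss.
#' @exportClass TrainedPromoterModel
setClass("TrainedPromoterModel",
  representation(config = "ModelConfig", params = "list",
                 bestEpoch = "integer", history = "data.frame"))

#' @rdname TrainedPromoterModel-class
#' @param object a \code{TrainedPromoterModel}.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname TrainedPromoterModel-class
#' @export
setMethod("modelConfig", "TrainedPromoterModel", function(object) object@config)

#' @rdname TrainedPromoterModel-class
#' @export
setGeneric("bestEpoch", function(object) standardGeneric("bestEpoch"))

#' @rdname TrainedPromoterModel-class
#' @export
setMethod("bestEpoch", "TrainedPromoterModel", function(object) object@bestEpoch)

#' @rdname TrainedPromoterModel-class
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname TrainedPromoterModel-class
#' @export
setMethod("trainingHistory", "TrainedPromoterModel",
          function(object) object@history)

setMethod("show", "TrainedPromoterModel", function(object) {
  fitted <- !is.na(object@bestEpoch)
  cat(sprintf("TrainedPromoterModel (%s): %s parameters\n",
              if (fitted) sprintf("best epoch %d of %d", object@bestEpoch,
                                  nrow(object@history)) else "untrained",
              format(parameterCount(object), big.mark = ",")))
})

#' A regulatory motif to plant in simulated promoters
#'
#' @slot name motif name (e.g. "TATA-box").
#' @slot consensus consensus string over A/C/G/T.
#' @slot positionStart,positionEnd TSS-relative window (negative =
#'   upstream); the consensus is left-anchored at positionStart.
#' @slot mutationProb per-position probability that a consensus letter is
#'   replaced by a fresh draw from the background composition.
#' @exportClass MotifSpec
setClass("MotifSpec",
  representation(name = "character", consensus = "character",
                 positionStart = "integer", positionEnd = "integer",
                 mutationProb = "numeric"))

setValidity("MotifSpec", function(object) {
  msg <- character()
  if (!grepl("^[ACGT]+$", object@consensus))
    msg <- c(msg, "consensus must be a non-empty string over A/C/G/T")
  if (nchar(object@consensus) > object@positionEnd - object@positionStart + 1L)
    msg <- c(msg, "consensus longer than its position window")
  if (object@mutationProb < 0 || object@mutationProb > 1)
    msg <- c(msg, "mutationProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname MotifSpec-class
#' @param name,consensus,positionStart,positionEnd,mutationProb see slots.
#' @return a \code{MotifSpec}.
#' @export
MotifSpec <- function(name, consensus, positionStart, positionEnd,
                      mutationProb = 0.1) {
  new("MotifSpec", name = name, consensus = toupper(consensus),
      positionStart = as.integer(positionStart),
      positionEnd = as.integer(positionEnd), mutationProb = mutationProb)
}

#' Simulation configuration for synthetic promoter benchmarks
#'
#' Emulates 300 nt promoter windows anchored at a TSS (index 249 in
#' 0-based coordinates) with planted TATA-box (-30..-25), CAAT-box
#' (-80..-70) and GC-box (-110..-80) elements over a configurable
#' background composition. TSS-relative position p maps to array index
#' tssIndex + p.
#'
#' @slot seqLength window length in nt.
#' @slot tssIndex 0-based index of the TSS within the window.
#' @slot backgroundComposition named probabilities for A/C/G/T, summing to 1.
#' @slot motifs list of \code{MotifSpec}.
#' @slot promoterClass "TATA" (plants TATA/CAAT/GC) or "nonTATA" (CAAT/GC).
#' @slot seed default RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seqLength = "integer", tssIndex = "integer",
                 backgroundComposition = "numeric", motifs = "list",
                 promoterClass = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  bc <- object@backgroundComposition
  if (length(bc) != 4L || is.null(names(bc)) ||
      !setequal(names(bc), c("A", "C", "G", "T")))
    msg <- c(msg, "backgroundComposition must be named probabilities for A/C/G/T")
  else if (abs(sum(bc) - 1) > 1e-6 || any(bc < 0))
    msg <- c(msg, "backgroundComposition must be non-negative and sum to 1")
  if (object@tssIndex < 0L || object@tssIndex >= object@seqLength)
    msg <- c(msg, "tssIndex must lie inside the sequence")
  if (!object@promoterClass %in% c("TATA", "nonTATA"))
    msg <- c(msg, "promoterClass must be 'TATA' or 'nonTATA'")
  has_tata <- any(vapply(object@motifs, function(m) m@name == "TATA-box",
                         logical(1)))
  if (object@promoterClass == "TATA" && length(object@motifs) && !has_tata)
    msg <- c(msg, "TATA class requires a TATA-box motif")
  if (object@promoterClass == "nonTATA" && has_tata)
    msg <- c(msg, "nonTATA class must not include a TATA-box motif")
  for (m in object@motifs) {
    if (!is(m, "MotifSpec")) { msg <- c(msg, "motifs must be MotifSpec objects"); break }
    i0 <- object@tssIndex + m@positionStart
    if (i0 < 0L || i0 + nchar(m@consensus) - 1L >= object@seqLength)
      msg <- c(msg, sprintf("motif '%s' falls outside the sequence", m@name))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d nt window, TSS at index %d, class %s, %d motifs\n",
              object@seqLength, object@tssIndex, object@promoterClass,
              length(object@motifs)))
})

#' Evaluation report for a binary promoter classifier
#'
#' Holds the confusion counts at the chosen threshold, the six threshold
#' metrics (balanced accuracy, sensitivity, specificity, precision, F1,
#' Matthews correlation coefficient) and both curve areas with their
#' coordinate lists.
#'
#' @slot counts named integer vector tp/fp/tn/fn.
#' @slot metrics named numeric vector ba/sn/sp/pr/f1/mcc.
#' @slot aucroc,aucpr curve areas in [0, 1].
#' @slot threshold decision threshold used for the counts.
#' @slot rocPoints data.frame (threshold, fpr, tpr).
#' @slot prPoints data.frame (threshold, recall, precision).
#' @exportClass EvalReport
setClass("EvalReport",
  representation(counts = "integer", metrics = "numeric",
                 aucroc = "numeric", aucpr = "numeric",
                 threshold = "numeric", rocPoints = "data.frame",
                 prPoints = "data.frame"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!setequal(names(object@counts), c("tp", "fp", "tn", "fn")))
    msg <- c(msg, "counts must be named tp/fp/tn/fn")
  if (!setequal(names(object@metrics), c("ba", "sn", "sp", "pr", "f1", "mcc")))
    msg <- c(msg, "metrics must be named ba/sn/sp/pr/f1/mcc")
  if (length(msg)) msg else TRUE
})

#' @rdname EvalReport-class
#' @param object an \code{EvalReport}.
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(object) object@counts)

#' @rdname EvalReport-class
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname EvalReport-class
#' @export
setMethod("metrics", "EvalReport", function(object) object@metrics)

#' @rdname EvalReport-class
#' @export
setGeneric("aucroc", function(object) standardGeneric("aucroc"))

#' @rdname EvalReport-class
#' @export
setMethod("aucroc", "EvalReport", function(object) object@aucroc)

#' @rdname EvalReport-class
#' @export
setGeneric("aucpr", function(object) standardGeneric("aucpr"))

#' @rdname EvalReport-class
#' @export
setMethod("aucpr", "EvalReport", function(object) object@aucpr)

setMethod("show", "EvalReport", function(object) {
  m <- round(object@metrics, 2)
  cat(sprintf("EvalReport (threshold %.2f): tp=%d fp=%d tn=%d fn=%d\n",
              object@threshold, object@counts["tp"], object@counts["fp"],
              object@counts["tn"], object@counts["fn"]))
  cat(sprintf("  BA %.2f  SN %.2f  SP %.2f  PR %.2f  F1 %.2f  MCC %.2f\n",
              m["ba"], m["sn"], m["sp"], m["pr"], m["f1"], m["mcc"]))
  cat(sprintf("  AUCROC %.4f  AUCPR %.4f\n", object@aucroc, object@aucpr))
})
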