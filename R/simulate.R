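# Synthetic promoter benchmark generator. Promoter-like sequences are
# background draws with core-promoter elements planted at their canonical
# TSS-relative windows: TATA-box at -30..-25, CAAT-box at -80..-70 and
# GC-box at -110..-80 (left-anchored consensus, each position
# independently mutated back into the background with a configurable
# probability). Background ("non-promoter") sequences are pure
# composition draws. TSS-relative position p maps to 0-based array index
# tssIndex + p.

#' Default core-promoter motif set
#'
#' Consensus strings follow standard promoter-element descriptions:
#' TATAAA (TATA-box), GGCCAATCT (CAAT-box), GGGCGG (GC-box). The
#' coordinate windows are the canonical TSS-relative locations; each
#' consensus is left-anchored at its window start.
#'
#' @param promoterClass "TATA" includes the TATA-box; "nonTATA" omits it.
#' @param mutationProb per-position mutation probability applied to every
#'   motif (default 0.1).
#' @return list of \code{MotifSpec}.
#' @export
defaultMotifs <- function(promoterClass = c("TATA", "nonTATA"),
                          mutationProb = 0.1) {
  promoterClass <- match.arg(promoterClass)
  motifs <- list(
    MotifSpec("CAAT-box", "GGCCAATCT", -80L, -70L, mutationProb),
    MotifSpec("GC-box", "GGGCGG", -110L, -80L, mutationProb))
  if (promoterClass == "TATA")
    motifs <- c(list(MotifSpec("TATA-box", "TATAAA", -30L, -25L,
                               mutationProb)), motifs)
  motifs
}

#' Construct a simulation configuration
#'
#' @param seqLength window length (default 300).
#' @param tssIndex 0-based TSS offset within the window (default 249,
#'   i.e. a -249..+50 window).
#' @param backgroundComposition named A/C/G/T probabilities summing to 1.
#' @param motifs list of \code{MotifSpec}; defaults to
#'   \code{defaultMotifs(promoterClass, mutationProb)}.
#' @param promoterClass "TATA" or "nonTATA".
#' @param mutationProb per-position motif mutation probability used when
#'   building the default motif set.
#' @param seed default RNG seed.
#' @return a \code{SimConfig}.
#' @export
SimConfig <- function(seqLength = 300L, tssIndex = 249L,
                      backgroundComposition = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                      motifs = NULL,
                      promoterClass = c("TATA", "nonTATA"),
                      mutationProb = 0.1, seed = 1L) {
  promoterClass <- match.arg(promoterClass)
  if (is.null(motifs)) motifs <- defaultMotifs(promoterClass, mutationProb)
  new("SimConfig", seqLength = as.integer(seqLength),
      tssIndex = as.integer(tssIndex),
      backgroundComposition = backgroundComposition[c("A", "C", "G", "T")],
      motifs = motifs, promoterClass = promoterClass,
      seed = as.integer(seed))
}

BASES <- c("A", "C", "G", "T")

# n x L character matrix of background draws
.backgroundMatrix <- function(cfg, n) {
  matrix(sample(BASES, n * cfg@seqLength, replace = TRUE,
                prob = cfg@backgroundComposition),
         nrow = n, ncol = cfg@seqLength)
}

.collapseRows <- function(m, prefix) {
  seqs <- DNAStringSet(apply(m, 1, paste, collapse = ""))
  names(seqs) <- sprintf("%s_%05d", prefix, seq_len(nrow(m)))
  seqs
}

#' Generate promoter-like sequences with planted motifs
#'
#' Each sequence is a background draw whose motif windows are overwritten
#' by the motif consensus; every consensus position is then independently
#' replaced by a fresh background draw with probability
#' \code{mutationProb} (so the expected per-position consensus match rate
#' is (1 - p) + p * background probability of the consensus letter).
#'
#' @param cfg a \code{SimConfig}.
#' @param n number of sequences.
#' @param seed RNG seed (defaults to \code{cfg@seed}).
#' @param prefix id prefix.
#' @return a named \code{DNAStringSet}.
#' @export
generatePromoters <- function(cfg, n = 1L, seed = cfg@seed,
                              prefix = "promoter") {
  validObject(cfg)
  withSeed(seed, {
    m <- .backgroundMatrix(cfg, n)
    for (motif in cfg@motifs) {
      letters <- strsplit(motif@consensus, "")[[1]]
      i0 <- cfg@tssIndex + motif@positionStart   # 0-based anchor
      for (j in seq_along(letters)) {
        col <- i0 + j                            # 1-based column
        planted <- rep(letters[j], n)
        mutate <- stats::runif(n) < motif@mutationProb
        if (any(mutate))
          planted[mutate] <- sample(BASES, sum(mutate), replace = TRUE,
                                    prob = cfg@backgroundComposition)
        m[, col] <- planted
      }
    }
    .collapseRows(m, prefix)
  })
}

#' Generate background (non-promoter) sequences
#'
#' Independent draws from the background composition with no motif
#' planting.
#'
#' @inheritParams generatePromoters
#' @return a named \code{DNAStringSet}.
#' @export
generateBackground <- function(cfg, n = 1L, seed = cfg@seed,
                               prefix = "background") {
  validObject(cfg)
  withSeed(seed, .collapseRows(.backgroundMatrix(cfg, n), prefix))
}

#' Generate a full synthetic benchmark (train/validation/test)
#'
#' Mirrors the benchmark design of promoter classification studies:
#' positives are simulated promoters; the training negatives are
#' artificial non-promoters constructed from the training positives by
#' block recombination (1:1), while validation and test negatives are
#' background sequences standing in for real non-promoters. All splits
#' are balanced.
#'
#' @param cfg a \code{SimConfig}.
#' @param nPerClass sequences per class (>= 10).
#' @param fractions (train, validation, test) fractions summing to 1.
#' @param seed master seed; sub-seeds for simulation and negative
#'   construction are derived deterministically from it.
#' @param negConfig a \code{NegativeConfig} for the training negatives.
#' @return named list of three \code{LabelledDataset}s.
#' @export
generateBenchmark <- function(cfg, nPerClass, fractions = c(train = 0.8,
                                                            validation = 0.1,
                                                            test = 0.1),
                              seed = cfg@seed,
                              negConfig = NegativeConfig()) {
  if (nPerClass < 10L) stop("nPerClass must be at least 10")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive values summing to 1")
  pos <- generatePromoters(cfg, nPerClass, seed = mixSeed(seed, 1L))
  cuts <- round(cumsum(c(0, fractions)) * nPerClass)
  idx <- withSeed(mixSeed(seed, 2L), sample(nPerClass))
  posSplit <- split(idx, factor(rep(VALID_SPLIT_TAGS, diff(cuts)),
                                levels = VALID_SPLIT_TAGS))
  counts <- vapply(posSplit, length, integer(1))
  if (any(counts == 0L)) stop("a split received no sequences; increase nPerClass")

  trainPos <- pos[sort(posSplit$train)]
  trainNeg <- sequences(buildTrainingNegatives(trainPos, negConfig,
                                               seed = mixSeed(seed, 3L)))
  valPos <- pos[sort(posSplit$validation)]
  testPos <- pos[sort(posSplit$test)]
  valNeg <- generateBackground(cfg, counts[["validation"]],
                               seed = mixSeed(seed, 4L),
                               prefix = "background_val")
  testNeg <- generateBackground(cfg, counts[["test"]],
                                seed = mixSeed(seed, 5L),
                                prefix = "background_test")
  mk <- function(p, n, tag) {
    new("LabelledDataset", sequences = c(p, n),
        labels = c(rep(1L, length(p)), rep(0L, length(n))), splitTag = tag)
  }
  list(train = mk(trainPos, trainNeg, "train"),
       validation = mk(valPos, valNeg, "validation"),
       test = mk(testPos, testNeg, "test"))
}
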