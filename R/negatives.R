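# Construction of artificial ("fake") non-promoter training sequences.
# Each 300 nt promoter is split into 20 blocks of 15 nt; 8 blocks are
# selected uniformly at random and refilled into the vacated positions by
# a uniform permutation, while the remaining 12 "conservative" blocks stay
# in place. The recombinant keeps the source's block multiset (hence its
# exact mononucleotide composition) but scrambles long-range structure, so
# a classifier trained against such negatives cannot rely on motif
# presence alone.

#' Split a sequence into fixed-size blocks
#'
#' @param seq a single sequence (character or \code{DNAString}).
#' @param blockSize block length in nt; must divide the sequence length.
#' @return character vector of blocks whose concatenation reproduces
#'   \code{seq}.
#' @export
splitBlocks <- function(seq, blockSize) {
  s <- toupper(if (is.character(seq)) seq else as.character(seq))
  if (length(s) != 1L) stop("splitBlocks expects a single sequence")
  n <- nchar(s)
  if (n %% blockSize != 0L)
    stop(sprintf("sequence length %d is not divisible by block size %d (remainder %d)",
                 n, blockSize, n %% blockSize))
  starts <- seq(1L, n, by = blockSize)
  substring(s, starts, starts + blockSize - 1L)
}

#' Construct one artificial non-promoter from a promoter template
#'
#' Selects \code{nSubstitutional} block indices uniformly without
#' replacement, then draws a uniform permutation of the selected blocks
#' over the vacated positions (fixed points allowed). When
#' \code{forbidIdentity} is set and the recombinant equals the source,
#' the permutation is redrawn up to \code{maxResample} times; if every
#' redraw reproduces the source (e.g. all selected blocks are identical)
#' construction fails. Deterministic given \code{(seq, config, seed)}.
#'
#' @param seq the template promoter (character or \code{DNAString});
#'   length must equal \code{blockSize * nBlocks}.
#' @param config a \code{NegativeConfig}.
#' @param seed RNG seed for this construction.
#' @param id identifier of the template (defaults to \code{names(seq)}).
#' @return an \code{ArtificialNegative} carrying the recombined sequence
#'   and its full construction trace.
#' @export
constructNegative <- function(seq, config = NegativeConfig(), seed = 1L,
                              id = NULL) {
  s <- toupper(if (is.character(seq)) seq else as.character(seq))
  if (is.null(id)) id <- if (!is.null(names(s))) names(s) else "unnamed"
  s <- unname(s)
  if (nchar(s) != config@blockSize * config@nBlocks)
    stop(sprintf("sequence '%s' has length %d; expected blockSize * nBlocks = %d",
                 id, nchar(s), config@blockSize * config@nBlocks))
  blocks <- splitBlocks(s, config@blockSize)
  k <- config@nSubstitutional
  if (k == 0L) {
    return(new("ArtificialNegative", residues = s, sourceId = id,
               selectedBlocks = integer(0), permutation = integer(0),
               seed = as.integer(seed)))
  }
  res <- withSeed(seed, {
    sel <- sort(sample.int(config@nBlocks, k))
    perm <- NULL
    for (try in seq_len(config@maxResample)) {
      p <- sel[sample.int(k)]
      if (!config@forbidIdentity || any(blocks[p] != blocks[sel])) {
        perm <- p
        break
      }
    }
    list(sel = sel, perm = perm)
  })
  if (is.null(res$perm))
    stop(sprintf("could not construct a non-identical negative for '%s' after %d resamples",
                 id, config@maxResample))
  newBlocks <- blocks
  newBlocks[res$sel] <- blocks[res$perm]
  new("ArtificialNegative",
      residues = paste(newBlocks, collapse = ""), sourceId = id,
      selectedBlocks = as.integer(res$sel - 1L),
      permutation = as.integer(res$perm - 1L), seed = as.integer(seed))
}

#' Build one artificial negative per promoter
#'
#' Per-sequence seeds are derived from the master seed by one
#' multiplicative-congruential step offset by the sequence ordinal
#' (seed_i = (master * 48271 + i) mod 2^31 - 1), so any subset of a
#' corpus reproduces independently of the rest.
#'
#' @param promoters a named \code{DNAStringSet} (or character vector) of
#'   template promoters.
#' @param config a \code{NegativeConfig}.
#' @param seed master seed.
#' @return an \code{ArtificialNegativeSet} with one negative per
#'   promoter, in input order (ids suffixed \code{"_fake"}).
#' @export
buildTrainingNegatives <- function(promoters, config = NegativeConfig(),
                                   seed = 1L) {
  chars <- if (is.character(promoters)) promoters else as.character(promoters)
  n <- length(chars)
  if (!n) {
    return(new("ArtificialNegativeSet", sequences = DNAStringSet(),
               trace = data.frame(source_id = character(0),
                                  selected_blocks = character(0),
                                  permutation = character(0),
                                  seed = integer(0))))
  }
  ids <- names(chars)
  if (is.null(ids)) ids <- sprintf("seq_%05d", seq_len(n))
  negs <- vector("list", n)
  for (i in seq_len(n)) {
    negs[[i]] <- constructNegative(chars[[i]], config,
                                   seed = mixSeed(seed, i), id = ids[i])
  }
  seqs <- DNAStringSet(vapply(negs, function(x) x@residues, character(1)))
  names(seqs) <- paste0(ids, "_fake")
  trace <- data.frame(
    source_id = ids,
    selected_blocks = vapply(negs, function(x)
      paste(x@selectedBlocks, collapse = ","), character(1)),
    permutation = vapply(negs, function(x)
      paste(x@permutation, collapse = ","), character(1)),
    seed = vapply(negs, function(x) x@seed, integer(1)),
    stringsAsFactors = FALSE)
  new("ArtificialNegativeSet", sequences = seqs, trace = trace)
}

#' Mono- and trinucleotide composition of a template/negative pair
#'
#' Diagnostic for the motif-preservation rationale of block-shuffled
#' negatives: mononucleotide counts are always identical (blocks are
#' permuted, never rewritten), and trinucleotide counts can differ only
#' in windows spanning block junctions.
#'
#' @param seq the template promoter.
#' @param negative the \code{ArtificialNegative} built from it.
#' @param id template id for pairing validation.
#' @return a data.frame with columns kmer, k, source_count,
#'   negative_count.
#' @export
compositionReport <- function(seq, negative, id = NULL) {
  s <- toupper(if (is.character(seq)) seq else as.character(seq))
  if (is.null(id)) id <- if (!is.null(names(s))) names(s) else negative@sourceId
  s <- unname(s)
  if (!identical(id, negative@sourceId))
    stop(sprintf("pairing error: negative was built from '%s', not '%s'",
                 negative@sourceId, id))
  if (nchar(s) != nchar(negative@residues))
    stop("pairing error: sequence lengths differ")
  counts <- function(x, k) {
    v <- Biostrings::oligonucleotideFrequency(DNAStringSet(x), width = k)[1, ]
    data.frame(kmer = names(v), k = k, count = as.integer(v),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    merge(counts(s, 1), counts(negative@residues, 1), by = c("kmer", "k")),
    merge(counts(s, 3), counts(negative@residues, 3), by = c("kmer", "k")))
  names(out)[3:4] <- c("source_count", "negative_count")
  out[order(out$k, out$kmer), , drop = FALSE]
}
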