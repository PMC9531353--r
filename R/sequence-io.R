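# FASTA reading/writing and TSS-window extraction for fixed-length
# promoter datasets. Parsing and serialisation are delegated to
# Biostrings; this layer adds the validation contracts (alphabet,
# fixed length, N policy) that the downstream encoder relies on.

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and validated against the alphabet
#' \{A,C,G,T,N\}. With \code{expectedLength}, records of any other length
#' are dropped and reported via \code{message()}; with
#' \code{nPolicy = "reject"}, records containing N are likewise dropped.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param expectedLength if given, only sequences of exactly this length
#'   are returned; others are dropped and counted.
#' @param nPolicy \code{"reject"} drops N-containing sequences (the
#'   default, appropriate for training data); \code{"keep"} retains them
#'   (N-containing triplets later map to the unknown index).
#' @return a named \code{DNAStringSet} in file order.
#' @export
readFasta <- function(path, expectedLength = NULL,
                      nPolicy = c("reject", "keep")) {
  nPolicy <- match.arg(nPolicy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA input: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: sequence data before first header at line %d",
                 first))
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("empty FASTA input: ", path)
  chars <- toupper(as.character(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop(sprintf("invalid characters outside {A,C,G,T,N} in record(s): %s",
                 paste(head(ids[bad], 5), collapse = ", ")))
  keep <- rep(TRUE, length(chars))
  if (!is.null(expectedLength)) {
    wrong <- nchar(chars) != expectedLength
    if (any(wrong)) {
      message(sprintf("readFasta: dropped %d record(s) not of length %d",
                      sum(wrong), expectedLength))
      keep <- keep & !wrong
    }
  }
  if (nPolicy == "reject") {
    hasN <- grepl("N", chars, fixed = TRUE)
    if (any(hasN & keep)) {
      message(sprintf("readFasta: dropped %d record(s) containing N",
                      sum(hasN & keep)))
      keep <- keep & !hasN
    }
  }
  out <- DNAStringSet(chars[keep])
  names(out) <- ids[keep]
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @param lineWidth sequence line width (default 60).
#' @return (invisibly) the number of records written.
#' @export
writeFasta <- function(seqs, path, lineWidth = 60) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (length(seqs) && any(Biostrings::width(seqs) == 0L))
    stop("cannot write empty sequences")
  if (!length(seqs)) {
    file.create(path)
  } else {
    Biostrings::writeXStringSet(seqs, filepath = path, width = lineWidth)
  }
  invisible(length(seqs))
}

#' Extract a fixed TSS-anchored window from a longer sequence
#'
#' Coordinates are 0-based; the window spans
#' \code{[tssPosition - upstream, tssPosition + downstream]} and has
#' length \code{upstream + downstream + 1} (300 for the defaults, with
#' the TSS at index 249 of the window).
#'
#' @param source a single sequence (character, \code{DNAString}, or
#'   length-1 \code{DNAStringSet}).
#' @param tssPosition 0-based TSS position within \code{source}.
#' @param upstream,downstream number of bases kept on each side of the TSS.
#' @return a length-1 \code{DNAStringSet} whose \code{mcols()$tssIndex}
#'   records the TSS offset within the window (= \code{upstream}).
#' @export
extractWindow <- function(source, tssPosition, upstream = 249,
                          downstream = 50) {
  if (upstream < 0 || downstream < 0)
    stop("upstream and downstream must be non-negative")
  s <- if (is.character(source)) source else as.character(source)
  if (length(s) != 1L) stop("extractWindow expects a single sequence")
  id <- names(s)
  n <- nchar(s)
  start0 <- tssPosition - upstream
  end0 <- tssPosition + downstream
  if (start0 < 0 || end0 > n - 1) {
    over <- max(0 - start0, end0 - (n - 1))
    stop(sprintf("window [%d, %d] out of bounds for sequence of length %d (overhang %d)",
                 start0, end0, n, over))
  }
  win <- substr(toupper(s), start0 + 1L, end0 + 1L)
  out <- DNAStringSet(win)
  names(out) <- if (is.null(id)) "window" else id
  S4Vectors::mcols(out)$tssIndex <- as.integer(upstream)
  out
}

#' Read or write a dataset manifest (id, label, split)
#'
#' Manifests are tab-separated with columns \code{id}, \code{label}
#' (0/1) and \code{split} (train/validation/test).
#'
#' @param path manifest path.
#' @return \code{readManifest}: a data.frame.
#' @export
readManifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "label", "split")
  if (!all(need %in% names(df)))
    stop("manifest must have columns id, label, split")
  df$label <- as.integer(df$label)
  df
}

#' @rdname readManifest
#' @param manifest a data.frame with columns id, label, split.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest[, c("id", "label", "split")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a LabelledDataset pair of files into an object and back
#'
#' Convenience wrappers joining a FASTA file with a manifest.
#'
#' @param dataset a \code{LabelledDataset}.
#' @param fastaPath,manifestPath output paths.
#' @return (invisibly) the dataset.
#' @export
writeDataset <- function(dataset, fastaPath, manifestPath) {
  writeFasta(sequences(dataset), fastaPath)
  writeManifest(data.frame(id = names(sequences(dataset)),
                           label = labels(dataset),
                           split = splitTag(dataset)), manifestPath)
  invisible(dataset)
}
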