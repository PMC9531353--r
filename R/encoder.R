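# Overlapping-triplet index encoding. A width-3 window slides along the
# sequence with step 1, so a 300 nt sequence yields 298 indices. The 64
# A/C/G/T triplets are numbered 1..64 in lexicographic order (AAA = 1,
# TTT = 64); index 0 is reserved for triplets containing N and for
# right-padding in batch matrices.

UNKNOWN_INDEX <- 0L

#' The canonical triplet index table
#'
#' @return a named integer vector mapping the 64 triplets (lexicographic
#'   over A < C < G < T) to indices 1..64, with attribute
#'   \code{unknownIndex = 0} reserved for N-containing triplets and padding.
#' @export
tripletIndexTable <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  tab <- seq_len(64L)
  names(tab) <- paste0(grid$b1, grid$b2, grid$b3)
  attr(tab, "unknownIndex") <- UNKNOWN_INDEX
  tab
}

#' Export the triplet index table as a two-column TSV for audit
#'
#' @param path output path.
#' @return (invisibly) the path.
#' @export
exportIndexTable <- function(path) {
  tab <- tripletIndexTable()
  utils::write.table(data.frame(triplet = names(tab), index = unname(tab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# base -> 0..3 codes; N and anything else -> NA
.baseCodes <- function(s) {
  v <- utf8ToInt(s)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L  # A
  code[v == 67L] <- 1L  # C
  code[v == 71L] <- 2L  # G
  code[v == 84L] <- 3L  # T
  code
}

#' Encode one sequence as overlapping-triplet indices
#'
#' @param seq a single sequence (character or \code{DNAString}), length
#'   at least 3.
#' @param table the index table (defaults to \code{tripletIndexTable()};
#'   only its unknown-index attribute and 1..64 lexicographic contract
#'   are assumed).
#' @return integer vector of length \code{nchar(seq) - 2}, values in
#'   [0, 64]; 0 marks windows containing N.
#' @export
encodeTriplets <- function(seq, table = tripletIndexTable()) {
  s <- toupper(if (is.character(seq)) seq else as.character(seq))
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than 3 nt cannot be encoded")
  code <- .baseCodes(s)
  if (any(is.na(code) & !strsplit(s, "")[[1]] %in% "N"))
    stop("sequence contains characters outside {A,C,G,T,N}")
  idx <- 16L * code[1:(n - 2L)] + 4L * code[2:(n - 1L)] + code[3:n] + 1L
  idx[is.na(idx)] <- attr(table, "unknownIndex")
  idx
}

#' Decode a triplet index vector back to its source sequence
#'
#' Valid only for vectors without the unknown index and with consistent
#' overlaps (the last two letters of triplet i must equal the first two
#' of triplet i+1).
#'
#' @param vec integer vector of indices in 1..64.
#' @param table the index table.
#' @return the unique source sequence, of length \code{length(vec) + 2}.
#' @export
decodeTriplets <- function(vec, table = tripletIndexTable()) {
  if (!length(vec)) stop("cannot decode an empty index vector")
  if (any(vec == attr(table, "unknownIndex")))
    stop("index vector contains the unknown index; decoding is undefined")
  if (any(vec < 1L | vec > 64L)) stop("indices must lie in [1, 64]")
  trips <- names(table)[vec]
  if (length(trips) > 1L) {
    ok <- substr(trips[-length(trips)], 2, 3) == substr(trips[-1], 1, 2)
    if (!all(ok))
      stop(sprintf("inconsistent overlap between triplets %d and %d",
                   which(!ok)[1], which(!ok)[1] + 1L))
  }
  paste0(trips[1], paste(substr(trips[-1], 3, 3), collapse = ""))
}

#' Encode a batch of sequences into an index matrix
#'
#' @param seqs a \code{DNAStringSet} or character vector.
#' @param table the index table.
#' @param padTo row width; rows shorter than this are right-padded with
#'   the unknown index. Defaults to the longest encoding in the batch.
#' @return an n x padTo integer matrix (rownames = sequence ids). For
#'   uniform 300 nt input and \code{padTo = 298} there is no padding.
#' @export
encodeBatch <- function(seqs, table = tripletIndexTable(), padTo = NULL) {
  chars <- if (is.character(seqs)) seqs else as.character(seqs)
  n <- length(chars)
  if (!n) {
    return(matrix(integer(0), nrow = 0,
                  ncol = if (is.null(padTo)) 0 else padTo))
  }
  lens <- nchar(chars) - 2L
  if (any(lens < 1L)) stop("all sequences must be at least 3 nt")
  if (is.null(padTo)) padTo <- max(lens)
  if (any(lens > padTo))
    stop(sprintf("sequence encoding of length %d exceeds padTo = %d",
                 max(lens), padTo))
  out <- matrix(attr(table, "unknownIndex"), nrow = n, ncol = padTo)
  for (i in seq_len(n)) {
    v <- encodeTriplets(chars[i], table)
    out[i, seq_along(v)] <- v
  }
  rownames(out) <- names(chars)
  out
}
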