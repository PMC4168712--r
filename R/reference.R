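#' Reference sequence set
#'
#' Bundle one or more nucleotide sequences into the container the indexer
#' consumes. Sequences are upper-cased; any character outside A/C/G/T is
#' treated as N (an unmatchable sentinel) by the index.
#'
#' @param sequences character vector of nucleotide sequences.
#' @param names sequence identifiers; defaults to `seq1`, `seq2`, ...
#' @return An object of class `reference_set`: a list with `names`,
#'   `sequences`, `starts0` (0-based start of each sequence in the
#'   concatenated forward genome), `seqlen` and `G` (total forward length).
#' @examples
#' ref <- reference_set(c("GATTACA", "AACGTT"), c("chrA", "chrB"))
#' ref$G
#' @export
reference_set <- function(sequences, names = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0 || any(!nzchar(sequences)))
    stop("reference must contain at least one non-empty sequence")
  if (is.null(names)) {
    nm <- base::names(sequences)
    names <- if (!is.null(nm) && all(nzchar(nm))) nm
             else paste0("seq", seq_along(sequences))
  }
  if (length(names) != length(sequences))
    stop("names and sequences differ in length")
  if (anyDuplicated(names)) stop("duplicate sequence names")
  seqlen <- nchar(sequences)
  starts0 <- cumsum(c(0L, seqlen[-length(seqlen)]))
  structure(
    list(names = as.character(names), sequences = unname(sequences),
         starts0 = as.integer(starts0), seqlen = as.integer(seqlen),
         G = sum(as.numeric(seqlen))),
    class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$names), "sequence(s),",
      format(x$G, big.mark = ","), "bp total\n")
  n <- min(length(x$names), 6L)
  for (i in seq_len(n))
    cat(" ", x$names[i], ":", format(x$seqlen[i], big.mark = ","), "bp\n")
  if (length(x$names) > n) cat("  ...\n")
  invisible(x)
}

#' Read a reference from FASTA
#'
#' Multi-record, wrapped-line, case-insensitive FASTA (plain or gzip).
#'
#' @param path FASTA file path.
#' @return A [reference_set()].
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  reference_set(as.character(ss), nm)
}

#' Write a reference to FASTA
#'
#' @param ref a [reference_set()].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "reference_set"))
  ss <- Biostrings::DNAStringSet(ref$sequences)
  names(ss) <- ref$names
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences (A/C/G/T/N; case-insensitive).
#' @return character vector of reverse complements (upper case).
#' @examples
#' revcomp("GATTACA")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANTGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
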