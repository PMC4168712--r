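#' Build the FM-index over a reference and its reverse complement
#'
#' The forward sequences are concatenated, their reverse complement is
#' appended, a terminator is added, and BWT, first-occurrence table,
#' checkpointed occurrence counts and the full suffix array are built over
#' the doubled text. Searching this index therefore covers both strands;
#' reverse-half hits are folded back to forward coordinates with a strand
#' flag at locate time. N bases become a sentinel symbol no query can
#' match, so no exact seed spans an N.
#'
#' @param ref a [reference_set()] or character vector of sequences.
#' @return An object of class `fm_index`.
#' @examples
#' idx <- build_fm_index(reference_set("GATTACA"))
#' idx
#' @export
build_fm_index <- function(ref) {
  if (!inherits(ref, "reference_set")) ref <- reference_set(ref)
  core <- cpp_fm_build(ref$sequences)
  idx <- c(core,
           list(names = ref$names, starts0 = ref$starts0,
                seqlen = ref$seqlen, version = 1L))
  class(idx) <- "fm_index"
  idx
}

#' @export
print.fm_index <- function(x, ...) {
  cat("fm_index over", length(x$names), "sequence(s):",
      format(x$G, big.mark = ","), "bp forward,",
      format(2 * x$G, big.mark = ","), "bp indexed (both strands)\n")
  invisible(x)
}

#' Right-to-left exact suffix search
#'
#' Extends an exact match leftward from read position `right`, one base per
#' step, until the suffix-array interval would become empty or `max_len`
#' bases have matched. The interval rows of the last non-empty state are
#' returned; its width is the occurrence count of the matched substring in
#' the doubled (two-strand) text.
#'
#' @param index an `fm_index`.
#' @param read read sequence (character scalar).
#' @param right 1-based read position of the rightmost base to match.
#' @param max_len maximum bases to match; `Inf` for unbounded.
#' @return list with `begin`, `end` (1-based inclusive BWT rows), `width`
#'   and `matched`. With `matched = 0` the interval spans every BWT row.
#' @export
match_right_to_left <- function(index, read, right, max_len = Inf) {
  stopifnot(inherits(index, "fm_index"))
  ml <- if (is.infinite(max_len)) -1 else as.double(max_len)
  r <- cpp_match_rl(unclass(index), toupper(read), as.integer(right) - 1L, ml)
  list(begin = r$begin + 1, end = r$end + 1, width = r$width,
       matched = r$matched)
}

#' Left-to-right exact extension length
#'
#' How far the substring starting at `start` extends rightward while
#' keeping at least one exact match, computed by backward search on the
#' reverse complement (the indexed text is closed under reverse
#' complement). Returns the length only.
#'
#' @inheritParams match_right_to_left
#' @param start 1-based read position of the leftmost base to match.
#' @return integer matched length.
#' @export
match_left_to_right <- function(index, read, start, max_len = Inf) {
  stopifnot(inherits(index, "fm_index"))
  ml <- if (is.infinite(max_len)) -1 else as.double(max_len)
  cpp_match_lr(unclass(index), toupper(read), as.integer(start) - 1L, ml)
}

#' Resolve a BWT row to a genomic position
#'
#' Maps a suffix-array row of a match of length `match_len` to (sequence,
#' 1-based forward leftmost coordinate, strand). Hits spanning the junction
#' between concatenated sequences or between the forward and reverse halves
#' are rejected (`NULL`): they do not correspond to a real genomic locus.
#'
#' @param index an `fm_index`.
#' @param row 1-based BWT row (e.g. from [match_right_to_left()]).
#' @param match_len length of the matched substring; must be >= 1.
#' @return list with `seqname`, `pos` (1-based), `strand`; or `NULL` for a
#'   junction-spanning hit.
#' @export
bwt_position <- function(index, row, match_len) {
  stopifnot(inherits(index, "fm_index"))
  r <- cpp_locate(unclass(index), as.double(row) - 1, as.integer(match_len))
  if (is.null(r)) return(NULL)
  list(seqname = index$names[r$seqid], pos = r$pos0 + 1, strand = r$strand)
}

#' Persist an FM-index to disk
#'
#' Writes a two-file format under `prefix`: `<prefix>.tgx.json`, a
#' versioned JSON header with sequence names, lengths and component sizes,
#' and `<prefix>.tgx`, the binary payload (text codes, BWT, suffix array,
#' first-occurrence table, occurrence checkpoints) in little-endian order.
#' This lets `index` and `align` run as separate steps.
#'
#' @param index an `fm_index`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
save_fm_index <- function(index, prefix) {
  stopifnot(inherits(index, "fm_index"))
  header <- list(format = "tagalign-index", version = index$version,
                 G = index$G, names = index$names,
                 seqlen = index$seqlen, starts0 = index$starts0,
                 n = length(index$text), n_occ = length(index$occ))
  jsonlite::write_json(header, paste0(prefix, ".tgx.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".tgx"), "wb")
  on.exit(close(con))
  writeBin(index$text, con)
  writeBin(index$bwt, con)
  writeBin(index$sa, con, size = 4L, endian = "little")
  writeBin(as.integer(index$C), con, size = 4L, endian = "little")
  writeBin(index$occ, con, size = 4L, endian = "little")
  invisible(prefix)
}

#' Load an FM-index written by [save_fm_index()]
#'
#' @param prefix path prefix used when saving.
#' @return An `fm_index`.
#' @export
load_fm_index <- function(prefix) {
  hpath <- paste0(prefix, ".tgx.json")
  if (!file.exists(hpath)) stop("no index header at ", hpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, "tagalign-index"))
    stop("not a tagalign index: ", hpath)
  if (h$version != 1) stop("unsupported index version ", h$version)
  n <- as.integer(h$n)
  con <- file(paste0(prefix, ".tgx"), "rb")
  on.exit(close(con))
  idx <- list(
    text = readBin(con, "raw", n),
    bwt = readBin(con, "raw", n),
    sa = readBin(con, "integer", n, size = 4L, endian = "little"),
    C = readBin(con, "integer", 8L, size = 4L, endian = "little"),
    occ = readBin(con, "integer", as.integer(h$n_occ), size = 4L,
                  endian = "little"),
    G = as.numeric(h$G), names = as.character(h$names),
    starts0 = as.integer(h$starts0), seqlen = as.integer(h$seqlen),
    version = as.integer(h$version))
  class(idx) <- "fm_index"
  idx
}
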