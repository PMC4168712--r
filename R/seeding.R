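#' Default minimum-seed-length schedule
#'
#' The minimum seed length k grows with read length: short seeds on short
#' reads keep sensitivity, longer seeds on long reads avoid floods of
#' uninformative repeat matches. The default is k = 16 for reads shorter
#' than 50 bp, then 20 / 24 / 28 from 50 / 200 / 500 bp.
#'
#' @return data.frame with columns `min_read_length` (ascending) and `k`.
#' @export
default_seed_schedule <- function() {
  data.frame(min_read_length = c(0L, 50L, 200L, 500L),
             k = c(16L, 20L, 24L, 28L))
}

#' Dynamic minimum seed length
#'
#' @param read_length read length in bp.
#' @param schedule a schedule data.frame as from [default_seed_schedule()].
#' @return integer k for that read length.
#' @examples
#' dynamic_seed_length(40) # 16
#' dynamic_seed_length(200) # 24
#' @export
dynamic_seed_length <- function(read_length, schedule = default_seed_schedule()) {
  stopifnot(read_length >= 1, nrow(schedule) >= 1,
            !is.unsorted(schedule$min_read_length))
  as.integer(schedule$k[max(which(read_length >= schedule$min_read_length))])
}

#' Greedy extraction of maximal seeds
#'
#' Walks the read right to left. Each iteration probes the rightmost
#' uncovered k-window left-to-right; if the whole window matches somewhere
#' exactly, the seed is extended leftward as far as any exact match
#' survives and every located occurrence is emitted (at most `P` per seed;
#' junction-spanning rows are discarded without counting against `P`).
#' If the window fails at j < k matched bases, the unmatched right tail is
#' skipped, since any seed containing it must fail too. Consecutive seeds
#' overlap by at most k - 1 bases.
#'
#' The returned hits are the score grants: each row carries the seed
#' length (the score) and `est_start`, the estimated 1-based read start
#' position used for tag assignment.
#'
#' @param index an `fm_index`.
#' @param read read sequence (character scalar).
#' @param k minimum seed length; default from [dynamic_seed_length()].
#'   Reads shorter than k get a single attempt with k = read length.
#' @param P per-seed cap on located occurrences (ascending BWT-row order).
#' @return data.frame with one row per located hit: `read_offset` (1-based
#'   leftmost base in the read as given), `length`, `seqname`, `pos`
#'   (1-based forward leftmost base), `strand`, `read_offset_aligned`
#'   (1-based offset in aligned orientation, i.e. in the
#'   reverse-complemented read for '-' hits) and `est_start` (1-based).
#' @export
extract_seeds <- function(index, read, k = NULL, P = 50L) {
  stopifnot(inherits(index, "fm_index"), P >= 1)
  read <- toupper(read)
  if (is.null(k)) k <- dynamic_seed_length(nchar(read))
  df <- cpp_extract_seeds(unclass(index), read, as.integer(k), as.integer(P))
  data.frame(
    read_offset = df$read_offset0 + 1L,
    length = df$length,
    seqname = index$names[df$seqid],
    pos = df$gpos0 - index$starts0[df$seqid] + 1,
    strand = df$strand,
    read_offset_aligned = df$read_offset_aligned0 + 1L,
    est_start = df$est_start0 + 1,
    gpos0 = df$gpos0,
    stringsAsFactors = FALSE)
}
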