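#' Greedy anchor chain selection
#'
#' From one tag record's seeds, pick a consistent, non-overlapping subset
#' to fix as exact blocks before gap alignment. Seeds are considered by
#' descending length (ties: leftmost read position, then leftmost genome
#' position); a seed is accepted iff it is collinear with and disjoint
#' from every accepted seed in both coordinates and its diagonal offset
#' (genome pos - read pos) differs by less than `d` from its adjacent
#' accepted neighbors in read order.
#'
#' @param seeds data.frame with columns `read_pos` (1-based,
#'   aligned-orientation), `genome_pos` (1-based) and `length`.
#' @param d band half-width used downstream; offsets of adjacent anchors
#'   must differ by < d.
#' @return the accepted rows of `seeds`, ordered by read position.
#' @export
select_anchor_chain <- function(seeds, d = 21L) {
  stopifnot(nrow(seeds) >= 1, d >= 1)
  keep <- cpp_anchor_chain(as.integer(seeds$read_pos) - 1L,
                           as.double(seeds$genome_pos) - 1,
                           as.integer(seeds$length), as.integer(d))
  out <- seeds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Banded gap alignment in offset coordinates
#'
#' Minimal unit-cost edit path (mismatch = indel = 1) between a read gap
#' and a reference gap, computed on a band |offset| < d where offset is
#' the reference-position-minus-read-position difference; cell (i, offset)
#' compares read base i with reference base i + offset. Runs in O(d n).
#'
#' Modes: `"global"` anchors both ends (requires the length difference to
#' be < d); `"free_ref_end"` leaves trailing reference unpenalized (used
#' for the right flank of a candidate window); `"free_ref_start"` is the
#' mirror (left flank).
#'
#' @param ref_gap reference segment (character scalar).
#' @param read_gap read segment (character scalar).
#' @param d band half-width (>= 1).
#' @param mode `"global"`, `"free_ref_start"` or `"free_ref_end"`.
#' @return list with `feasible`; when feasible also `distance`,
#'   `ref_consumed` (reference bases covered by the path) and `ops`
#'   (character scalar over M/I/D, one per op).
#' @examples
#' banded_gap_align("ACGT", "AGT", d = 3)$distance # 1
#' @export
banded_gap_align <- function(ref_gap, read_gap, d = 21L,
                             mode = c("global", "free_ref_start",
                                      "free_ref_end")) {
  mode <- match.arg(mode)
  m <- c(global = 0L, free_ref_start = 1L, free_ref_end = 2L)[[mode]]
  cpp_band_align(toupper(ref_gap), toupper(read_gap), as.integer(d), m)
}

#' Align a read to one candidate tag region
#'
#' Builds the greedy anchor chain from the tag's seeds, extends the
#' spanned reference window by `e` bp on each side, aligns interior gaps
#' globally and the two flanks with the unused window end free, and
#' assembles the CIGAR. Anchors contribute zero-cost M runs. An
#' infeasible band is retried once with the half-width doubled, after
#' which the candidate is dropped (`feasible = FALSE`).
#'
#' @param index an `fm_index`.
#' @param read the read as given (character scalar). For `strand = "-"`
#'   it is reverse-complemented internally; seed offsets must already be
#'   aligned-orientation (as stored by the tag table).
#' @param seeds data.frame with `read_pos`, `genome_pos` (1-based global
#'   forward coordinates), `length`.
#' @param strand `"+"` or `"-"`.
#' @param tag_score total seed score of the tag (used for ranking).
#' @param tag_id 0-based tag id.
#' @param e flank extension in bp.
#' @param d band half-width.
#' @return list with `feasible`; when feasible also `seqname`, `pos`
#'   (1-based leftmost forward coordinate), `strand`, `cigar`, `edit`,
#'   `tag_score`, `tag_id`.
#' @export
align_to_candidate <- function(index, read, seeds, strand = "+",
                               tag_score = sum(seeds$length), tag_id = 0,
                               e = 20L, d = 21L) {
  stopifnot(inherits(index, "fm_index"), nrow(seeds) >= 1,
            strand %in% c("+", "-"))
  read <- toupper(read)
  aligned <- if (strand == "-") revcomp(read) else read
  r <- cpp_align_to_candidate(
    unclass(index), aligned,
    as.integer(seeds$read_pos) - 1L, as.double(seeds$genome_pos) - 1,
    as.integer(seeds$length), as.double(tag_score), as.double(tag_id),
    if (strand == "+") 0L else 1L, as.integer(e), as.integer(d))
  if (!isTRUE(r$feasible)) return(list(feasible = FALSE))
  r$seqname <- index$names[r$seqid]
  r$seqid <- NULL
  r
}

#' Rank candidate alignments
#'
#' Best candidate = minimal edit distance; ties broken by higher tag
#' score, then lowest coordinate, then `"+"` strand. The runner-up is the
#' best-ranked candidate from a different tag (used for mapping quality).
#'
#' @param results data.frame with columns `edit`, `tag_score`, `pos`,
#'   `strand`, `tag_id` (and optionally `seqname`).
#' @return list with `best` (row index), `runner_up` (row index or `NA`),
#'   and `order` (the full ranking permutation); or `NULL` for an empty
#'   input (the read is unaligned).
#' @export
rank_candidates <- function(results) {
  if (is.null(results) || nrow(results) == 0) return(NULL)
  sq <- if ("seqname" %in% names(results)) xtfrm(results$seqname)
        else rep(0L, nrow(results))
  o <- order(results$edit, -results$tag_score, sq, results$pos,
             results$strand != "+")
  best <- o[1]
  ru <- NA_integer_
  for (i in o[-1]) {
    if (results$tag_id[i] != results$tag_id[best] ||
        results$strand[i] != results$strand[best]) { ru <- i; break }
  }
  list(best = best, runner_up = ru, order = o)
}

#' Mapping quality from the best-vs-runner-up score gap
#'
#' With alignment score s = read length - edit distance, MAPQ is 60 when
#' no runner-up from another tag exists, 0 when the scores tie, and
#' `floor(60 * (s_best - s_runner) / max(s_best, 1))` otherwise, capped
#' at 60.
#'
#' @param read_length read length in bp.
#' @param best_edit edit distance of the best candidate.
#' @param runner_edit edit distance of the runner-up, or `NULL`/`NA` when
#'   there is none.
#' @return integer MAPQ in 0..60.
#' @examples
#' compute_mapq(100, 2, 12) # 6
#' @export
compute_mapq <- function(read_length, best_edit, runner_edit = NULL) {
  if (is.null(runner_edit) || is.na(runner_edit)) return(60L)
  sb <- read_length - best_edit
  sr <- read_length - runner_edit
  if (sb <= sr) return(0L)
  as.integer(min(60, floor(60 * (sb - sr) / max(sb, 1))))
}
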