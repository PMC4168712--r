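#' Score alignments against simulation truth
#'
#' A read counts as correctly placed iff it is aligned, on the true
#' sequence and strand, and its reported leftmost coordinate is within
#' `tolerance` bp of the true leftmost coordinate. Recall is correct
#' reads over all reads; precision is correct reads over aligned reads.
#' The default 20 bp tolerance matches the candidate-window flank: indels
#' inside a read shift the reported leftmost coordinate by at most the
#' bracketed indel budget.
#'
#' @param sam a `sam_records` data.frame (from [align_reads()],
#'   [align_read_pairs()] or [read_sam()]).
#' @param truth truth data.frame from [simulate_reads()] /
#'   [read_truth_tsv()].
#' @param tolerance positional tolerance in bp.
#' @return object of class `eval_summary`: list with `n_reads`,
#'   `n_aligned`, `n_correct`, `recall` and `precision` (percent).
#' @examples
#' ref <- simulate_genome(2000, seed = 7)
#' sim <- simulate_reads(ref, 20, 60, sub_rate = 0, seed = 8)
#' idx <- build_fm_index(ref)
#' sam <- align_reads(idx, sim$reads)
#' evaluate_alignments(sam, sim$truth, tolerance = 0)
#' @export
evaluate_alignments <- function(sam, truth, tolerance = 20) {
  stopifnot(is.data.frame(sam), is.data.frame(truth), tolerance >= 0)
  if (anyDuplicated(paste(truth$id, truth$mate)))
    stop("duplicate truth ids")
  mate <- if ("mate" %in% names(sam)) sam$mate
          else ifelse(bitwAnd(sam$flag, 64L) > 0, 1L,
                      ifelse(bitwAnd(sam$flag, 128L) > 0, 2L, 0L))
  key <- paste(sam$qname, mate)
  tkey <- paste(truth$id, truth$mate)
  m <- match(key, tkey)
  if (anyNA(m))
    stop("SAM record(s) without a truth entry: ",
         paste(head(sam$qname[is.na(m)]), collapse = ", "))
  aligned <- !bitwAnd(sam$flag, 4L)
  strand <- ifelse(bitwAnd(sam$flag, 16L) > 0, "-", "+")
  correct <- aligned &
    sam$rname == truth$seqname[m] &
    strand == truth$strand[m] &
    abs(sam$pos - truth$pos[m]) <= tolerance
  n_reads <- nrow(truth)
  n_aligned <- sum(aligned)
  n_correct <- sum(correct)
  structure(list(
    n_reads = n_reads, n_aligned = n_aligned, n_correct = n_correct,
    recall = 100 * n_correct / n_reads,
    precision = if (n_aligned > 0) 100 * n_correct / n_aligned else NA_real_,
    tolerance = tolerance), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "eval_summary: %d reads | %d aligned | %d correct (tol %g bp)\n",
    x$n_reads, x$n_aligned, x$n_correct, x$tolerance))
  cat(sprintf("  recall    %6.2f %%\n  precision %6.2f %%\n",
              x$recall, x$precision))
  invisible(x)
}
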