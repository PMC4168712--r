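#' Aligner parameters
#'
#' @param k_schedule minimum-seed-length schedule, see
#'   [default_seed_schedule()].
#' @param c tag-length multiplier: tags have length L = read length * c.
#' @param P per-seed cap on located occurrences.
#' @param t number of top-scoring tags carried into precise alignment.
#' @param e candidate window flank extension in bp.
#' @param d band half-width of the gap DP (|offset| < d).
#' @param min_insert,max_insert paired-end outer-distance bounds in bp.
#' @param orientation required relative orientation of proper pairs;
#'   only `"fr"` (forward-reverse) is supported.
#' @param workers number of alignment workers (reads are chunked; each
#'   chunk has its own tag table, the index is the only shared state).
#' @param capacity tag-table slot count per worker (power of two).
#' @return object of class `aligner_params`.
#' @export
aligner_params <- function(k_schedule = default_seed_schedule(),
                           c = 10L, P = 50L, t = 10L, e = 20L, d = 21L,
                           min_insert = 0L, max_insert = 1000L,
                           orientation = "fr", workers = 1L,
                           capacity = 2^18) {
  stopifnot(c >= 1, P >= 1, t >= 1, e >= 0, d >= 1, workers >= 1,
            min_insert <= max_insert, identical(orientation, "fr"),
            capacity >= 2, bitwAnd(as.integer(capacity),
                                   as.integer(capacity) - 1L) == 0L)
  structure(list(k_schedule = k_schedule, c = as.integer(c),
                 P = as.integer(P), t = as.integer(t), e = as.integer(e),
                 d = as.integer(d), min_insert = as.double(min_insert),
                 max_insert = as.double(max_insert),
                 orientation = orientation, workers = as.integer(workers),
                 capacity = as.integer(capacity)),
            class = "aligner_params")
}

#' @export
print.aligner_params <- function(x, ...) {
  cat("aligner_params: c =", x$c, "| P =", x$P, "| t =", x$t,
      "| e =", x$e, "| d =", x$d, "\n  insert [", x$min_insert, ",",
      x$max_insert, "] bp,", x$orientation, "| workers =", x$workers, "\n")
  invisible(x)
}

params_cpp <- function(p) {
  list(k_breaks = as.integer(p$k_schedule$min_read_length),
       k_values = as.integer(p$k_schedule$k),
       c = p$c, P = p$P, t = p$t, e = p$e, d = p$d, capacity = p$capacity)
}

normalize_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    reads <- data.frame(id = ids, seq = unname(reads), qual = NA_character_,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(reads)))
  if (is.null(reads$qual)) reads$qual <- NA_character_
  if (any(!nzchar(reads$seq))) stop("empty read sequence")
  reads
}

chunk_indices <- function(n, workers) {
  w <- max(1L, min(workers, n))
  split(seq_len(n), ceiling(seq_len(n) / ceiling(n / w)))
}

run_chunks <- function(chunks, workers, fun) {
  if (workers > 1 && length(chunks) > 1 &&
      .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, fun, mc.cores = workers)
  } else {
    lapply(chunks, fun)
  }
}

#' Align single-end reads
#'
#' Per read: (phase 1) advance the tag table serial, extract maximal
#' seeds, grant each located occurrence's length to the tag containing the
#' estimated read start, and take the top-t tags; (phase 2) align the read
#' precisely to each candidate via anchored banded gap DP, rank by edit
#' distance, and compute mapping quality from the best-vs-runner-up gap.
#' A read with no seeds (e.g. all N) or no feasible candidate is reported
#' unaligned (FLAG 4).
#'
#' @param index an `fm_index`.
#' @param reads a character vector of sequences (optionally named), or a
#'   data.frame with columns `id`, `seq` and optionally `qual`.
#' @param params an [aligner_params()].
#' @return data.frame of SAM records (class `sam_records`): `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`, `nm`. For reverse-strand alignments `seq`/`qual` are
#'   stored reverse-complemented/reversed as SAM requires.
#' @export
align_reads <- function(index, reads, params = aligner_params()) {
  stopifnot(inherits(index, "fm_index"), inherits(params, "aligner_params"))
  reads <- normalize_reads(reads)
  pcl <- params_cpp(params)
  idx <- unclass(index)
  chunks <- chunk_indices(nrow(reads), params$workers)
  parts <- run_chunks(chunks, params$workers, function(ix) {
    cpp_align_batch(idx, toupper(reads$seq[ix]), pcl)
  })
  res <- lapply(do.call(Map, c(list(c), unname(parts))), unname)
  sam_from_single(index, reads, res)
}

sam_from_single <- function(index, reads, res) {
  aligned <- !bitwAnd(res$flag, 4L)
  rev <- bitwAnd(res$flag, 16L) > 0
  seqout <- toupper(reads$seq)
  qualout <- ifelse(is.na(reads$qual), "*", reads$qual)
  seqout[rev] <- revcomp(seqout[rev])
  qualout[rev & qualout != "*"] <-
    vapply(qualout[rev & qualout != "*"],
           function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
  out <- data.frame(
    qname = reads$id,
    flag = res$flag,
    rname = ifelse(aligned, index$names[res$seqid], "*"),
    pos = ifelse(aligned, res$pos, 0),
    mapq = res$mapq,
    cigar = ifelse(aligned, res$cigar, "*"),
    rnext = "*", pnext = 0, tlen = 0,
    seq = seqout, qual = qualout,
    nm = ifelse(aligned, res$edit, NA_integer_),
    stringsAsFactors = FALSE)
  class(out) <- c("sam_records", "data.frame")
  out
}

#' Align paired-end reads
#'
#' Each end is aligned independently to produce up to t ranked finalists;
#' all cross pairs on one sequence with forward-reverse orientation and
#' outer distance (leftmost start to rightmost end) within
#' `[min_insert, max_insert]` are enumerated, and the pair maximizing the
#' total score (per end: read length - edit distance; ties: leftmost,
#' then enumeration order) is reported as a proper pair with mate fields
#' and TLEN. Without a valid pair both ends report their individual best
#' alignments without the proper-pair flag; an unaligned end sets the
#' mate-unmapped flag on its partner.
#'
#' @param index an `fm_index`.
#' @param reads1,reads2 first/second mates, same format as in
#'   [align_reads()]; row i of `reads1` pairs with row i of `reads2`.
#' @param params an [aligner_params()].
#' @return `sam_records` data.frame with both ends interleaved
#'   (read1 then read2 per pair).
#' @export
align_read_pairs <- function(index, reads1, reads2,
                             params = aligner_params()) {
  stopifnot(inherits(index, "fm_index"), inherits(params, "aligner_params"))
  reads1 <- normalize_reads(reads1)
  reads2 <- normalize_reads(reads2)
  if (nrow(reads1) != nrow(reads2)) stop("mate files differ in read count")
  pcl <- params_cpp(params)
  idx <- unclass(index)
  chunks <- chunk_indices(nrow(reads1), params$workers)
  parts <- run_chunks(chunks, params$workers, function(ix) {
    cpp_align_pairs(idx, toupper(reads1$seq[ix]), toupper(reads2$seq[ix]),
                    pcl, params$min_insert, params$max_insert)
  })
  parts <- unname(parts)
  e1 <- lapply(do.call(Map, c(list(c), lapply(parts, `[[`, "end1"))), unname)
  e2 <- lapply(do.call(Map, c(list(c), lapply(parts, `[[`, "end2"))), unname)
  tlen1 <- unname(unlist(lapply(parts, `[[`, "tlen1")))
  tlen2 <- unname(unlist(lapply(parts, `[[`, "tlen2")))

  s1 <- sam_from_single(index, reads1, e1)
  s2 <- sam_from_single(index, reads2, e2)
  s1$qname <- reads1$id
  s2$qname <- reads1$id # pair shares QNAME
  s1$tlen <- tlen1
  s2$tlen <- tlen2
  fill_mate <- function(a, b) {
    both <- a$rname != "*" & b$rname != "*"
    a$rnext[both] <- ifelse(a$rname[both] == b$rname[both], "=",
                            b$rname[both])
    a$pnext[both] <- b$pos[both]
    only_mate <- a$rname == "*" & b$rname != "*"
    # SAM convention: unmapped mate placed at its partner's coordinates
    a$rname[only_mate] <- b$rname[only_mate]
    a$pos[only_mate] <- b$pos[only_mate]
    a$rnext[only_mate] <- "="
    a$pnext[only_mate] <- b$pos[only_mate]
    a
  }
  s1 <- fill_mate(s1, s2)
  s2 <- fill_mate(s2, s1)
  out <- rbind(s1, s2)
  ix <- as.vector(rbind(seq_len(nrow(s1)), nrow(s1) + seq_len(nrow(s2))))
  out <- out[ix, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sam_records", "data.frame")
  out
}

#' @export
print.sam_records <- function(x, ...) {
  n <- nrow(x)
  al <- sum(!bitwAnd(x$flag, 4L))
  cat("sam_records:", n, "record(s),", al, "aligned\n")
  NextMethod()
}
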