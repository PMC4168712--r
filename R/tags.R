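#' Estimated read start position from a seed match
#'
#' A seed with n read bases to its left matching at genome position m
#' places the read start near m - n; all seeds of an indel-free read yield
#' the same estimate. Clamped at the sequence start.
#'
#' @param m 1-based genome coordinate of the seed match's leftmost base.
#' @param n number of read bases before the seed (aligned orientation).
#' @return estimated 1-based read start coordinate, >= 1.
#' @examples
#' estimated_read_start(1006, 5) # 1001
#' @export
estimated_read_start <- function(m, n) {
  stopifnot(all(m >= 1), all(n >= 0))
  pmax(1, m - n)
}

#' Tag index of a genome coordinate
#'
#' Tags are consecutive non-overlapping genome partitions of length L;
#' by default L = R * c with c = 10, so a whole-read placement stays inside
#' one or two adjacent tags unless its total indel size exceeds L.
#'
#' @param est_start estimated 1-based read start coordinate.
#' @param L tag length in bp.
#' @return 0-based tag id, `floor((est_start - 1) / L)`.
#' @examples
#' tag_index(1000, 1000) # 0
#' tag_index(1001, 1000) # 1
#' @export
tag_index <- function(est_start, L) {
  stopifnot(L >= 1)
  floor((est_start - 1) / L)
}

#' Reset-free tag score table
#'
#' Open-addressing hash table over (tag id, strand) keys. Each record
#' carries the serial number of the read that wrote it; advancing the
#' serial ([advance_read()]) makes all previous records invisible without
#' clearing any memory. A ranked list of the `t` top-scoring visible
#' records is maintained incrementally on every grant.
#'
#' @param capacity slot count, a power of two.
#' @param t number of top-scoring tags to track.
#' @return object of class `tag_table`.
#' @export
tag_table <- function(capacity = 2^18, t = 10L) {
  structure(list(ptr = cpp_tt_new(as.integer(capacity), as.integer(t)),
                 capacity = as.integer(capacity), t = as.integer(t)),
            class = "tag_table")
}

#' @export
print.tag_table <- function(x, ...) {
  cat("tag_table: capacity", x$capacity, "| top-t =", x$t,
      "| read serial", format(cpp_tt_serial(x$ptr)), "\n")
  invisible(x)
}

#' Start scoring a new read
#'
#' Increments the read serial, clearing the top list; every record granted
#' under earlier serials becomes invisible. No slot memory is touched
#' (the reset-free property).
#'
#' @param table a [tag_table()].
#' @return the new serial number, invisibly.
#' @export
advance_read <- function(table) {
  stopifnot(inherits(table, "tag_table"))
  invisible(cpp_tt_advance(table$ptr))
}

#' Grant a seed's score to a tag
#'
#' Finds or creates the record for (tag_id, strand) under the current read
#' serial, adds the seed length to its score, appends the seed info, and
#' updates the top list if the record's rank changed.
#'
#' @param table a [tag_table()].
#' @param tag_id 0-based tag id (see [tag_index()]).
#' @param strand `"+"` or `"-"`.
#' @param length seed length in bp (the score granted).
#' @param read_pos 1-based seed offset in the aligned-orientation read.
#' @param genome_pos 1-based forward coordinate of the match (global).
#' @return the table, invisibly.
#' @export
grant_score <- function(table, tag_id, strand, length, read_pos = 1L,
                        genome_pos = 1) {
  stopifnot(inherits(table, "tag_table"), strand %in% c("+", "-"),
            length >= 1)
  cpp_tt_grant(table$ptr, as.double(tag_id),
               if (strand == "+") 0L else 1L,
               as.integer(length), as.integer(read_pos) - 1L,
               as.double(genome_pos) - 1)
  invisible(table)
}

#' Top-scoring visible tags
#'
#' @param table a [tag_table()].
#' @param t return at most this many records (capped at the table's own t).
#' @return data.frame with `tag_id`, `strand`, `score`, `n_seeds`, ranked
#'   by score (descending), ties by lower tag id then `"+"` first.
#' @export
top_tags <- function(table, t = NULL) {
  stopifnot(inherits(table, "tag_table"))
  df <- cpp_tt_top(table$ptr)
  if (!is.null(t) && nrow(df) > t) df <- df[seq_len(t), , drop = FALSE]
  df
}

#' Seeds stored for one visible tag record
#'
#' @param table a [tag_table()].
#' @param tag_id 0-based tag id.
#' @param strand `"+"` or `"-"`.
#' @return data.frame of (length, read_pos, genome_pos), 1-based, or
#'   `NULL` if no visible record exists.
#' @export
tag_seeds <- function(table, tag_id, strand) {
  stopifnot(inherits(table, "tag_table"))
  df <- cpp_tt_seeds(table$ptr, as.double(tag_id),
                     if (strand == "+") 0L else 1L)
  if (is.null(df)) return(NULL)
  data.frame(length = df$length,
             read_pos = df$read_offset_aligned0 + 1L,
             genome_pos = df$gpos0 + 1,
             stringsAsFactors = FALSE)
}
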