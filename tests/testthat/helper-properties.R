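# Shared property checkers used by both the unit suites and the
# acceptance suite.

# Per-length substring count tables for O(1) overlapping-occurrence counts.
substring_tables <- function(txt, max_len) {
  n <- nchar(txt)
  lapply(seq_len(max_len), function(l) {
    if (l > n) return(table(character(0)))
    table(substring(txt, 1:(n - l + 1), l:n))
  })
}

tab_count <- function(tabs, pat) {
  l <- nchar(pat)
  if (l == 0 || l > length(tabs)) return(NA_integer_)
  v <- tabs[[l]][pat]
  if (is.na(v)) 0L else as.integer(v)
}

# naive right-to-left extension using precomputed tables (suffix lengths
# bounded by length(tabs))
tab_match_rl <- function(tabs, read, right, max_len) {
  best_len <- 0L
  best_cnt <- NA_integer_
  for (m in seq_len(min(right, max_len))) {
    pat <- substr(read, right - m + 1L, right)
    if (grepl("[^ACGT]", pat)) break
    cnt <- tab_count(tabs, pat)
    if (cnt == 0) break
    best_len <- m
    best_cnt <- cnt
  }
  list(matched = best_len, count = best_cnt)
}

tab_match_lr <- function(tabs, read, start, max_len) {
  best <- 0L
  R <- nchar(read)
  for (m in seq_len(min(R - start + 1L, max_len))) {
    pat <- substr(read, start, start + m - 1L)
    if (grepl("[^ACGT]", pat) || tab_count(tabs, pat) == 0) break
    best <- m
  }
  best
}

# Exhaustively compare FM search primitives against the naive scan on one
# genome; returns number of queries checked (fails via expect_* inside).
check_fm_against_scan <- function(ref, idx, qmax = 12L, stride = 37L) {
  txt <- doubled_text(ref)
  tabs <- substring_tables(txt, qmax)
  n <- nchar(txt)
  checked <- 0L
  for (start in seq(1L, max(1L, n - qmax), by = stride)) {
    read <- substr(txt, start, min(n, start + qmax - 1L))
    R <- nchar(read)
    got <- match_right_to_left(idx, read, right = R, max_len = qmax)
    want <- tab_match_rl(tabs, read, R, qmax)
    expect_equal(got$matched, want$matched)
    if (want$matched > 0) expect_equal(got$width, want$count)
    got_lr <- match_left_to_right(idx, read, start = 1, max_len = qmax)
    expect_equal(got_lr, tab_match_lr(tabs, read, 1L, qmax))
    checked <- checked + 1L
  }
  # random (mostly non-occurring) queries as well
  for (i in 1:15) {
    read <- rand_genome(sample(1:qmax, 1))
    R <- nchar(read)
    got <- match_right_to_left(idx, read, right = R, max_len = qmax)
    want <- tab_match_rl(tabs, read, R, qmax)
    expect_equal(got$matched, want$matched)
    if (want$matched > 0) expect_equal(got$width, want$count)
    checked <- checked + 1L
  }
  checked
}

# Independent reimplementation of the greedy seed-extraction loop on top
# of the naive scan, producing (seed set, hit set).
oracle_seed_hits <- function(ref, read, k) {
  txt <- doubled_text(ref)
  G <- ref$G
  R <- nchar(read)
  kk <- min(k, R)
  right <- R
  seeds <- list()
  hits <- list()
  while (right >= kk) {
    s <- right - kk + 1L
    matched <- oracle_match_lr(txt, read, s, kk)
    if (matched < kk) {
      right <- right - kk + matched
      next
    }
    m <- oracle_match_rl(txt, read, right, Inf)
    pat <- substr(read, right - m$matched + 1L, right)
    seeds[[length(seeds) + 1L]] <-
      c(offset = right - m$matched + 1L, len = m$matched)
    for (p in occ_positions(pat, txt)) {
      p0 <- p - 1L
      len <- m$matched
      if (p0 + len <= G) { strand <- "+"; g0 <- p0 }
      else if (p0 >= G && p0 + len <= 2 * G) {
        strand <- "-"; g0 <- 2 * G - p0 - len
      } else next
      ends <- cumsum(ref$seqlen)
      sid <- findInterval(g0, c(0, ends[-length(ends)]))
      if (g0 + len > ends[sid]) next
      hits[[length(hits) + 1L]] <- data.frame(
        read_offset = right - m$matched + 1L, length = len,
        seqname = ref$names[sid], pos = g0 - ref$starts0[sid] + 1,
        strand = strand, stringsAsFactors = FALSE)
    }
    right <- right - m$matched + kk - 1L
  }
  list(seeds = do.call(rbind, seeds),
       hits = if (length(hits)) do.call(rbind, hits) else NULL)
}

hit_key <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(paste(df$read_offset, df$length, df$seqname, df$pos, df$strand))
}

# The four seed-set validity conditions plus maximality, by brute force.
check_seed_validity <- function(ref, read, k, seeds_df) {
  txt <- doubled_text(ref)
  R <- nchar(read)
  sd <- unique(seeds_df[, c("read_offset", "length")])
  sd <- sd[order(sd$read_offset), , drop = FALSE]
  kk <- min(k, R)
  for (i in seq_len(nrow(sd))) {
    off <- sd$read_offset[i]; len <- sd$length[i]
    expect_gte(len, kk)                                    # condition 1
    expect_gte(count_occ(substr(read, off, off + len - 1L), txt), 1) # 3
    if (i > 1) {                                           # condition 2
      prev_end <- sd$read_offset[i - 1] + sd$length[i - 1] - 1L
      overlap <- prev_end - off + 1L
      expect_lte(overlap, kk - 1L)
    }
    # condition 4 (maximality): one-base extension loses all matches or
    # breaks the overlap bound
    if (off > 1) {
      left_ok <- count_occ(substr(read, off - 1L, off + len - 1L), txt) == 0
      lo <- if (i > 1) sd$read_offset[i - 1] + sd$length[i - 1] - (off - 1L) + 1L
            else -Inf
      expect_true(left_ok || lo > kk - 1L)
    }
    if (off + len - 1L < R) {
      right_ok <- count_occ(substr(read, off, off + len), txt) == 0
      ro <- if (i < nrow(sd)) (off + len) - sd$read_offset[i + 1] + 1L
            else -Inf
      expect_true(right_ok || ro > kk - 1L)
    }
  }
  invisible(nrow(sd))
}

# Fuzz the reset-free tag table against a freshly-built naive map per read.
check_tag_table_vs_fresh <- function(n_reads = 60, grants_per_read = 12,
                                     t = 5, capacity = 64) {
  tt <- tag_table(capacity = capacity, t = t)
  for (r in seq_len(n_reads)) {
    advance_read(tt)
    oracle <- fresh_tag_oracle()
    for (g in seq_len(sample.int(grants_per_read, 1))) {
      tag <- sample(0:12, 1)
      strand <- sample(c("+", "-"), 1)
      len <- sample(15:40, 1)
      grant_score(tt, tag, strand, len)
      oracle$grant(tag, strand, len)
      got <- top_tags(tt)
      want <- oracle$top(t)
      expect_equal(got$tag_id, want$tag_id)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score)
    }
  }
  invisible(TRUE)
}

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MID]$", "", m)),
             op = sub("^[0-9]+", "", m), stringsAsFactors = FALSE)
}

cigar_read_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I")])
}

cigar_ref_len <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "D")])
}

sorted_records <- function(sam) {
  o <- order(sam$qname, sam$flag)
  x <- sam[o, ]
  rownames(x) <- NULL
  x
}
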