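# Independent brute-force oracles used across the suite. These never call
# the package's search/alignment code paths.

rand_genome <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

oracle_revcomp <- function(s) {
  # independent of tagalign::revcomp (different mechanism)
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(m[strsplit(s, "")[[1]]])), collapse = "")
}

doubled_text <- function(ref) {
  fwd <- paste(ref$sequences, collapse = "")
  paste0(fwd, oracle_revcomp(fwd))
}

# overlapping occurrence positions of `pat` in `txt` (1-based starts)
occ_positions <- function(pat, txt) {
  if (nchar(pat) == 0 || nchar(pat) > nchar(txt)) return(integer(0))
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pat, substr(txt, from, nchar(txt)), fixed = TRUE)
    if (i < 0) break
    hits <- c(hits, from + i - 1L)
    from <- from + i
  }
  hits
}

count_occ <- function(pat, txt) length(occ_positions(pat, txt))

# naive maximal right-to-left extension: longest suffix of read[.., right]
# (of length <= max_len) occurring in txt, returning count and length
oracle_match_rl <- function(txt, read, right, max_len = Inf) {
  best_len <- 0L
  best_cnt <- NA_integer_
  m <- 1L
  while (m <= right && m <= max_len) {
    pat <- substr(read, right - m + 1L, right)
    if (grepl("[^ACGT]", pat)) break
    cnt <- count_occ(pat, txt)
    if (cnt == 0) break
    best_len <- m
    best_cnt <- cnt
    m <- m + 1L
  }
  list(matched = best_len, count = best_cnt)
}

oracle_match_lr <- function(txt, read, start, max_len = Inf) {
  best <- 0L
  m <- 1L
  R <- nchar(read)
  while (start + m - 1L <= R && m <= max_len) {
    pat <- substr(read, start, start + m - 1L)
    if (grepl("[^ACGT]", pat) || count_occ(pat, txt) == 0) break
    best <- m
    m <- m + 1L
  }
  best
}

# full-matrix unit-cost global edit distance (Needleman-Wunsch), row-vector
# recurrence, independent of the banded implementation
nw_edit <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- 0:m
  if (n == 0) return(m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    if (m > 0) {
      for (j in seq_len(m)) {
        cur[j + 1] <- min(prev[j] + (av[i] != bv[j]),
                          prev[j + 1] + 1, cur[j] + 1)
      }
    }
    prev <- cur
  }
  prev[m + 1]
}

# naive tag scorer: plain environment-backed map, rebuilt for every read
fresh_tag_oracle <- function() {
  env <- new.env(parent = emptyenv())
  list(
    grant = function(tag, strand, len) {
      key <- paste0(tag, strand)
      cur <- if (exists(key, envir = env)) get(key, envir = env)
             else list(tag = tag, strand = strand, score = 0)
      cur$score <- cur$score + len
      assign(key, cur, envir = env)
    },
    top = function(t) {
      ks <- ls(env)
      if (length(ks) == 0)
        return(data.frame(tag_id = numeric(0), strand = character(0),
                          score = numeric(0)))
      recs <- do.call(rbind, lapply(ks, function(k) {
        r <- get(k, envir = env)
        data.frame(tag_id = r$tag, strand = r$strand, score = r$score,
                   stringsAsFactors = FALSE)
      }))
      o <- order(-recs$score, recs$tag_id, recs$strand != "+")
      head(recs[o, , drop = FALSE], t)
    })
}

# seeded fixture: genome in which every k-mer occurs exactly once in the
# doubled (two-strand) text, so error-free reads of length >= k have
# unambiguous placements
unique_kmer_genome <- function(len, k, seed) {
  set.seed(seed)
  repeat {
    g <- rand_genome(len)
    txt <- paste0(g, oracle_revcomp(g))
    kmers <- substring(txt, 1:(nchar(txt) - k + 1), k:nchar(txt))
    if (!anyDuplicated(kmers)) return(g)
  }
}

# seeded fixture: (genome, window) such that every k-mer of the window
# occurs exactly once in the doubled text
unique_window <- function(glen, wstart, wlen, k, seed) {
  set.seed(seed)
  repeat {
    g <- rand_genome(glen)
    txt <- paste0(g, oracle_revcomp(g))
    win <- substr(g, wstart, wstart + wlen - 1)
    kmers <- substring(win, 1:(wlen - k + 1), k:wlen)
    if (all(vapply(kmers, count_occ, integer(1), txt) == 1)) return(g)
  }
}

default_params <- function(...) aligner_params(...)
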