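#' Simulate a random reference genome
#'
#' I.i.d. bases with a chosen GC content; a desk-scale stand-in for a real
#' reference. Repeat structure of real genomes is deliberately absent
#' (see the methods vignette for what that implies).
#'
#' @param length total length in bp.
#' @param gc fraction of G+C bases in 0..1.
#' @param seed RNG seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @param n_sequences split the total length over this many equally sized
#'   sequences (last one takes the remainder).
#' @return a [reference_set()] with sequences named `sim1`, `sim2`, ...
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL,
                            n_sequences = 1L) {
  stopifnot(length >= 1, gc >= 0, gc <= 1, n_sequences >= 1,
            length >= n_sequences)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  per <- floor(length / n_sequences)
  cuts <- c(rep(per, n_sequences - 1), length - per * (n_sequences - 1))
  off <- cumsum(c(0, cuts[-n_sequences]))
  seqs <- vapply(seq_len(n_sequences), function(i)
    paste(bases[(off[i] + 1):(off[i] + cuts[i])], collapse = ""),
    character(1))
  reference_set(seqs, paste0("sim", seq_len(n_sequences)))
}

geom_len <- function(ext) {
  # indel length: 1 + geometric extension with parameter `ext`
  n <- 1L
  while (runif(1) < ext) n <- n + 1L
  n
}

# Walk a template emitting read_len bases with uniform substitutions and
# geometric-length indels; returns read string, consumed template length,
# substitution count and indel bases.
mutate_walk <- function(template, read_len, sub_rate, indel_rate,
                        indel_ext) {
  tpl <- strsplit(template, "", fixed = TRUE)[[1]]
  out <- character(read_len)
  ti <- 1L
  oi <- 1L
  n_sub <- 0L
  indel_bases <- 0L
  bases <- c("A", "C", "G", "T")
  while (oi <= read_len) {
    if (indel_rate > 0 && runif(1) < indel_rate) {
      len <- geom_len(indel_ext)
      if (runif(1) < 0.5) { # insertion into the read
        take <- min(len, read_len - oi + 1L)
        out[oi:(oi + take - 1L)] <- sample(bases, take, replace = TRUE)
        oi <- oi + take
        indel_bases <- indel_bases + take
        next
      } else {              # deletion from the template
        if (ti + len > length(tpl)) return(NULL)
        ti <- ti + len
        indel_bases <- indel_bases + len
      }
    }
    if (ti > length(tpl)) return(NULL)
    b <- tpl[ti]
    ti <- ti + 1L
    if (sub_rate > 0 && runif(1) < sub_rate) {
      alt <- bases[bases != b]
      b <- alt[sample.int(3L, 1L)]
      n_sub <- n_sub + 1L
    }
    out[oi] <- b
    oi <- oi + 1L
  }
  list(read = paste(out, collapse = ""), consumed = ti - 1L,
       n_sub = n_sub, indel_bases = indel_bases)
}

#' Simulate sequencing reads with known truth
#'
#' dwgsim-style Illumina emulation: uniform start positions, fair-coin
#' strand, uniform per-base substitutions (equal probability over the
#' three alternatives), indels opened at `indel_rate` per base and
#' extended geometrically with parameter `indel_ext` (insertion or
#' deletion with equal probability). The error profile is uniform along
#' the read (no quality ramp). Truth records carry the pre-error origin:
#' sequence, strand and 1-based leftmost forward coordinate of the
#' template span. Paired mode emits forward-reverse pairs with
#' normally distributed outer insert sizes (read 1 on the forward
#' strand).
#'
#' @param ref a [reference_set()].
#' @param n number of reads (or read pairs).
#' @param read_len read length in bp.
#' @param sub_rate per-base substitution probability in [0, 1).
#' @param indel_rate per-base indel-open probability; default
#'   `sub_rate / 10`.
#' @param indel_ext geometric extension parameter of indel length.
#' @param paired emit FR pairs?
#' @param insert_mean,insert_sd outer insert size distribution (paired
#'   mode).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`, `mate`;
#'   mate is 0 for single-end, 1/2 for pairs) and `truth` (data.frame
#'   `id`, `mate`, `seqname`, `strand`, `pos`, `n_sub`, `indel_bases`).
#' @export
simulate_reads <- function(ref, n, read_len, sub_rate,
                           indel_rate = NULL, indel_ext = 0.3,
                           paired = FALSE, insert_mean = 300,
                           insert_sd = 30, seed = NULL) {
  stopifnot(inherits(ref, "reference_set"), n >= 1,
            sub_rate >= 0, sub_rate < 1, read_len >= 1)
  if (is.null(indel_rate)) indel_rate <- sub_rate / 10
  stopifnot(indel_rate >= 0, indel_rate < 1, indel_ext >= 0, indel_ext < 1)
  if (read_len > max(ref$seqlen))
    stop("read length exceeds every reference sequence")
  if (paired && insert_mean > max(ref$seqlen))
    stop("insert size larger than the reference sequences")
  if (!is.null(seed)) set.seed(seed)

  slack <- 50L + ceiling(read_len * 0.2)
  pick_seq <- function(min_len) {
    ok <- which(ref$seqlen >= min_len)
    if (length(ok) == 0) stop("no reference sequence long enough")
    if (length(ok) == 1) return(ok)
    ok[sample.int(length(ok), 1L, prob = ref$seqlen[ok])]
  }

  make_read <- function(sid, strand, leftmost = NULL, rightmost = NULL) {
    # repeat until indel drift stays inside the template slack
    repeat {
      span <- read_len + slack
      L <- ref$seqlen[sid]
      if (is.null(leftmost) && is.null(rightmost)) {
        if (strand == "+") lm <- sample.int(L - read_len + 1L, 1L)
        else rm <- sample.int(L - read_len + 1L, 1L) + read_len - 1L
      } else {
        if (!is.null(leftmost)) lm <- leftmost else rm <- rightmost
      }
      if (strand == "+") {
        span <- min(span, L - lm + 1L)
        tpl <- substr(ref$sequences[sid], lm, lm + span - 1L)
      } else {
        span <- min(span, rm)
        tpl <- revcomp(substr(ref$sequences[sid], rm - span + 1L, rm))
      }
      w <- mutate_walk(tpl, read_len, sub_rate, indel_rate, indel_ext)
      if (is.null(w)) {
        if (!is.null(leftmost) || !is.null(rightmost)) return(NULL)
        next
      }
      pos <- if (strand == "+") lm else rm - w$consumed + 1L
      return(list(seq = w$read, pos = pos, n_sub = w$n_sub,
                  indel_bases = w$indel_bases))
    }
  }

  qual <- strrep("I", read_len)
  if (!paired) {
    ids <- sprintf("sim_%06d", seq_len(n))
    seqs <- character(n); sid <- integer(n); strand <- character(n)
    pos <- numeric(n); nsub <- integer(n); ind <- integer(n)
    for (i in seq_len(n)) {
      sid[i] <- pick_seq(read_len)
      strand[i] <- if (runif(1) < 0.5) "+" else "-"
      r <- make_read(sid[i], strand[i])
      seqs[i] <- r$seq; pos[i] <- r$pos
      nsub[i] <- r$n_sub; ind[i] <- r$indel_bases
    }
    reads <- data.frame(id = ids, seq = seqs, qual = qual, mate = 0L,
                        stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, mate = 0L, seqname = ref$names[sid],
                        strand = strand, pos = pos, n_sub = nsub,
                        indel_bases = ind, stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }

  ids <- sprintf("simp_%06d", seq_len(n))
  r1 <- character(n); r2 <- character(n)
  sid <- integer(n); pos1 <- numeric(n); pos2 <- numeric(n)
  ns1 <- integer(n); ns2 <- integer(n); ib1 <- integer(n); ib2 <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      ins <- max(2L * read_len,
                 as.integer(round(rnorm(1, insert_mean, insert_sd))))
      sid[i] <- pick_seq(ins)
      L <- ref$seqlen[sid[i]]
      fstart <- sample.int(L - ins + 1L, 1L)
      a <- make_read(sid[i], "+", leftmost = fstart)
      b <- make_read(sid[i], "-", rightmost = fstart + ins - 1L)
      if (!is.null(a) && !is.null(b)) break
    }
    r1[i] <- a$seq; pos1[i] <- a$pos; ns1[i] <- a$n_sub; ib1[i] <- a$indel_bases
    r2[i] <- b$seq; pos2[i] <- b$pos; ns2[i] <- b$n_sub; ib2[i] <- b$indel_bases
  }
  reads <- data.frame(
    id = rep(ids, 2), seq = c(r1, r2), qual = qual,
    mate = rep(c(1L, 2L), each = n), stringsAsFactors = FALSE)
  truth <- data.frame(
    id = rep(ids, 2), mate = rep(c(1L, 2L), each = n),
    seqname = ref$names[rep(sid, 2)],
    strand = rep(c("+", "-"), each = n),
    pos = c(pos1, pos2), n_sub = c(ns1, ns2),
    indel_bases = c(ib1, ib2), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write / read the 6+ column truth sidecar
#'
#' Tab-separated with a header line: `id`, `mate`, `seqname`, `strand`,
#' `pos` (1-based leftmost forward coordinate of the pre-error origin),
#' `n_sub`, `indel_bases`.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param path output path.
#' @return `path` (write) / truth data.frame (read).
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(id = "character", seqname = "character",
                            strand = "character"))
}
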