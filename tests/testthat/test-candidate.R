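# independent reimplementation of the greedy anchor-chain rule
oracle_chain <- function(seeds, d) {
  o <- order(-seeds$length, seeds$read_pos, seeds$genome_pos)
  acc <- integer(0)
  for (i in o) {
    ok <- TRUE
    for (j in acc) {
      sl <- seeds$read_pos[i] + seeds$length[i] <= seeds$read_pos[j]
      sr <- seeds$read_pos[j] + seeds$length[j] <= seeds$read_pos[i]
      gl <- seeds$genome_pos[i] + seeds$length[i] <= seeds$genome_pos[j]
      gr <- seeds$genome_pos[j] + seeds$length[j] <= seeds$genome_pos[i]
      if (!((sl || sr) && (gl || gr)) || !((sl && gl) || (sr && gr))) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    off_i <- seeds$genome_pos[i] - seeds$read_pos[i]
    ordacc <- acc[order(seeds$read_pos[acc])]
    before <- ordacc[seeds$read_pos[ordacc] < seeds$read_pos[i]]
    after <- ordacc[seeds$read_pos[ordacc] > seeds$read_pos[i]]
    neigh <- c(tail(before, 1), head(after, 1))
    offs <- seeds$genome_pos[neigh] - seeds$read_pos[neigh]
    if (any(abs(off_i - offs) >= d)) next
    acc <- c(acc, i)
  }
  sort(seeds$read_pos[acc])
}

test_that("anchor chain keeps consistent seeds and prefers longer ones", {
  one <- data.frame(read_pos = 1, genome_pos = 101, length = 20)
  expect_equal(nrow(select_anchor_chain(one, d = 21)), 1)

  two <- data.frame(read_pos = c(1, 31), genome_pos = c(101, 131),
                    length = c(20, 20))
  ch <- select_anchor_chain(two, d = 21)
  expect_equal(ch$read_pos, c(1, 31)) # both kept, read order

  confl <- data.frame(read_pos = c(1, 11), genome_pos = c(101, 501),
                      length = c(20, 25))
  ch2 <- select_anchor_chain(confl, d = 21)
  expect_equal(nrow(ch2), 1)
  expect_equal(ch2$length, 25) # longer seed wins the conflict
})

test_that("greedy anchor chains match an independent implementation on random instances", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:7, 1)
    seeds <- data.frame(
      read_pos = sample(1:80, n, replace = TRUE),
      genome_pos = sample(1:200, n, replace = TRUE),
      length = sample(4:30, n, replace = TRUE))
    d <- sample(c(3, 10, 21), 1)
    got <- select_anchor_chain(seeds, d = d)
    expect_equal(got$read_pos, oracle_chain(seeds, d))
    # chain invariants: collinear and disjoint in both coordinates
    if (nrow(got) > 1) {
      expect_true(all(diff(got$read_pos) > 0))
      expect_true(all(diff(got$genome_pos) > 0))
      expect_true(all(got$read_pos[-1] >=
                      head(got$read_pos + got$length, -1)))
      expect_true(all(got$genome_pos[-1] >=
                      head(got$genome_pos + got$length, -1)))
    }
  }
})

test_that("candidate alignment reproduces exact, mismatched and deleted reads", {
  set.seed(55)
  g <- rand_genome(2000)
  ref <- reference_set(g)
  idx <- build_fm_index(ref)

  # error-free single anchor: full-length M, zero edits
  read <- substr(g, 501, 560)
  a <- align_to_candidate(idx, read,
                          data.frame(read_pos = 1, genome_pos = 501,
                                     length = 60),
                          strand = "+", tag_id = 0)
  expect_true(a$feasible)
  expect_equal(a$cigar, "60M")
  expect_equal(a$edit, 0)
  expect_equal(a$pos, 501)

  # one mismatch between two anchors: edit 1, all-M CIGAR
  read_mm <- read
  substr(read_mm, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, 30, 30))[1]
  b <- align_to_candidate(idx, read_mm,
                          data.frame(read_pos = c(1, 35),
                                     genome_pos = c(501, 535),
                                     length = c(25, 26)),
                          strand = "+", tag_id = 0)
  expect_equal(b$edit, 1)
  expect_equal(b$cigar, "60M")

  # 2 bp deletion between anchors: edit 2, CIGAR contains 2D
  read_del <- paste0(substr(g, 501, 530), substr(g, 533, 562))
  cc <- align_to_candidate(idx, read_del,
                           data.frame(read_pos = c(1, 31),
                                      genome_pos = c(501, 533),
                                      length = c(30, 30)),
                           strand = "+", tag_id = 0)
  expect_equal(cc$edit, 2)
  expect_match(cc$cigar, "2D")
  expect_equal(cc$pos, 501)
  expect_equal(cigar_read_len(cc$cigar), 60)
  expect_equal(cigar_ref_len(cc$cigar), 62)

  # reverse-strand candidate aligns the reverse-complemented read
  rc <- align_to_candidate(idx, oracle_revcomp(read),
                           data.frame(read_pos = 1, genome_pos = 501,
                                      length = 60),
                           strand = "-", tag_id = 0)
  expect_true(rc$feasible)
  expect_equal(rc$pos, 501)
  expect_equal(rc$edit, 0)
  expect_equal(rc$strand, "-")
})

test_that("candidate ranking follows edit, tag score, coordinate, strand", {
  res <- data.frame(edit = c(7, 3), tag_score = c(10, 10),
                    pos = c(5, 9), strand = c("+", "+"),
                    tag_id = c(1, 2))
  r <- rank_candidates(res)
  expect_equal(r$best, 2)
  expect_equal(r$runner_up, 1)

  res2 <- data.frame(edit = c(2, 2), tag_score = c(150, 180),
                     pos = c(5, 900), strand = c("+", "+"),
                     tag_id = c(1, 2))
  expect_equal(rank_candidates(res2)$best, 2) # higher tag score wins ties

  expect_null(rank_candidates(res2[0, ]))

  # random sets vs exhaustive comparison under the stated order
  set.seed(8)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    rs <- data.frame(edit = sample(0:5, n, TRUE),
                     tag_score = sample(c(50, 100, 150), n, TRUE),
                     pos = sample(1:50, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE),
                     tag_id = seq_len(n))
    want <- order(rs$edit, -rs$tag_score, rs$pos, rs$strand != "+")[1]
    expect_equal(rank_candidates(rs)$best, want)
  }
})

test_that("mapping quality reflects the best-vs-runner-up score gap", {
  expect_equal(compute_mapq(100, 2, NULL), 60)
  expect_equal(compute_mapq(100, 2, NA), 60)
  expect_equal(compute_mapq(100, 2, 2), 0)
  expect_equal(compute_mapq(100, 2, 12), 6) # floor(60 * 10 / 98)
  expect_equal(compute_mapq(100, 0, 100), 60) # capped
})
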