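test_that("genome simulation is seeded-deterministic and honors GC content", {
  g1 <- simulate_genome(1000, seed = 1)
  g2 <- simulate_genome(1000, seed = 1)
  expect_identical(g1$sequences, g2$sequences)

  at_only <- simulate_genome(500, gc = 0, seed = 2)
  expect_false(grepl("[GC]", at_only$sequences))
  gc_only <- simulate_genome(500, gc = 1, seed = 2)
  expect_false(grepl("[AT]", gc_only$sequences))

  g <- simulate_genome(1e6, gc = 0.5, seed = 3)
  obs <- sum(strsplit(g$sequences, "")[[1]] %in% c("G", "C")) / 1e6
  se <- sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(obs - 0.5), 3 * se)

  multi <- simulate_genome(1000, seed = 4, n_sequences = 3)
  expect_equal(length(multi$names), 3)
  expect_equal(sum(multi$seqlen), 1000)
})

test_that("error-free reads are exact substrings at their recorded origin", {
  ref <- simulate_genome(20000, seed = 5)
  sim <- simulate_reads(ref, 100, 80, sub_rate = 0, indel_rate = 0, seed = 6)
  expect_equal(sim$truth$n_sub, rep(0L, 100))
  expect_equal(sim$truth$indel_bases, rep(0L, 100))
  for (i in 1:100) {
    tr <- sim$truth[i, ]
    origin <- substr(ref$sequences[match(tr$seqname, ref$names)],
                     tr$pos, tr$pos + 80 - 1)
    want <- if (tr$strand == "+") origin else oracle_revcomp(origin)
    expect_equal(sim$reads$seq[i], want)
  }
})

test_that("read simulation is seeded-deterministic (byte-identical FASTQ)", {
  ref <- simulate_genome(10000, seed = 7)
  s1 <- simulate_reads(ref, 30, 60, sub_rate = 0.02, seed = 8)
  s2 <- simulate_reads(ref, 30, 60, sub_rate = 0.02, seed = 8)
  expect_identical(s1, s2)
  f1 <- file.path(tempdir(), "s1.fq"); f2 <- file.path(tempdir(), "s2.fq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("observed substitution rate matches the requested rate", {
  ref <- simulate_genome(100000, seed = 9)
  n <- 5000; rl <- 200 # 1e6 sequenced bases
  sim <- simulate_reads(ref, n, rl, sub_rate = 0.02, indel_rate = 0, seed = 10)
  mism <- 0L
  for (i in seq_len(n)) {
    tr <- sim$truth[i, ]
    origin <- substr(ref$sequences[1], tr$pos, tr$pos + rl - 1)
    tmpl <- if (tr$strand == "+") origin else oracle_revcomp(origin)
    mism <- mism + sum(strsplit(sim$reads$seq[i], "")[[1]] !=
                       strsplit(tmpl, "")[[1]])
  }
  obs <- mism / (n * rl)
  se <- sqrt(0.02 * 0.98 / (n * rl))
  expect_lt(abs(obs - 0.02), 3 * se)
  expect_equal(mism, sum(sim$truth$n_sub))
})

test_that("indel truth accounting matches the emitted reads", {
  ref <- simulate_genome(50000, seed = 11)
  sim <- simulate_reads(ref, 200, 100, sub_rate = 0, indel_rate = 0.02,
                        indel_ext = 0.3, seed = 12)
  expect_gt(sum(sim$truth$indel_bases), 0)
  expect_true(all(nchar(sim$reads$seq) == 100))
  expect_true(all(sim$truth$pos >= 1))
  expect_true(all(sim$truth$pos <= ref$seqlen[1]))
})

test_that("truth sidecar round-trips through TSV", {
  ref <- simulate_genome(5000, seed = 13)
  sim <- simulate_reads(ref, 10, 50, sub_rate = 0.01, seed = 14)
  path <- file.path(tempdir(), "truth.tsv")
  write_truth_tsv(sim$truth, path)
  rt <- read_truth_tsv(path)
  expect_equal(rt, sim$truth)
})

test_that("the evaluator applies the exact correctness rule", {
  truth <- data.frame(id = sprintf("r%02d", 1:10), mate = 0L,
                      seqname = "chr1", strand = "+",
                      pos = seq(100, 1000, by = 100),
                      n_sub = 0L, indel_bases = 0L,
                      stringsAsFactors = FALSE)
  sam <- data.frame(
    qname = truth$id,
    flag = c(rep(0L, 7), 0L, 4L, 4L),   # 2 unaligned
    rname = c(rep("chr1", 8), "*", "*"),
    pos = c(truth$pos[1:7], truth$pos[8] + 500, 0, 0), # 1 misplaced
    mapq = 60L, cigar = "50M", rnext = "*", pnext = 0, tlen = 0,
    seq = strrep("A", 50), qual = "*", nm = 0L,
    stringsAsFactors = FALSE)
  ev <- evaluate_alignments(sam, truth, tolerance = 20)
  expect_equal(ev$n_reads, 10)
  expect_equal(ev$n_aligned, 8)
  expect_equal(ev$n_correct, 7)
  expect_equal(ev$recall, 70)
  expect_equal(ev$precision, 87.5)

  # positional tolerance boundary
  sam17 <- sam[1, ]; sam17$pos <- truth$pos[1] + 17
  expect_equal(evaluate_alignments(sam17, truth[1, ], 20)$n_correct, 1)
  sam25 <- sam[1, ]; sam25$pos <- truth$pos[1] + 25
  expect_equal(evaluate_alignments(sam25, truth[1, ], 20)$n_correct, 0)
  # wrong strand is never correct
  samws <- sam[1, ]; samws$flag <- 16L
  expect_equal(evaluate_alignments(samws, truth[1, ], 20)$n_correct, 0)

  # a SAM record without truth is an error (guards id mangling)
  bad <- sam; bad$qname[1] <- "ghost"
  expect_error(evaluate_alignments(bad, truth, 20), "truth")
})

test_that("zero-error reads from a unique-k-mer genome map perfectly at tolerance 0", {
  g <- unique_kmer_genome(3000, 20, seed = 2025)
  ref <- reference_set(g, "uniq")
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 150, 100, sub_rate = 0, indel_rate = 0,
                        seed = 15)
  sam <- align_reads(idx, sim$reads)
  ev <- evaluate_alignments(sam, sim$truth, tolerance = 0)
  expect_equal(ev$recall, 100)
  expect_equal(ev$precision, 100)
})

test_that("mean recall does not increase with the substitution rate", {
  ref <- simulate_genome(50000, seed = 16)
  idx <- build_fm_index(ref)
  recalls <- vapply(c(0, 0.06, 0.15), function(rate) {
    rs <- vapply(1:2, function(rep) {
      sim <- simulate_reads(ref, 150, 100, sub_rate = rate,
                            indel_rate = 0.002,
                            seed = 160 + round(1000 * rate) + rep)
      ev <- evaluate_alignments(align_reads(idx, sim$reads), sim$truth, 20)
      ev$recall
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1)) # non-increasing up to MC noise
  expect_gt(recalls[1] - recalls[3], 5) # and genuinely lower at 15%
})
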