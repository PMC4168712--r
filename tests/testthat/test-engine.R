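make_fixture <- function() {
  # genome whose 20-mers are all unique across both strands
  g <- unique_kmer_genome(2000, 20, seed = 2024)
  ref <- reference_set(g, "chrF")
  list(g = g, ref = ref, idx = build_fm_index(ref))
}

test_that("error-free reads from a unique region align exactly, both strands", {
  fx <- make_fixture()
  read <- substr(fx$g, 701, 800)
  sam <- align_reads(fx$idx, c(fwd = read, rev = oracle_revcomp(read)))
  expect_equal(sam$flag, c(0L, 16L))
  expect_equal(sam$rname, c("chrF", "chrF"))
  expect_equal(sam$pos, c(701, 701))
  expect_equal(sam$cigar, c("100M", "100M"))
  expect_equal(sam$nm, c(0L, 0L))
  expect_equal(sam$mapq, c(60L, 60L)) # unique placement, no runner-up
  # reverse record stores the reverse-complemented sequence per SAM
  expect_equal(sam$seq[2], read)
})

test_that("an all-N read is reported unaligned with placeholders", {
  fx <- make_fixture()
  sam <- align_reads(fx$idx, c(nn = strrep("N", 80)))
  expect_equal(sam$flag, 4L)
  expect_equal(sam$rname, "*")
  expect_equal(sam$cigar, "*")
  expect_equal(sam$pos, 0)
  expect_error(align_reads(fx$idx, c(bad = "")), "empty")
})

test_that("an exact repeat yields MAPQ 0 but still aligns", {
  set.seed(31)
  a <- rand_genome(300)
  g <- paste0(rand_genome(200), a, rand_genome(400), a, rand_genome(200))
  idx <- build_fm_index(reference_set(g, "dup"))
  read <- substr(a, 101, 200)
  sam <- align_reads(idx, c(r = read))
  expect_equal(sam$flag, 0L)
  expect_equal(sam$mapq, 0L) # two equally good placements
  expect_true(sam$pos %in% c(301, 901))
  expect_equal(sam$pos, 301) # deterministic tie-break: lowest coordinate
})

test_that("CIGAR bookkeeping holds on noisy simulated reads", {
  ref <- simulate_genome(40000, seed = 91)
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 150, 120, sub_rate = 0.03, indel_rate = 0.01,
                        seed = 92)
  sam <- align_reads(idx, sim$reads)
  al <- sam[!bitwAnd(sam$flag, 4L), ]
  expect_gt(nrow(al), 100)
  for (i in seq_len(nrow(al))) {
    expect_equal(cigar_read_len(al$cigar[i]), nchar(al$seq[i]))
    ref_len <- cigar_ref_len(al$cigar[i])
    expect_lte(al$pos[i] + ref_len - 1, ref$seqlen[1])
    expect_gte(al$pos[i], 1)
  }
})

test_that("simulated FR pairs become proper pairs with symmetric TLEN", {
  ref <- simulate_genome(30000, seed = 41)
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 30, 80, sub_rate = 0, indel_rate = 0,
                        paired = TRUE, insert_mean = 300, insert_sd = 0,
                        seed = 42)
  r1 <- sim$reads[sim$reads$mate == 1, ]
  r2 <- sim$reads[sim$reads$mate == 2, ]
  sam <- align_read_pairs(idx, r1, r2,
                          aligner_params(min_insert = 0, max_insert = 1000))
  expect_true(all(bitwAnd(sam$flag, 1L) > 0))
  expect_true(all(bitwAnd(sam$flag, 2L) > 0))
  e1 <- sam[bitwAnd(sam$flag, 64L) > 0, ]
  e2 <- sam[bitwAnd(sam$flag, 128L) > 0, ]
  expect_equal(e1$tlen, rep(300, 30))
  expect_equal(e2$tlen, rep(-300, 30))
  expect_equal(e1$rnext, rep("=", 30))
  expect_equal(e1$pnext, e2$pos)
  expect_true(all(bitwAnd(e1$flag, 32L) > 0)) # mate on reverse strand
  expect_true(all(bitwAnd(e2$flag, 16L) > 0))

  # the same pairs fail a max_insert of 100: no proper-pair flag
  sam2 <- align_read_pairs(idx, r1, r2,
                           aligner_params(min_insert = 0, max_insert = 100))
  expect_true(all(bitwAnd(sam2$flag, 2L) == 0))
  expect_true(all(bitwAnd(sam2$flag, 4L) == 0)) # ends still aligned solo
  expect_equal(sam2$tlen, rep(0, 60))
})

test_that("pair selection equals exhaustive enumeration over candidate placements", {
  # two copies of region A and two of region B; only (A1,B1) at outer
  # distance 300 and (A2,B2) at 400 are orientation/distance-valid, and
  # the B2 copy carries two mismatches, so (A1,B1) must win
  set.seed(51)
  A <- rand_genome(100)
  B <- rand_genome(100)
  B2 <- B
  substr(B2, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(B, 20, 20))[1]
  substr(B2, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(B, 60, 60))[1]
  g <- paste0(rand_genome(150), A, strrep("T", 100), oracle_revcomp(B),
              rand_genome(2000), A, strrep("C", 200), oracle_revcomp(B2),
              rand_genome(150))
  idx <- build_fm_index(reference_set(g, "pp"))
  a1 <- 151; b1_end <- a1 + 100 + 100 + 100 - 1   # outer span 300
  a2 <- a1 + 100 + 100 + 100 + 2000                # second copy
  sam <- align_read_pairs(idx, c(p = A), c(p = B),
                          aligner_params(min_insert = 200, max_insert = 500))
  expect_true(all(bitwAnd(sam$flag, 2L) > 0))
  e1 <- sam[bitwAnd(sam$flag, 64L) > 0, ]
  expect_equal(e1$pos, a1)
  expect_equal(e1$tlen, 300)

  # exhaustive oracle over the four cross placements
  placements1 <- c(a1, a2)           # A copies, forward, edit 0
  placements2_start <- c(a1 + 200, a2 + 300) # B copies (reverse), edits 0 / 2
  edits2 <- c(0, 2)
  best <- NULL
  for (i in 1:2) for (j in 1:2) {
    dist <- placements2_start[j] + 100 - placements1[i]
    if (dist < 200 || dist > 500) next
    score <- (100 - 0) + (100 - edits2[j])
    if (is.null(best) || score > best$score) best <- list(i = i, j = j,
                                                          score = score)
  }
  expect_equal(placements1[best$i], e1$pos)
})

test_that("one unaligned end keeps the pair consistent", {
  fx <- make_fixture()
  read <- substr(fx$g, 301, 380)
  sam <- align_read_pairs(fx$idx, c(q = read), c(q = strrep("N", 80)))
  e1 <- sam[bitwAnd(sam$flag, 64L) > 0, ]
  e2 <- sam[bitwAnd(sam$flag, 128L) > 0, ]
  expect_equal(bitwAnd(e1$flag, 4L), 0L)
  expect_equal(bitwAnd(e1$flag, 8L), 8L) # mate unmapped
  expect_equal(bitwAnd(e2$flag, 4L), 4L)
  # unmapped mate is placed at its partner's coordinate per SAM convention
  expect_equal(e2$rname, "chrF")
  expect_equal(e2$pos, e1$pos)
})

test_that("SAM output passes strict validation and round-trips", {
  ref <- simulate_genome(20000, seed = 61, n_sequences = 2)
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 60, 90, sub_rate = 0.02, indel_rate = 0.005,
                        seed = 62)
  sam <- align_reads(idx, sim$reads)
  # reads drawn from both sequences of the multi-sequence reference map back
  ev <- evaluate_alignments(sam, sim$truth, tolerance = 20)
  expect_gte(ev$recall, 95)
  expect_equal(sort(unique(sam$rname[sam$rname != "*"])), c("sim1", "sim2"))
  path <- file.path(tempdir(), "out.sam")
  write_sam(sam, idx, path)

  rt <- read_sam(path)
  expect_equal(nrow(rt$records), nrow(sam))
  expect_equal(rt$records$qname, sam$qname)
  expect_equal(rt$records$flag, sam$flag)
  expect_equal(rt$records$pos, sam$pos)
  expect_equal(rt$records$cigar, sam$cigar)
  expect_equal(rt$records$nm, sam$nm)
  expect_equal(sum(grepl("^@SQ", rt$header)), 2)

  # strict validation by an external SAM parser
  st <- Sys.which("samtools")
  if (nzchar(st)) {
    out <- suppressWarnings(
      system2(st, c("view", "-c", path), stdout = TRUE, stderr = TRUE))
    expect_null(attr(out, "status"))
    expect_equal(as.integer(out[length(out)]), nrow(sam))
  } else {
    # fall back to Rsamtools if the CLI is unavailable
    bam <- Rsamtools::asBam(path, file.path(tempdir(), "out"),
                            overwrite = TRUE)
    expect_true(file.exists(bam))
  }
})

test_that("1 worker and N workers produce identical sorted records", {
  ref <- simulate_genome(25000, seed = 71)
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 80, 100, sub_rate = 0.02, seed = 72)
  s1 <- align_reads(idx, sim$reads, aligner_params(workers = 1))
  s3 <- align_reads(idx, sim$reads, aligner_params(workers = 3))
  expect_equal(sorted_records(s1), sorted_records(s3))
})

test_that("alignment is deterministic across repeated runs", {
  ref <- simulate_genome(25000, seed = 81)
  idx <- build_fm_index(ref)
  sim <- simulate_reads(ref, 50, 100, sub_rate = 0.04, indel_rate = 0.01,
                        seed = 82)
  s1 <- align_reads(idx, sim$reads)
  s2 <- align_reads(idx, sim$reads)
  expect_identical(s1, s2)
})

test_that("FASTQ round-trips through write and read", {
  reads <- data.frame(id = c("a", "b"), seq = c("ACGTACGT", "GGGTTTCC"),
                      qual = c("IIIIIIII", "HHHHHHHH"),
                      stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "reads.fq.gz")
  write_fastq(reads, path)
  rt <- read_fastq(path)
  expect_equal(rt$id, reads$id)
  expect_equal(rt$seq, reads$seq)
  expect_equal(rt$qual, reads$qual)
})
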