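test_that("alignment identity counts every edited column", {
  expect_equal(alignment_identity(100, 0, 0, 0), 1.0)
  expect_equal(alignment_identity(95, 5, 0, 0), 0.95)
  expect_equal(alignment_identity(192, 6, 1, 1), 0.96)
  expect_error(alignment_identity(0, 0, 0, 0), "zero")
})

test_that("SAM loader reproduces the simulator's ground truth", {
  dir <- withr::local_tempdir()
  sim <- make_small_sim(n_reads = 120, seed = 201)
  sam <- file.path(dir, "truth.sam")
  tsv <- file.path(dir, "truth.tsv")
  write_truth_sam(sim, sam)
  write_truth_table(sim, tsv)
  reads <- load_alignments(sam, sim$strain_set$ancestor)
  truth <- read.delim(tsv)
  m <- match(truth$read_id, reads$read_id)
  expect_false(anyNA(m))
  expect_equal(reads$identity[m], truth$identity_anc, tolerance = 1e-12)
  expect_equal(reads$n_ins[m], truth$n_ins)
  expect_equal(reads$n_del[m], truth$n_del)
  expect_equal(reads$n_mismatch[m], truth$n_mismatch_anc)
  expect_equal(reads$ref_start[m], truth$start)
})

test_that("loader re-derives mismatches from the reference when NM is absent", {
  dir <- withr::local_tempdir()
  sim <- make_small_sim(n_reads = 40, seed = 207)
  sam <- file.path(dir, "truth.sam")
  write_truth_sam(sim, sam)
  lines <- readLines(sam)
  stripped <- sub("\tNM:i:\\d+$", "", lines)
  sam2 <- file.path(dir, "nonm.sam")
  writeLines(stripped, sam2)
  a <- load_alignments(sam, sim$strain_set$ancestor)
  b <- load_alignments(sam2, sim$strain_set$ancestor)
  m <- match(a$read_id, b$read_id)
  expect_equal(a$n_mismatch, b$n_mismatch[m])
  expect_equal(a$identity, b$identity[m], tolerance = 1e-12)
})

test_that("loader handles empty files and unknown references", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:ancestor\tLN:1000"), empty)
  anc <- generate_ancestor(1000, seed = 1)
  out <- load_alignments(empty, anc)
  expect_s3_class(out, "recruited_reads")
  expect_identical(nrow(out), 0L)

  sim <- make_small_sim(n_reads = 5, seed = 208)
  sam <- file.path(dir, "t.sam")
  write_truth_sam(sim, sam)
  other <- generate_ancestor(8000, seed = 9, id = "other_ref")
  expect_error(load_alignments(sam, other), "read_0000001")
})

test_that("identity filter is boundary-inclusive and idempotent", {
  df <- data.frame(
    read_id = c("a", "b", "c"), ref_id = "r", ref_start = c(5L, 9L, 2L),
    cigar = "100M", seq = strrep("A", 100),
    n_match = c(94L, 95L, 99L), n_mismatch = c(6L, 5L, 1L),
    n_ins = 0L, n_del = 0L, identity = c(0.94, 0.95, 0.99),
    mate_ref = NA_character_)
  class(df) <- c("recruited_reads", "data.frame")
  kept <- apply_filters(df, min_identity = 0.95)
  expect_identical(sort(kept$read_id), c("b", "c"))
  expect_identical(apply_filters(kept, min_identity = 0.95), kept)
  expect_identical(nrow(apply_filters(df, min_identity = 0)), 3L)
  # Unpaired reads pass the non-discordant filter vacuously.
  expect_identical(nrow(apply_filters(df, min_identity = 0,
                                      pairing = "non_discordant")), 3L)
})

test_that("best-match selection keeps one alignment per read", {
  df <- data.frame(
    read_id = c("a", "a", "a", "b"), ref_id = c("r2", "r1", "r1", "r1"),
    ref_start = c(10L, 30L, 7L, 0L), cigar = "50M", seq = strrep("A", 50),
    n_match = c(50L, 48L, 50L, 50L), n_mismatch = c(0L, 2L, 0L, 0L),
    n_ins = 0L, n_del = 0L, identity = c(1, 0.96, 1, 1),
    mate_ref = NA_character_)
  class(df) <- c("recruited_reads", "data.frame")
  kept <- apply_filters(df, min_identity = 0, best_match = TRUE)
  expect_identical(nrow(kept), 2L)
  a <- kept[kept$read_id == "a", ]
  expect_identical(a$identity, 1)       # highest identity wins
  expect_identical(a$ref_start, 7L)     # tie broken by leftmost start
})

test_that("discordant mates are removed, concordant ones kept", {
  df <- data.frame(
    read_id = c("p1", "p2"), ref_id = c("r1", "r1"), ref_start = c(0L, 10L),
    cigar = "50M", seq = strrep("A", 50), n_match = 50L, n_mismatch = 0L,
    n_ins = 0L, n_del = 0L, identity = 1, mate_ref = c("r1", "r9"))
  class(df) <- c("recruited_reads", "data.frame")
  kept <- apply_filters(df, min_identity = 0)
  expect_identical(kept$read_id, "p1")
  expect_identical(nrow(apply_filters(df, min_identity = 0,
                                      pairing = "none")), 2L)
})

test_that("pileup counts behave linearly and ignore read order", {
  anc <- generate_ancestor(1000, seed = 11)
  one <- data.frame(
    read_id = "r1", ref_id = anc$id, ref_start = 10L, cigar = "150M",
    seq = substring(anc$sequence, 11, 160), n_match = 150L, n_mismatch = 0L,
    n_ins = 0L, n_del = 0L, identity = 1, mate_ref = NA_character_)
  class(one) <- c("recruited_reads", "data.frame")
  pu <- build_pileup(one, anc)
  depth <- colSums(pu$counts)
  expect_identical(sum(depth), 150)
  expect_true(all(depth[11:160] == 1))
  expect_true(all(depth[-(11:160)] == 0))

  two <- rbind(one, one)
  class(two) <- c("recruited_reads", "data.frame")
  expect_equal(build_pileup(two, anc)$counts, 2 * pu$counts)

  sim <- make_small_sim(n_reads = 30, seed = 301)
  rr <- local({
    dir <- withr::local_tempdir()
    sam <- file.path(dir, "t.sam")
    write_truth_sam(sim, sam)
    load_alignments(sam, sim$strain_set$ancestor)
  })
  shuffled <- rr[rev(seq_len(nrow(rr))), ]
  class(shuffled) <- c("recruited_reads", "data.frame")
  expect_equal(build_pileup(rr, sim$strain_set$ancestor)$counts,
               build_pileup(shuffled, sim$strain_set$ancestor)$counts)
})

test_that("pileup equals the pure-loop oracle and conserves aligned columns", {
  sim <- make_small_sim(n_reads = 50, seed = 302)
  anc <- sim$strain_set$ancestor
  seqs <- sim_read_sequences(sim, orientation = "reference")
  cig <- microdepth:::sim_cigars(sim)
  expected <- oracle_pileup(unname(seqs), sim$reads$start - 1L, cig,
                            anc$length)
  fast <- build_pileup(sim)
  expect_equal(fast$counts, expected, ignore_attr = TRUE)
  rr <- data.frame(
    read_id = names(seqs), ref_id = anc$id, ref_start = sim$reads$start - 1L,
    cigar = cig, seq = unname(seqs),
    n_match = sim$read_length - sim$reads$n_del - sim$reads$n_mm_anc,
    n_mismatch = sim$reads$n_mm_anc, n_ins = sim$reads$n_ins,
    n_del = sim$reads$n_del, identity = sim$reads$identity_anc,
    mate_ref = NA_character_)
  class(rr) <- c("recruited_reads", "data.frame")
  generic <- build_pileup(rr, anc)
  expect_equal(generic$counts, expected, ignore_attr = TRUE)
  # Conservation: total counts == total aligned match+mismatch columns.
  expect_equal(sum(fast$counts),
               sum(sim$read_length - sim$reads$n_del))
})

test_that("reads overhanging the reference end are rejected", {
  anc <- generate_ancestor(1000, seed = 12)
  bad <- data.frame(
    read_id = "r1", ref_id = anc$id, ref_start = 950L, cigar = "100M",
    seq = strrep("A", 100), n_match = 100L, n_mismatch = 0L, n_ins = 0L,
    n_del = 0L, identity = 1, mate_ref = NA_character_)
  class(bad) <- c("recruited_reads", "data.frame")
  expect_error(build_pileup(bad, anc), "overhang")
})
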