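test_that("ancestor generation honours length, GC target and seed", {
  g <- generate_ancestor(10000, gc_fraction = 0.5, seed = 1)
  expect_s3_class(g, "genome")
  expect_identical(g$length, 10000L)
  expect_identical(nchar(g$sequence), 10000L)
  gc <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)

  at_only <- generate_ancestor(10000, gc_fraction = 0, seed = 1)
  expect_true(all(strsplit(at_only$sequence, "")[[1]] %in% c("A", "T")))

  expect_identical(generate_ancestor(5000, 0.4, seed = 7)$sequence,
                   generate_ancestor(5000, 0.4, seed = 7)$sequence)
  expect_false(identical(generate_ancestor(5000, 0.4, seed = 7)$sequence,
                         generate_ancestor(5000, 0.4, seed = 8)$sequence))

  expect_error(generate_ancestor(500), "length")
  expect_error(generate_ancestor(10000, gc_fraction = 1.2), "gc_fraction")
})

test_that("strain sets carry exact edit lists and pairwise ANI", {
  anc <- generate_ancestor(100000, seed = 3)

  solo <- derive_strain_set(anc, 1, seed = 4)
  expect_identical(solo$strains[[1]]$sequence, anc$sequence)
  expect_equal(solo$pairwise_ani, matrix(1, 1, 1))

  two <- derive_strain_set(anc, 2, c(0.01, 0.01), seed = 5)
  ndiff <- sum(strsplit(anc$sequence, "")[[1]] !=
               strsplit(two$strains[[2]]$sequence, "")[[1]])
  expect_identical(ndiff, 1000L)
  expect_equal(two$pairwise_ani[1, 2], 0.99)

  # Strains must be reconstructable from their edit lists.
  ed <- two$edits[[2]]
  r <- charToRaw(anc$sequence)
  r[ed$pos] <- charToRaw(paste0(ed$base, collapse = ""))
  expect_identical(rawToChar(r), two$strains[[2]]$sequence)

  expect_error(derive_strain_set(anc, 2, c(0, 0.06)), "95%")
})

test_that("pairwise ANI from edit lists matches brute-force Hamming identity", {
  anc <- generate_ancestor(20000, seed = 6)
  ss <- derive_strain_set(anc, 4, c(0, 0.0249), seed = 7)
  for (j in 1:4) for (k in 1:4) {
    if (k <= j) next
    h <- oracle_hamming_identity(ss$strains[[j]]$sequence,
                                 ss$strains[[k]]$sequence)
    expect_equal(ss$pairwise_ani[j, k], h)
    expect_gte(ss$pairwise_ani[j, k], 0.9502)
    expect_lte(ss$pairwise_ani[j, k], 1)
  }
})

test_that("log-normal abundances form a simplex with log-normal shape", {
  expect_equal(sample_lognormal_abundances(1, 1, seed = 1), 1.0)

  w <- sample_lognormal_abundances(5, 1, seed = 7)
  expect_length(w, 5)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  lw <- log(sample_lognormal_abundances(1000, 1, seed = 11))
  z <- lw - mean(lw)
  skew <- mean(z^3) / mean(z^2)^1.5
  expect_lt(abs(skew), 0.25)

  expect_error(sample_lognormal_abundances(5, sigma = 0), "sigma")
})

test_that("error-free reads are exact genome substrings with identity 1", {
  anc <- generate_ancestor(20000, seed = 21)
  ss <- derive_strain_set(anc, 1, seed = 21)
  sim <- simulate_metagenome(ss, n_reads = 300, read_length = 150, seed = 22)
  expect_true(all(sim$reads$identity == 1))
  expect_true(all(sim$reads$identity_anc == 1))
  seqs <- sim_read_sequences(sim, orientation = "sequencing")
  g <- anc$sequence
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  hits <- vapply(seqs, function(s) grepl(s, g, fixed = TRUE) ||
                                    grepl(s, grc, fixed = TRUE), TRUE)
  expect_true(all(hits))
})

test_that("per-base event rates match the preset probabilities", {
  anc <- generate_ancestor(50000, seed = 31)
  ss <- derive_strain_set(anc, 1, seed = 31)
  n <- 20000L; Lr <- 150L
  sim <- simulate_metagenome(ss, n_reads = n, read_length = Lr,
                             error_profile = error_profile("q20"), seed = 32)
  ev <- sim$events
  mid <- ev$off > 10 & ev$off <= Lr - 10
  n_mid_bases <- as.numeric(n) * (Lr - 20)
  for (chk in list(list(p = 0.006, k = sum(ev$type == 3 & mid)),
                   list(p = 0.001, k = sum(ev$type == 2 & mid)),
                   list(p = 0.001, k = sum(ev$type == 1 & mid)))) {
    se <- sqrt(chk$p * (1 - chk$p) / n_mid_bases)
    expect_lt(abs(chk$k / n_mid_bases - chk$p), 3 * se)
  }
  # Mean per-read identity ~ 1 - (p_ins + p_del + p_mm) away from windows.
  expect_lt(abs(mean(sim$reads$identity) - 0.992), 0.001)
})

test_that("strain and error edits compose into the emitted reads (oracle)", {
  sim <- make_small_sim(n_reads = 80, seed = 101)
  seqs <- sim_read_sequences(sim, orientation = "reference")
  anc_seq <- sim$strain_set$ancestor$sequence
  for (i in seq_len(sim$n_reads)) {
    rd <- sim$reads[i, ]
    rebuilt <- oracle_build_read(
      anc_seq, sim$strain_set$edits[[rd$strain]], rd$start,
      sim$read_length, sim$events[sim$events$read == i, , drop = FALSE])
    expect_identical(unname(seqs[i]), rebuilt)
  }
  # Sequencing orientation reverse-complements minus-strand reads.
  fq <- sim_read_sequences(sim, orientation = "sequencing")
  neg <- sim$reads$strand == "-"
  expect_identical(
    unname(fq[neg]),
    unname(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))))
  expect_identical(unname(fq[!neg]), unname(seqs[!neg]))
})

test_that("simulation output files are byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  anc <- generate_ancestor(10000, seed = 51)
  ss <- derive_strain_set(anc, 2, c(0.01, 0.02), seed = 52)
  for (run in c("a", "b"))
    simulate_metagenome(ss, c(0.6, 0.4), n_reads = 100, read_length = 100,
                        error_profile = error_profile("q20"), seed = 53,
                        out_prefix = file.path(dir, run))
  for (ext in c(".fastq", ".truth.sam", ".truth.tsv"))
    expect_identical(readLines(file.path(dir, paste0("a", ext))),
                     readLines(file.path(dir, paste0("b", ext))))
  simulate_metagenome(ss, c(0.6, 0.4), n_reads = 100, read_length = 100,
                      error_profile = error_profile("q20"), seed = 54,
                      out_prefix = file.path(dir, "c"))
  expect_false(identical(readLines(file.path(dir, "a.fastq")),
                         readLines(file.path(dir, "c.fastq"))))
})

test_that("empirical strain shares recover the abundance profile", {
  anc <- generate_ancestor(20000, seed = 61)
  ss <- derive_strain_set(anc, 5, c(0.005, 0.02), seed = 62)
  w <- sample_lognormal_abundances(5, 1, seed = 63)
  n <- 100000L
  sim <- simulate_metagenome(ss, w, n_reads = n, read_length = 100, seed = 64)
  share <- tabulate(sim$reads$strain, 5) / n
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(share - w) < 3 * se))
})

test_that("simulator rejects degenerate inputs", {
  anc <- generate_ancestor(5000, seed = 71)
  ss <- derive_strain_set(anc, 2, c(0.01, 0.01), seed = 72)
  expect_error(simulate_metagenome(ss, n_reads = 0), "n_reads")
  expect_error(simulate_metagenome(ss, abundances = c(1, 1, 1), n_reads = 10),
               "match")
  expect_error(simulate_metagenome(ss, n_reads = 10, read_length = 6000),
               "read_length")
})

test_that("shredding fragments reads and conserves bases", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "long.fastq")
  writeLines(c("@long1", strrep("ACGTA", 130),          # 650 bp
               "+", strrep("I", 650),
               "@short1", strrep("AC", 40),             # 80 bp
               "+", strrep("I", 80)), fq)
  frags <- shred_reads(fq, fragment_length = 200)
  w <- Biostrings::width(frags)
  expect_identical(w[1:4], c(200L, 200L, 200L, 50L))
  expect_identical(w[5], 80L)
  expect_identical(sum(w), 650L + 80L)
  expect_identical(paste0(as.character(frags[1:4]), collapse = ""),
                   strrep("ACGTA", 130))
  kept <- shred_reads(fq, fragment_length = 200, drop_short = TRUE)
  expect_identical(length(kept), 3L)
  out <- file.path(dir, "frag.fastq")
  shred_reads(fq, output = out, fragment_length = 200)
  expect_identical(length(Biostrings::readDNAStringSet(out, format = "fastq")),
                   5L)
})
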