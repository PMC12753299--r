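# Independent pure-loop oracles. These deliberately avoid the package's
# vectorized code paths: everything is computed character by character.

# Tally A/C/G/T counts per reference position from reference-oriented read
# sequences + CIGAR strings, walking every column in an explicit loop.
oracle_pileup <- function(seqs, starts0, cigars, ref_length) {
  counts <- matrix(0L, nrow = 4, ncol = ref_length,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    ops <- regmatches(cigars[i], gregexpr("\\d+[MIDNS]", cigars[i]))[[1]]
    rpos <- starts0[i] + 1L
    qpos <- 1L
    for (tok in ops) {
      len <- as.integer(sub(".$", "", tok))
      op <- substring(tok, nchar(tok))
      if (op == "M") {
        for (j in seq_len(len)) {
          b <- substring(seqs[i], qpos, qpos)
          k <- match(b, c("A", "C", "G", "T"))
          if (!is.na(k)) counts[k, rpos] <- counts[k, rpos] + 1L
          qpos <- qpos + 1L
          rpos <- rpos + 1L
        }
      } else if (op == "I" || op == "S") {
        qpos <- qpos + len
      } else if (op == "D" || op == "N") {
        rpos <- rpos + len
      }
    }
  }
  counts
}

# Site diversity by direct summation.
oracle_site_pi <- function(counts) {
  d <- 0
  for (c_ in counts) d <- d + c_
  s <- 0
  for (c_ in counts) s <- s + (c_ / d)^2
  1 - s
}

# Genome pi: loop positions, average site pi over depth >= min_cov.
oracle_genome_pi <- function(counts, min_cov = 5) {
  tot <- 0; n <- 0
  for (p in seq_len(ncol(counts))) {
    d <- sum(counts[, p])
    if (d >= min_cov) {
      tot <- tot + oracle_site_pi(counts[, p])
      n <- n + 1
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# Hamming identity between equal-length sequences, char by char.
oracle_hamming_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  nd <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) nd <- nd + 1L
  1 - nd / length(a)
}

# Rebuild one simulated read from the ancestor sequence, the strain's
# substitution list and the read's error events (composition oracle).
oracle_build_read <- function(anc_seq, strain_edits, start, read_length,
                              events) {
  chars <- strsplit(substring(anc_seq, start, start + read_length - 1L),
                    "")[[1]]
  if (nrow(strain_edits)) {
    for (j in seq_len(nrow(strain_edits))) {
      off <- strain_edits$pos[j] - start + 1L
      if (off >= 1L && off <= read_length) chars[off] <- strain_edits$base[j]
    }
  }
  if (nrow(events)) {
    ev <- events[order(events$off), , drop = FALSE]
    for (j in seq_len(nrow(ev)))            # mismatches first (no shifts)
      if (ev$type[j] == 3L) chars[ev$off[j]] <- c("A", "C", "G", "T")[ev$new[j]]
    for (j in rev(seq_len(nrow(ev)))) {      # indels right to left
      if (ev$type[j] == 2L) chars <- chars[-ev$off[j]]
      else if (ev$type[j] == 1L)
        chars <- append(chars, c("A", "C", "G", "T")[ev$new[j]],
                        after = ev$off[j])
    }
  }
  paste0(chars, collapse = "")
}

# Small reusable fixture: a 3-strain Q20 community.
make_small_sim <- function(n_reads = 60, seed = 42, profile = "q20",
                           n_strains = 3, genome_length = 8000,
                           read_length = 120) {
  anc <- generate_ancestor(genome_length, seed = seed)
  ss <- derive_strain_set(anc, n_strains, c(0.005, 0.02), seed = seed + 1)
  ab <- if (n_strains > 1)
    sample_lognormal_abundances(n_strains, 1, seed = seed + 2) else 1
  simulate_metagenome(ss, ab, n_reads = n_reads, read_length = read_length,
                      error_profile = error_profile(profile),
                      seed = seed + 3)
}
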