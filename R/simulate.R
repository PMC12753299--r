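#' Simulate a strain-mixture metagenome with full ground truth
#'
#' Draws reads from a set of conspecific strains: each read's source strain is
#' sampled from the relative abundances, its start uniformly along the strain
#' and its strand uniformly. Sequencing errors are then applied per base: every
#' base independently suffers at most one event (insertion / deletion /
#' mismatch) with the profile's probabilities, the elevated mismatch rates
#' applying only within the start/end windows. A mismatch replaces the base by
#' one of the 3 alternatives uniformly; an insertion adds one uniform base
#' after the position; a deletion removes the base.
#'
#' The returned object keeps the complete ground truth (source strain, start,
#' strand, per-read edit list, identity to the source strain and to the
#' ancestor), which downstream profiling consumes directly; FASTQ, truth SAM
#' (alignments expressed in ancestor coordinates, with strain substitutions
#' and error edits composed into CIGAR/NM) and a TSV truth table can be
#' written with [write_fastq()], [write_truth_sam()] and
#' [write_truth_table()], or all at once via `out_prefix`.
#'
#' @param strain_set A `strain_set` from [derive_strain_set()].
#' @param abundances Numeric vector of relative abundances, one per strain
#'   (normalized internally); `NULL` for equal weights.
#' @param n_reads Number of reads (>= 1).
#' @param read_length Read length in bp (<= genome length); 150 by default.
#' @param error_profile An [error_profile()].
#' @param seed Integer seed; identical inputs give byte-identical outputs.
#' @param out_prefix If non-`NULL`, writes `<prefix>.fastq`,
#'   `<prefix>.truth.sam` and `<prefix>.truth.tsv`.
#' @return An object of class `sim_metagenome`.
#' @examples
#' anc <- generate_ancestor(5000, seed = 1)
#' ss <- derive_strain_set(anc, 2, c(0.01, 0.01), seed = 2)
#' sim <- simulate_metagenome(ss, n_reads = 200, read_length = 100,
#'                            error_profile = error_profile("q20"), seed = 3)
#' sim
#' @export
simulate_metagenome <- function(strain_set, abundances = NULL, n_reads,
                                read_length = 150L,
                                error_profile = microdepth::error_profile("none"),
                                seed = 1L, out_prefix = NULL) {
  if (!inherits(strain_set, "strain_set") || length(strain_set$strains) == 0L)
    stop("'strain_set' must be a non-empty strain_set")
  stopifnot_scalar_num(n_reads, "n_reads", lower = 1, integer = TRUE)
  n_strains <- length(strain_set$strains)
  L <- strain_set$ancestor$length
  Lr <- as.integer(read_length)
  if (Lr < 1L || Lr > L)
    stop("'read_length' must be in [1, genome length]")
  if (is.null(abundances)) abundances <- rep(1 / n_strains, n_strains)
  if (length(abundances) != n_strains)
    stop("'abundances' length (", length(abundances),
         ") does not match number of strains (", n_strains, ")")
  if (any(abundances <= 0)) stop("abundances must all be positive")
  w <- abundances / sum(abundances)
  stopifnot(inherits(error_profile, "error_profile"))
  ep <- error_profile
  anc_code <- seq_to_code(strain_set$ancestor$sequence)

  st <- withr::with_seed(seed, {
    strain <- sample.int(n_strains, n_reads, replace = TRUE, prob = w)
    start <- sample.int(L - Lr + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    ev <- .draw_error_events(n_reads, Lr, ep)
    list(strain = strain, start = start, strand = strand, ev = ev)
  })
  ev <- st$ev

  # Resolve each event's template base (the source strain's base at the
  # reference position) and whether the position is a strain substitution.
  ev$ref_pos <- st$start[ev$read] + ev$off - 1L
  ev$tmpl <- anc_code[ev$ref_pos]
  ev$is_sub <- logical(nrow(ev))
  ev_strain <- st$strain[ev$read]
  for (k in unique(ev_strain)) {
    ed <- strain_set$edits[[k]]
    if (nrow(ed) == 0L) next
    sel <- which(ev_strain == k)
    m <- match(ev$ref_pos[sel], ed$pos)
    hit <- !is.na(m)
    ev$tmpl[sel[hit]] <- ed$code[m[hit]]
    ev$is_sub[sel[hit]] <- TRUE
  }
  # Replacement / inserted bases (seeded continuation of the same stream).
  ev$new <- rep(NA_integer_, nrow(ev))
  ev <- withr::with_seed(child_seed(seed, "bases"), {
    is_mm <- ev$type == 3L
    is_ins <- ev$type == 1L
    ev$new[is_mm] <- ((ev$tmpl[is_mm] - 1L +
                       sample.int(3L, sum(is_mm), replace = TRUE)) %% 4L) + 1L
    ev$new[is_ins] <- sample.int(4L, sum(is_ins), replace = TRUE)
    ev
  })
  ev <- ev[order(ev$read, ev$off), , drop = FALSE]
  rownames(ev) <- NULL

  n_mm  <- tabulate(ev$read[ev$type == 3L], n_reads)
  n_ins <- tabulate(ev$read[ev$type == 1L], n_reads)
  n_del <- tabulate(ev$read[ev$type == 2L], n_reads)

  # Substitution sites of the source strain covered by each read.
  subs_covered <- integer(n_reads)
  for (k in seq_len(n_strains)) {
    ed <- strain_set$edits[[k]]
    if (nrow(ed) == 0L) next
    idx <- which(st$strain == k)
    if (!length(idx)) next
    subs_covered[idx] <- findInterval(st$start[idx] + Lr - 1L, ed$pos) -
      findInterval(st$start[idx] - 1L, ed$pos)
  }
  # Mismatch columns vs the ancestor: strain substitutions covered, minus
  # those erased by a deletion or reverted by an error mismatch, plus error
  # mismatches at non-substituted positions.
  plus  <- ev$type == 3L & !ev$is_sub
  minus <- (ev$type == 2L & ev$is_sub) |
           (ev$type == 3L & ev$is_sub & ev$new == anc_code[ev$ref_pos])
  n_mm_anc <- subs_covered + tabulate(ev$read[plus], n_reads) -
    tabulate(ev$read[minus], n_reads)

  reads <- data.frame(
    strain = st$strain, start = st$start, strand = st$strand,
    n_mm = n_mm, n_ins = n_ins, n_del = n_del, n_mm_anc = n_mm_anc,
    identity = (Lr - n_del - n_mm) / (Lr + n_ins),
    identity_anc = (Lr - n_del - n_mm_anc) / (Lr + n_ins))

  sim <- structure(
    list(strain_set = strain_set, reads = reads, events = ev,
         read_length = Lr, n_reads = as.integer(n_reads),
         error_profile = ep, seed = as.integer(seed),
         anc_code = anc_code, active = seq_len(n_reads)),
    class = "sim_metagenome")

  if (!is.null(out_prefix)) {
    write_fastq(sim, paste0(out_prefix, ".fastq"))
    write_truth_sam(sim, paste0(out_prefix, ".truth.sam"))
    write_truth_table(sim, paste0(out_prefix, ".truth.tsv"))
  }
  sim
}

# One categorical error event per (read, base) pair, drawn exactly yet fully
# vectorized: within each read segment (start window / middle / end window)
# the number of affected pairs is Binomial(n_reads * segment_length, p_total)
# and affected pairs are sampled without replacement.
.draw_error_events <- function(n_reads, Lr, ep) {
  a <- min(ep$start_window, Lr)
  b <- max(Lr - ep$end_window + 1L, a + 1L)
  segs <- list(
    list(off0 = 0L, len = a, extra = ep$p_mm_start),
    list(off0 = a, len = b - 1L - a, extra = 0),
    list(off0 = b - 1L, len = Lr - b + 1L, extra = ep$p_mm_end))
  out <- list()
  for (sg in segs) {
    if (sg$len <= 0L) next
    p <- c(ep$p_ins, ep$p_del, ep$p_mm + sg$extra)
    p_tot <- sum(p)
    if (p_tot <= 0) next
    npairs <- as.numeric(n_reads) * sg$len
    m <- rbinom_big(npairs, p_tot)
    if (m == 0L) next
    idx <- sample.int(npairs, m)
    out[[length(out) + 1L]] <- data.frame(
      read = as.integer((idx - 1) %/% sg$len + 1),
      off = as.integer(sg$off0 + (idx - 1) %% sg$len + 1),
      type = sample.int(3L, m, replace = TRUE, prob = p / p_tot))
  }
  if (!length(out))
    return(data.frame(read = integer(), off = integer(), type = integer()))
  do.call(rbind, out)
}

#' @export
print.sim_metagenome <- function(x, ...) {
  cat(sprintf(
    "<sim_metagenome> %d reads x %d bp from %d strain(s) of %d bp (%s errors)\n",
    x$n_reads, x$read_length, length(x$strain_set$strains),
    x$strain_set$ancestor$length, x$error_profile$name))
  if (length(x$active) < x$n_reads)
    cat(sprintf("  active subset: %d reads\n", length(x$active)))
  cat(sprintf("  mean identity to ancestor: %.4f\n",
              mean(x$reads$identity_anc[x$active])))
  invisible(x)
}

read_ids <- function(sim, idx = sim$active) {
  sprintf("read_%07d", idx)
}

#' Materialize simulated read sequences
#'
#' Rebuilds each read's nucleotide sequence from its source strain and edit
#' list. `orientation = "reference"` returns sequences as aligned to the
#' forward reference strand (as stored in SAM); `"sequencing"` returns the
#' as-sequenced sequence (reverse-complemented for minus-strand reads, as
#' written to FASTQ).
#'
#' @param sim A `sim_metagenome`.
#' @param idx Read indices (defaults to the active subset).
#' @param orientation `"reference"` or `"sequencing"`.
#' @return Character vector of sequences named by read id.
#' @export
sim_read_sequences <- function(sim, idx = sim$active,
                               orientation = c("reference", "sequencing")) {
  orientation <- match.arg(orientation)
  rd <- sim$reads
  Lr <- sim$read_length
  seqs <- character(length(idx))
  for (k in unique(rd$strain[idx])) {
    sel <- which(rd$strain[idx] == k)
    s <- rd$start[idx[sel]]
    seqs[sel] <- substring(sim$strain_set$strains[[k]]$sequence, s, s + Lr - 1L)
  }
  ev <- sim$events
  ev <- ev[ev$read %in% idx, , drop = FALSE]
  if (nrow(ev)) {
    pos_in_idx <- match(ev$read, idx)
    for (grp in split(seq_len(nrow(ev)), pos_in_idx)) {
      i <- pos_in_idx[grp[1]]
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      rows <- ev[grp, , drop = FALSE]
      mm <- rows[rows$type == 3L, , drop = FALSE]
      chars[mm$off] <- .BASES[mm$new]
      indel <- rows[rows$type != 3L, , drop = FALSE]
      if (nrow(indel)) {
        indel <- indel[order(-indel$off), , drop = FALSE]
        for (j in seq_len(nrow(indel))) {
          if (indel$type[j] == 2L) chars <- chars[-indel$off[j]]
          else chars <- append(chars, .BASES[indel$new[j]],
                               after = indel$off[j])
        }
      }
      seqs[i] <- paste0(chars, collapse = "")
    }
  }
  if (orientation == "sequencing") {
    neg <- rd$strand[idx] == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
  }
  names(seqs) <- read_ids(sim, idx)
  seqs
}

# CIGAR strings vs the ancestor (full template span; "<Lr>M" when no indels).
sim_cigars <- function(sim, idx = sim$active) {
  Lr <- sim$read_length
  out <- rep(sprintf("%dM", Lr), length(idx))
  ev <- sim$events
  ev <- ev[ev$read %in% idx & ev$type != 3L, , drop = FALSE]
  if (!nrow(ev)) return(out)
  pos_in_idx <- match(ev$read, idx)
  for (grp in split(seq_len(nrow(ev)), pos_in_idx)) {
    rows <- ev[grp, , drop = FALSE]
    rows <- rows[order(rows$off), , drop = FALSE]
    ops <- character(0); lens <- integer(0)
    cur <- 1L
    for (j in seq_len(nrow(rows))) {
      o <- rows$off[j]
      if (rows$type[j] == 2L) {          # deletion consumes template base o
        mlen <- o - cur
        if (mlen > 0L) { ops <- c(ops, "M"); lens <- c(lens, mlen) }
        ops <- c(ops, "D"); lens <- c(lens, 1L)
        cur <- o + 1L
      } else {                           # insertion after template base o
        mlen <- o - cur + 1L
        if (mlen > 0L) { ops <- c(ops, "M"); lens <- c(lens, mlen) }
        ops <- c(ops, "I"); lens <- c(lens, 1L)
        cur <- o + 1L
      }
    }
    if (Lr - cur + 1L > 0L) { ops <- c(ops, "M"); lens <- c(lens, Lr - cur + 1L) }
    r <- rle(ops)
    lens2 <- vapply(split(lens, rep(seq_along(r$lengths), r$lengths)), sum, 0L)
    out[pos_in_idx[grp[1]]] <- paste0(lens2, r$values, collapse = "")
  }
  out
}

#' Write simulated reads to FASTQ
#'
#' Sequences are written in sequencing orientation with a constant placeholder
#' quality string (`I`).
#'
#' @param sim A `sim_metagenome`.
#' @param path Output FASTQ path.
#' @param idx Read indices (defaults to the active subset).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path, idx = sim$active) {
  seqs <- sim_read_sequences(sim, idx, orientation = "sequencing")
  ss <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(ss)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write truth alignments to SAM
#'
#' Every read is written as an alignment to the ancestor genome: strain
#' substitutions and simulated error edits are composed into the CIGAR and the
#' `NM` tag, so the file is a ground-truth recruitment that needs no mapper.
#'
#' @inheritParams write_fastq
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, path, idx = sim$active) {
  anc <- sim$strain_set$ancestor
  rd <- sim$reads
  seqs <- sim_read_sequences(sim, idx, orientation = "reference")
  cig <- sim_cigars(sim, idx)
  nm <- rd$n_mm_anc[idx] + rd$n_ins[idx] + rd$n_del[idx]
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", anc$id, anc$length),
    "@PG\tID:microdepth\tPN:microdepth",
    paste(read_ids(sim, idx),
          ifelse(rd$strand[idx] == "-", 16L, 0L),
          anc$id, rd$start[idx], 60L, cig, "*", 0L, 0L,
          seqs, strrep("I", nchar(seqs)),
          sprintf("NM:i:%d", nm), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the ground-truth read table to TSV
#'
#' Columns: `read_id`, `strain`, `start` (0-based on the source strain),
#' `strand`, `n_mismatch`, `n_ins`, `n_del`, `true_identity` (vs the source
#' strain), plus `n_mismatch_anc` and `identity_anc` (vs the ancestor, i.e.
#' the identity a recruiter would see against the species reference).
#'
#' @inheritParams write_fastq
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path, idx = sim$active) {
  rd <- sim$reads[idx, , drop = FALSE]
  df <- data.frame(
    read_id = read_ids(sim, idx),
    strain = vapply(sim$strain_set$strains, `[[`, "", "id")[rd$strain],
    start = rd$start - 1L, strand = rd$strand,
    n_mismatch = rd$n_mm, n_ins = rd$n_ins, n_del = rd$n_del,
    true_identity = rd$identity,
    n_mismatch_anc = rd$n_mm_anc, identity_anc = rd$identity_anc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shred reads into fixed-length fragments
#'
#' Splits each input read into consecutive non-overlapping fragments of
#' `fragment_length` bp (the standard preprocessing that makes long reads
#' comparable to short-read recruitments). The terminal fragment, when shorter
#' than `fragment_length`, is kept by default.
#'
#' @param input FASTQ path or a `QualityScaledDNAStringSet`.
#' @param output Optional output FASTQ path.
#' @param fragment_length Fragment size in bp (default 200).
#' @param drop_short If `TRUE`, drop terminal fragments shorter than
#'   `fragment_length`.
#' @return A `QualityScaledDNAStringSet` of fragments (invisibly when
#'   `output` is given).
#' @export
shred_reads <- function(input, output = NULL, fragment_length = 200L,
                        drop_short = FALSE) {
  stopifnot_scalar_num(fragment_length, "fragment_length", lower = 1,
                       integer = TRUE)
  x <- if (is.character(input))
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input))
  else input
  w <- Biostrings::width(x)
  starts <- unlist(lapply(w, function(wi) seq.int(1L, wi, by = fragment_length)))
  nfrag <- ceiling(w / fragment_length)
  ri <- rep(seq_along(x), nfrag)
  ends <- pmin(starts + fragment_length - 1L, w[ri])
  frags <- Biostrings::subseq(x[ri], start = starts, end = ends)
  names(frags) <- paste0(names(x)[ri], "_f",
                         unlist(lapply(nfrag, seq_len)))
  if (drop_short) frags <- frags[Biostrings::width(frags) == fragment_length]
  if (!is.null(output)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(frags), output, format = "fastq",
      qualities = Biostrings::BStringSet(Biostrings::quality(frags)))
    return(invisible(frags))
  }
  frags
}
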