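#' Alignment identity over aligned columns
#'
#' Identity is the fraction of matched columns among all aligned columns,
#' where each inserted or deleted base counts as one non-matching column
#' (the NM-based convention of common read recruiters); soft-clipped columns
#' are excluded entirely.
#'
#' @param n_match,n_mismatch,n_ins,n_del Non-negative column counts
#'   (vectorized).
#' @return `n_match / (n_match + n_mismatch + n_ins + n_del)`.
#' @examples
#' alignment_identity(192, 6, 1, 1)  # 0.96
#' @export
alignment_identity <- function(n_match, n_mismatch, n_ins, n_del) {
  tot <- n_match + n_mismatch + n_ins + n_del
  if (any(tot == 0))
    stop("alignment with zero aligned columns")
  n_match / tot
}

# Tokenize CIGAR strings into per-read op/length lists.
.cigar_tokens <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  lapply(toks, function(tk) {
    if (!length(tk)) stop("empty or invalid CIGAR")
    list(op = substring(tk, nchar(tk), nchar(tk)),
         len = as.integer(substring(tk, 1L, nchar(tk) - 1L)))
  })
}

#' Load read alignments from SAM/BAM
#'
#' Reads a SAM or BAM file (SAM text is converted through
#' [Rsamtools::asBam()]), drops unmapped, secondary and supplementary
#' records, and computes per-read edit counts and identity. Mismatch counts
#' are taken from the `NM` tag when present (`n_mismatch = NM - ins - del`
#' bases) and otherwise re-derived by comparing aligned M columns to the
#' reference sequence.
#'
#' @param path SAM (`.sam`) or BAM file path.
#' @param ref Reference: a `genome` object, a FASTA path, or a named list of
#'   `genome` objects for multi-reference files.
#' @return A data.frame of class `recruited_reads` with columns `read_id`,
#'   `ref_id`, `ref_start` (0-based), `cigar`, `seq`, `n_match`,
#'   `n_mismatch`, `n_ins`, `n_del`, `identity`, `mate_ref` (NA when
#'   unpaired).
#' @export
load_alignments <- function(path, ref) {
  refs <- if (inherits(ref, "genome")) stats::setNames(list(ref), ref$id)
          else if (is.character(ref)) { g <- as_genome(ref)
                                        stats::setNames(list(g), g$id) }
          else stats::setNames(ref, vapply(ref, `[[`, "", "id"))
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "mrnm"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  if (n == 0L)
    return(.as_recruited(data.frame(
      read_id = character(), ref_id = character(), ref_start = integer(),
      cigar = character(), seq = character(), n_match = integer(),
      n_mismatch = integer(), n_ins = integer(), n_del = integer(),
      identity = numeric(), mate_ref = character())))
  rname <- as.character(x$rname)
  bad <- !(rname %in% names(refs))
  if (any(bad))
    stop("record '", x$qname[which(bad)[1]], "' maps to unknown reference '",
         rname[which(bad)[1]], "'")
  toks <- .cigar_tokens(x$cigar)
  m_cols <- vapply(toks, function(t) sum(t$len[t$op %in% c("M", "=", "X")]), 0L)
  n_ins <- vapply(toks, function(t) sum(t$len[t$op == "I"]), 0L)
  n_del <- vapply(toks, function(t) sum(t$len[t$op == "D"]), 0L)
  nm <- x$tag$NM
  seqs <- as.character(x$seq)
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  n_mismatch <- nm - n_ins - n_del
  need <- which(is.na(n_mismatch))
  for (i in need)
    n_mismatch[i] <- .count_mismatches(seqs[i], toks[[i]], x$pos[i],
                                       refs[[rname[i]]])
  if (any(n_mismatch < 0))
    stop("inconsistent NM tag (NM < ins + del bases)")
  .as_recruited(data.frame(
    read_id = x$qname, ref_id = rname, ref_start = x$pos - 1L,
    cigar = x$cigar, seq = seqs,
    n_match = as.integer(m_cols - n_mismatch),
    n_mismatch = as.integer(n_mismatch),
    n_ins = as.integer(n_ins), n_del = as.integer(n_del),
    identity = alignment_identity(m_cols - n_mismatch, n_mismatch,
                                  n_ins, n_del),
    mate_ref = as.character(x$mrnm)))
}

.as_recruited <- function(df) {
  class(df) <- c("recruited_reads", "data.frame")
  df
}

# Walk M segments comparing read vs reference (soft clips consume query only).
.count_mismatches <- function(seq, tok, pos, ref) {
  rpos <- pos
  qpos <- 1L
  mm <- 0L
  for (j in seq_along(tok$op)) {
    op <- tok$op[j]; len <- tok$len[j]
    if (op %in% c("M", "=", "X")) {
      a <- seq_to_code(substring(seq, qpos, qpos + len - 1L))
      b <- seq_to_code(substring(ref$sequence, rpos, rpos + len - 1L))
      mm <- mm + sum(a != b, na.rm = TRUE)
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op %in% c("I", "S")) qpos <- qpos + len
    else if (op %in% c("D", "N")) rpos <- rpos + len
  }
  mm
}

#' Apply recruitment filters
#'
#' Mirrors the standard species-delimiting recruitment contract: reads below
#' the identity threshold are removed (boundary inclusive, so
#' `identity >= min_identity` is kept); under the `non_discordant` pairing
#' filter a read is dropped only when its mate maps to a different reference
#' (unpaired reads are vacuously retained); under best-match selection a
#' single alignment is kept per read id (highest identity, ties broken by
#' leftmost start then lexicographic reference id).
#'
#' @param reads A `recruited_reads` data.frame.
#' @param min_identity Identity threshold in `[0, 1]` (default 0.95).
#' @param pairing `"non_discordant"` or `"none"`.
#' @param best_match Keep one alignment per read id (default `TRUE`).
#' @return Filtered `recruited_reads` (idempotent).
#' @export
apply_filters <- function(reads, min_identity = 0.95,
                          pairing = c("non_discordant", "none"),
                          best_match = TRUE) {
  pairing <- match.arg(pairing)
  stopifnot_scalar_num(min_identity, "min_identity", lower = 0, upper = 1)
  out <- reads[reads$identity >= min_identity, , drop = FALSE]
  if (pairing == "non_discordant" && nrow(out) &&
      "mate_ref" %in% names(out)) {
    has_mate <- !is.na(out$mate_ref) & out$mate_ref != ""
    keep <- !has_mate | out$mate_ref == out$ref_id
    out <- out[keep, , drop = FALSE]
  }
  if (best_match && nrow(out)) {
    o <- order(out$read_id, -out$identity, out$ref_start, out$ref_id)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$read_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  .as_recruited(out)
}
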