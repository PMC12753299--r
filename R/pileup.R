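#' Per-position nucleotide pileup
#'
#' Builds the A/C/G/T count matrix over reference positions from recruited
#' reads. Match/mismatch (M/=/X) columns increment the count of the read base
#' at the reference position; insertions contribute nothing; deletions leave
#' gaps (spanned positions are not consensus-filled); non-ACGT read bases are
#' skipped.
#'
#' For `sim_metagenome` input the pileup is assembled from the ground truth
#' by exact sparse accounting (aggregate per-strain coverage plus per-event
#' corrections) rather than by expanding every read, which is algebraically
#' identical to the per-read CIGAR walk.
#'
#' @param reads A `recruited_reads` data.frame or a `sim_metagenome`.
#' @param ref Reference `genome` (ignored for `sim_metagenome`, which carries
#'   its ancestor).
#' @param ... Further arguments passed to methods.
#' @return An object of class `pileup`: list with `ref_id`, `ref_length` and
#'   `counts`, a 4 x L numeric matrix with rows A, C, G, T.
#' @export
build_pileup <- function(reads, ref = NULL, ...) UseMethod("build_pileup")

.new_pileup <- function(ref_id, L, counts) {
  rownames(counts) <- .BASES
  structure(list(ref_id = ref_id, ref_length = as.integer(L),
                 counts = counts), class = "pileup")
}

#' @rdname build_pileup
#' @export
build_pileup.recruited_reads <- function(reads, ref = NULL, ...) {
  stopifnot(inherits(ref, "genome"))
  L <- ref$length
  counts <- matrix(0, nrow = 4L, ncol = L)
  for (i in seq_len(nrow(reads))) {
    if (reads$ref_id[i] != ref$id) next
    tok <- .cigar_tokens(reads$cigar[i])[[1]]
    rpos <- reads$ref_start[i] + 1L
    qpos <- 1L
    for (j in seq_along(tok$op)) {
      op <- tok$op[j]; len <- tok$len[j]
      if (op %in% c("M", "=", "X")) {
        if (rpos + len - 1L > L)
          stop("read '", reads$read_id[i], "' overhangs the reference end")
        base <- seq_to_code(substring(reads$seq[i], qpos, qpos + len - 1L))
        ok <- !is.na(base)
        lin <- (rpos + seq_len(len) - 2L) * 4 + base
        counts[lin[ok]] <- counts[lin[ok]] + 1
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op %in% c("I", "S")) qpos <- qpos + len
      else if (op %in% c("D", "N")) rpos <- rpos + len
    }
  }
  .new_pileup(ref$id, L, counts)
}

#' @rdname build_pileup
#' @param subset Read indices to include (defaults to the active subset).
#' @export
build_pileup.sim_metagenome <- function(reads, ref = NULL, ...,
                                        subset = reads$active) {
  sim <- reads
  L <- sim$strain_set$ancestor$length
  Lr <- sim$read_length
  anc <- sim$anc_code
  starts <- sim$reads$start[subset]
  # Total coverage from full read spans, then assign to the ancestor base
  # channel of every position in one vectorized shot.
  d <- tabulate(starts, nbins = L + 1L) -
       tabulate(starts + Lr, nbins = L + 1L)
  cov <- cumsum(d)[seq_len(L)]
  counts <- matrix(0, nrow = 4L, ncol = L)
  counts[(seq_len(L) - 1) * 4 + anc] <- cov
  # Move per-strain coverage at substituted positions to the strain allele.
  strains <- sim$reads$strain[subset]
  for (k in unique(strains)) {
    ed <- sim$strain_set$edits[[k]]
    if (nrow(ed) == 0L) next
    st <- sort(starts[strains == k])
    c_sp <- findInterval(ed$pos, st) - findInterval(ed$pos - Lr, st)
    nz <- c_sp > 0
    if (!any(nz)) next
    p <- ed$pos[nz]
    counts[(p - 1) * 4 + anc[p]] <- counts[(p - 1) * 4 + anc[p]] - c_sp[nz]
    counts[(p - 1) * 4 + ed$code[nz]] <-
      counts[(p - 1) * 4 + ed$code[nz]] + c_sp[nz]
  }
  # Per-event corrections: deletions remove one template base; mismatches
  # move one count from the template base to the replacement base.
  ev <- sim$events
  keep <- logical(sim$n_reads); keep[subset] <- TRUE
  ev <- ev[keep[ev$read], , drop = FALSE]
  if (nrow(ev)) {
    dec <- (ev$ref_pos - 1) * 4 + ev$tmpl        # del and mm both decrement
    dec <- dec[ev$type != 1L]
    inc <- (ev$ref_pos[ev$type == 3L] - 1) * 4 + ev$new[ev$type == 3L]
    for (upd in list(list(lin = dec, s = -1), list(lin = inc, s = +1))) {
      if (!length(upd$lin)) next
      u <- unique(upd$lin)
      counts[u] <- counts[u] + upd$s * tabulate(match(upd$lin, u),
                                                length(u))
    }
  }
  .new_pileup(sim$strain_set$ancestor$id, L, counts)
}

#' @export
print.pileup <- function(x, ...) {
  depth <- colSums(x$counts)
  cat(sprintf(
    "<pileup> %s: %d bp, mean depth %.2fX, breadth %.2f%%\n",
    x$ref_id, x$ref_length, mean(depth), 100 * mean(depth > 0)))
  invisible(x)
}
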