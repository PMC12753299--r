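#' Generate a random ancestor genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content. The ancestor
#' stands in for a species reference (e.g. an isolate genome) from which a set
#' of conspecific strains is derived by point substitution.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_fraction Target GC fraction in `[0, 1]`; `P(G) + P(C)` of the
#'   per-base distribution.
#' @param seed Integer seed; identical inputs give identical sequences.
#' @param id Sequence identifier used in FASTA/SAM output.
#' @return An object of class `genome`: a list with elements `id`,
#'   `sequence` (single character string over A/C/G/T) and `length`.
#' @examples
#' g <- generate_ancestor(2000, gc_fraction = 0.5, seed = 1)
#' g$length
#' @export
generate_ancestor <- function(length, gc_fraction = 0.5, seed = 1L,
                              id = "ancestor") {
  stopifnot_scalar_num(length, "length", lower = 1000, integer = TRUE)
  stopifnot_scalar_num(gc_fraction, "gc_fraction", lower = 0, upper = 1)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  code <- withr::with_seed(seed,
    sample.int(4L, length, replace = TRUE, prob = prob))
  structure(
    list(id = id, sequence = code_to_seq(code), length = as.integer(length)),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp, GC %.1f%%\n", x$id, x$length,
              100 * mean(seq_to_code(x$sequence) %in% c(2L, 3L))))
  invisible(x)
}

as_genome <- function(x, id = NULL) {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    if (length(ss) == 0L) stop("no sequences in FASTA file: ", x)
    return(structure(list(id = if (is.null(id)) sub("\\s.*", "", names(ss)[1])
                          else id,
                          sequence = as.character(ss[[1]]),
                          length = Biostrings::width(ss)[1]),
                     class = "genome"))
  }
  stop("cannot interpret 'ref' as a genome (pass a genome object or a FASTA path)")
}

#' Write genomes to a FASTA file
#'
#' @param x A `genome`, `strain_set`, or list of `genome` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  gl <- if (inherits(x, "genome")) list(x)
        else if (inherits(x, "strain_set")) x$strains
        else x
  ss <- Biostrings::DNAStringSet(vapply(gl, `[[`, "", "sequence"))
  names(ss) <- vapply(gl, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Derive a set of conspecific strains from an ancestor genome
#'
#' Strain 1 is the ancestor itself; every further strain carries
#' `round(d * L)` point substitutions at distinct, uniformly sampled
#' positions, with its divergence `d` drawn uniformly from
#' `divergence_range`. The default range (0, 0.0249) produces strain pairs
#' sharing roughly 95-100% ANI, the regime delimited by the >= 95% identity
#' read-recruitment convention for a species. Pairwise ANI is computed
#' exactly from the edit lists (no re-alignment).
#'
#' @param ancestor A `genome` object.
#' @param n_strains Number of strains (>= 1).
#' @param divergence_range Length-2 numeric `(min, max)` per-strain divergence
#'   from the ancestor, each in `[0, 0.05)`.
#' @param seed Integer seed.
#' @return An object of class `strain_set`: list with `ancestor`, `strains`
#'   (list of `genome`), `edits` (per-strain data.frame of `pos`, `base`,
#'   `code`), `divergence` and `pairwise_ani` (symmetric matrix).
#' @examples
#' anc <- generate_ancestor(5000, seed = 1)
#' ss <- derive_strain_set(anc, 3, c(0.005, 0.02), seed = 2)
#' ss$pairwise_ani
#' @export
derive_strain_set <- function(ancestor, n_strains,
                              divergence_range = c(0, 0.0249), seed = 1L) {
  stopifnot(inherits(ancestor, "genome"))
  stopifnot_scalar_num(n_strains, "n_strains", lower = 1, integer = TRUE)
  if (length(divergence_range) != 2L || any(divergence_range < 0) ||
      divergence_range[1] > divergence_range[2])
    stop("'divergence_range' must be (min, max) with 0 <= min <= max")
  if (divergence_range[2] >= 0.05)
    stop("divergence above 5% would fall outside the >=95% identity ",
         "recruitment regime")
  L <- ancestor$length
  anc_code <- seq_to_code(ancestor$sequence)

  out <- withr::with_seed(seed, {
    d <- c(0, if (n_strains > 1)
      stats::runif(n_strains - 1L, divergence_range[1], divergence_range[2]))
    edits <- vector("list", n_strains)
    strains <- vector("list", n_strains)
    strains[[1]] <- structure(
      list(id = paste0(ancestor$id, "_strain01"),
           sequence = ancestor$sequence, length = L), class = "genome")
    edits[[1]] <- data.frame(pos = integer(), base = character(),
                             code = integer())
    for (k in seq_len(n_strains)[-1]) {
      n_sub <- round(d[k] * L)
      if (n_sub > L) stop("requested substitutions exceed genome length")
      pos <- sort(sample.int(L, n_sub))
      alt <- ((anc_code[pos] - 1L + sample.int(3L, n_sub, replace = TRUE)) %%
                4L) + 1L
      r <- charToRaw(ancestor$sequence)
      r[pos] <- charToRaw(code_to_seq(alt))
      strains[[k]] <- structure(
        list(id = sprintf("%s_strain%02d", ancestor$id, k),
             sequence = rawToChar(r), length = L), class = "genome")
      edits[[k]] <- data.frame(pos = pos, base = .BASES[alt], code = alt)
    }
    list(d = d, edits = edits, strains = strains)
  })

  ani <- diag(1, n_strains)
  for (j in seq_len(n_strains)) for (k in seq_len(n_strains)) {
    if (k <= j) next
    ani[j, k] <- ani[k, j] <- .ani_from_edits(out$edits[[j]], out$edits[[k]], L)
  }
  structure(list(ancestor = ancestor, strains = out$strains,
                 edits = out$edits, divergence = out$d, pairwise_ani = ani),
            class = "strain_set")
}

# Exact identity between two strains given their substitution lists vs the
# shared ancestor; positions edited in both count as differing only when the
# replacement bases differ.
.ani_from_edits <- function(e1, e2, L) {
  shared <- intersect(e1$pos, e2$pos)
  ndiff <- (nrow(e1) - length(shared)) + (nrow(e2) - length(shared)) +
    sum(e1$code[match(shared, e1$pos)] != e2$code[match(shared, e2$pos)])
  1 - ndiff / L
}

#' @export
print.strain_set <- function(x, ...) {
  n <- length(x$strains)
  off <- x$pairwise_ani[upper.tri(x$pairwise_ani)]
  cat(sprintf("<strain_set> %d strain(s) of %d bp", n, x$ancestor$length))
  if (length(off))
    cat(sprintf("; pairwise ANI %.4f-%.4f", min(off), max(off)))
  cat("\n")
  invisible(x)
}

#' Sample log-normal relative abundances
#'
#' Relative strain abundances are drawn as `exp(Normal(0, sigma^2))` and
#' normalized to sum to one, the canonical rank-abundance shape for
#' strain mixtures in mock metagenomes.
#'
#' @param n_strains Number of strains (>= 1).
#' @param sigma Log-scale standard deviation (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of positive weights summing to 1.
#' @examples
#' sample_lognormal_abundances(5, sigma = 1, seed = 7)
#' @export
sample_lognormal_abundances <- function(n_strains, sigma = 1, seed = 1L) {
  stopifnot_scalar_num(n_strains, "n_strains", lower = 1, integer = TRUE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive number")
  w <- withr::with_seed(seed, exp(stats::rnorm(n_strains, 0, sigma)))
  w / sum(w)
}
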