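#' Profiling parameters
#'
#' @param min_cov Minimum depth for a site to enter the genome-wide pi
#'   average (default 5).
#' @param min_identity Minimum read identity for recruitment (default 0.95,
#'   boundary inclusive).
#' @param anir_weight `"reads"` (each read one vote, the default) or
#'   `"bases"` (reads weighted by aligned columns).
#' @param pi_sites `"min_cov"` (sites with depth >= `min_cov` only, the
#'   default) or `"covered"` (all sites with depth >= 1).
#' @return An object of class `profile_params`.
#' @export
profile_params <- function(min_cov = 5L, min_identity = 0.95,
                           anir_weight = c("reads", "bases"),
                           pi_sites = c("min_cov", "covered")) {
  stopifnot_scalar_num(min_cov, "min_cov", lower = 1, integer = TRUE)
  stopifnot_scalar_num(min_identity, "min_identity", lower = 0, upper = 1)
  structure(list(min_cov = as.integer(min_cov), min_identity = min_identity,
                 anir_weight = match.arg(anir_weight),
                 pi_sites = match.arg(pi_sites)),
            class = "profile_params")
}

#' Per-site nucleotide diversity
#'
#' The plugin heterozygosity of one pileup column:
#' `pi = 1 - (fA^2 + fC^2 + fG^2 + fT^2)` with frequencies `f = counts /
#' depth`. A monomorphic column gives 0; an equal quartet gives the maximum,
#' 0.75. No small-sample (`n/(n-1)`) correction is applied — the downward
#' bias of the plugin estimator at finite depth is precisely the phenomenon
#' this package quantifies.
#'
#' @param counts Length-4 vector of A/C/G/T counts with `sum(counts) >= 1`.
#' @return Site diversity in `[0, 0.75]`.
#' @examples
#' site_pi(c(12, 0, 0, 0))  # 0
#' site_pi(c(3, 3, 3, 3))   # 0.75
#' @export
site_pi <- function(counts) {
  if (length(counts) != 4L || any(counts < 0))
    stop("'counts' must be 4 non-negative values (A, C, G, T)")
  depth <- sum(counts)
  if (depth == 0) stop("zero-depth column has no defined diversity")
  1 - sum((counts / depth)^2)
}

# Vectorized site pi over pileup columns (selected positions).
.site_pi_cols <- function(counts, depth) {
  1 - colSums((counts / rep(depth, each = 4L))^2)
}

#' Genome-wide nucleotide diversity
#'
#' Mean of per-site pi over reference positions with depth >= `min_cov`.
#' When no site qualifies the estimate is undefined and `NA` is returned
#' (never zero).
#'
#' @param pileup A `pileup`.
#' @param params A [profile_params()].
#' @return List with `pi` (numeric or `NA`) and `n_sites_pi`.
#' @export
genome_pi <- function(pileup, params = profile_params()) {
  depth <- colSums(pileup$counts)
  sel <- if (params$pi_sites == "min_cov") depth >= params$min_cov
         else depth >= 1
  n <- sum(sel)
  if (n == 0L) return(list(pi = NA_real_, n_sites_pi = 0L))
  list(pi = mean(.site_pi_cols(pileup$counts[, sel, drop = FALSE],
                               depth[sel])),
       n_sites_pi = as.integer(n))
}

#' Average nucleotide identity of recruited reads (ANIr)
#'
#' The mean alignment identity of reads recruited to the reference,
#' expressed as a percentage. By default each read contributes one vote;
#' `weight = "bases"` weights reads by their aligned columns.
#'
#' @param reads A `recruited_reads` data.frame or a numeric vector of
#'   per-read identities in `[0, 1]`.
#' @param weight `"reads"` or `"bases"`.
#' @return ANIr percentage.
#' @examples
#' compute_anir(c(0.95, 0.99))  # 97
#' @export
compute_anir <- function(reads, weight = c("reads", "bases")) {
  weight <- match.arg(weight)
  if (is.numeric(reads)) {
    if (!length(reads)) stop("no recruited reads")
    return(100 * mean(reads))
  }
  if (!nrow(reads)) stop("no recruited reads")
  if (weight == "bases") {
    w <- reads$n_match + reads$n_mismatch + reads$n_ins + reads$n_del
    return(100 * sum(reads$identity * w) / sum(w))
  }
  100 * mean(reads$identity)
}

#' Sequencing depth and breadth
#'
#' Mean depth counts match/mismatch columns over all reference positions
#' (zeros included in the denominator); breadth is the percentage of
#' positions covered by at least one read.
#'
#' @param pileup A `pileup`.
#' @return List with `mean_depth` (X) and `breadth` (percent).
#' @export
coverage_stats <- function(pileup) {
  depth <- colSums(pileup$counts)
  list(mean_depth = sum(depth) / pileup$ref_length,
       breadth = 100 * mean(depth >= 1))
}

#' Profile a genome: pi, ANIr, depth and breadth
#'
#' The full deterministic composition: recruitment filtering, pileup
#' construction, then nucleotide diversity, ANIr and coverage statistics.
#'
#' @param x A `sim_metagenome`, `recruited_reads` data.frame, or SAM/BAM
#'   path.
#' @param ref Reference `genome` (or FASTA path); ignored for
#'   `sim_metagenome`.
#' @param params A [profile_params()].
#' @param ... Passed to methods.
#' @return An object of class `microdiv_profile` with fields `ref_id`,
#'   `pi`, `anir`, `mean_depth`, `breadth`, `n_reads`, `n_sites_pi` and
#'   `params`.
#' @examples
#' anc <- generate_ancestor(5000, seed = 1)
#' ss <- derive_strain_set(anc, 1, seed = 1)
#' sim <- simulate_metagenome(ss, n_reads = 500, read_length = 100, seed = 5)
#' profile_genome(sim)
#' @export
profile_genome <- function(x, ref = NULL, params = profile_params(), ...)
  UseMethod("profile_genome")

.new_profile <- function(ref_id, pu, reads_identity, n_reads, params) {
  gp <- genome_pi(pu, params)
  cs <- coverage_stats(pu)
  structure(list(ref_id = ref_id, pi = gp$pi, anir = reads_identity,
                 mean_depth = cs$mean_depth, breadth = cs$breadth,
                 n_reads = n_reads, n_sites_pi = gp$n_sites_pi,
                 params = params),
            class = "microdiv_profile")
}

#' @rdname profile_genome
#' @export
profile_genome.sim_metagenome <- function(x, ref = NULL,
                                          params = profile_params(), ...) {
  kept <- x$active[x$reads$identity_anc[x$active] >= params$min_identity]
  if (!length(kept)) stop("no reads pass the identity filter")
  pu <- build_pileup(x, subset = kept)
  ids <- x$reads$identity_anc[kept]
  anir <- if (params$anir_weight == "bases") {
    w <- x$read_length + x$reads$n_ins[kept]
    100 * sum(ids * w) / sum(w)
  } else 100 * mean(ids)
  .new_profile(x$strain_set$ancestor$id, pu, anir, length(kept), params)
}

#' @rdname profile_genome
#' @export
profile_genome.recruited_reads <- function(x, ref = NULL,
                                           params = profile_params(), ...) {
  ref <- as_genome(ref)
  kept <- apply_filters(x, min_identity = params$min_identity)
  if (!nrow(kept)) stop("no reads pass the identity filter")
  pu <- build_pileup(kept, ref)
  .new_profile(ref$id, pu, compute_anir(kept, params$anir_weight),
               nrow(kept), params)
}

#' @rdname profile_genome
#' @export
profile_genome.character <- function(x, ref = NULL,
                                     params = profile_params(), ...) {
  profile_genome(load_alignments(x, as_genome(ref)), ref = as_genome(ref),
                 params = params)
}

#' @export
print.microdiv_profile <- function(x, ...) {
  cat(sprintf("<microdiv_profile> %s\n", x$ref_id))
  cat(sprintf("  reads recruited : %d\n", x$n_reads))
  cat(sprintf("  mean depth      : %.2fX\n", x$mean_depth))
  cat(sprintf("  breadth         : %.2f%%\n", x$breadth))
  cat(sprintf("  ANIr            : %.4f%%\n", x$anir))
  cat(sprintf("  pi              : %s (over %d sites with depth >= %d)\n",
              ifelse(is.na(x$pi), "NA", sprintf("%.6f", x$pi)),
              x$n_sites_pi, x$params$min_cov))
  invisible(x)
}

#' @export
as.data.frame.microdiv_profile <- function(x, ...) {
  data.frame(ref_id = x$ref_id, n_reads = x$n_reads,
             mean_depth = x$mean_depth, breadth_pct = x$breadth,
             anir_pct = x$anir, pi = x$pi, n_sites_pi = x$n_sites_pi)
}
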