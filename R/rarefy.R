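#' Subsample a read set
#'
#' Default mode is exact subsampling without replacement: exactly
#' `floor(fraction * N)` reads are kept (mirroring classic FASTA subsampling
#' semantics). `mode = "bernoulli"` keeps each read independently with
#' probability `fraction`. Mates are kept or dropped together when pairing
#' information exists.
#'
#' @param x A `sim_metagenome` or `recruited_reads` data.frame.
#' @param fraction Fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @param mode `"exact"` or `"bernoulli"`.
#' @param ... Passed to methods.
#' @return Object of the same class restricted to the sampled reads.
#' @export
subsample_fraction <- function(x, fraction, seed = 1L,
                               mode = c("exact", "bernoulli"), ...)
  UseMethod("subsample_fraction")

.check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
}

#' @rdname subsample_fraction
#' @export
subsample_fraction.sim_metagenome <- function(x, fraction, seed = 1L,
                                              mode = c("exact", "bernoulli"),
                                              ...) {
  .check_fraction(fraction)
  mode <- match.arg(mode)
  n <- length(x$active)
  if (n == 0L) stop("empty read set")
  keep <- withr::with_seed(seed, {
    if (mode == "exact") {
      k <- floor(fraction * n)
      if (k == n) seq_len(n) else sort(sample.int(n, k))
    } else which(stats::runif(n) < fraction)
  })
  x$active <- x$active[keep]
  x
}

#' @rdname subsample_fraction
#' @export
subsample_fraction.recruited_reads <- function(x, fraction, seed = 1L,
                                               mode = c("exact", "bernoulli"),
                                               ...) {
  .check_fraction(fraction)
  mode <- match.arg(mode)
  units <- unique(x$read_id)   # mates share a read id: sampled as one unit
  n <- length(units)
  if (n == 0L) stop("empty read set")
  keep_units <- withr::with_seed(seed, {
    if (mode == "exact") {
      k <- floor(fraction * n)
      if (k == n) units else units[sort(sample.int(n, k))]
    } else units[stats::runif(n) < fraction]
  })
  out <- x[x$read_id %in% keep_units, , drop = FALSE]
  rownames(out) <- NULL
  .as_recruited(out)
}

# Cheap mean-depth estimate (aligned template bases / reference length),
# used to translate target depths into subsampling fractions.
.est_mean_depth <- function(x, ref_length = NULL) {
  if (inherits(x, "sim_metagenome")) {
    L <- x$strain_set$ancestor$length
    return(sum(x$read_length - x$reads$n_del[x$active]) / L)
  }
  if (is.null(ref_length)) stop("'ref_length' is required for read tables")
  tot <- sum(x$n_match + x$n_mismatch)
  tot / ref_length
}

#' Rarefy a read set to a fixed target depth
#'
#' Subsamples so that the expected mean depth equals `target_depth`
#' (fraction = target / current mean depth). Refuses to proceed when the
#' current depth is below the target rather than silently keeping all reads.
#'
#' @param x A `sim_metagenome` or `recruited_reads` data.frame.
#' @param target_depth Target mean depth (X).
#' @param ref_length Reference length in bp (required for read tables).
#' @param seed Integer seed.
#' @return The subsampled object, with attribute `achieved_depth`.
#' @export
rarefy_to_depth <- function(x, target_depth, ref_length = NULL, seed = 1L) {
  stopifnot_scalar_num(target_depth, "target_depth", lower = 1e-9)
  cur <- .est_mean_depth(x, ref_length)
  if (cur < target_depth)
    stop(sprintf(
      "current mean depth (%.2fX) is below the target (%.2fX); cannot rarefy",
      cur, target_depth))
  out <- if (cur == target_depth) x
         else subsample_fraction(x, target_depth / cur, seed = seed)
  attr(out, "achieved_depth") <- .est_mean_depth(out, ref_length)
  out
}

#' Diversity ratio of a subsample relative to the full dataset
#'
#' `sub_value / full_value`; 1 means the subsample recovers the
#' whole-dataset estimate exactly. When the full-dataset value is zero or
#' undefined (e.g. pi of a clonal error-free metagenome) the ratio is
#' undefined and `NA` is returned, to be excluded from summaries.
#'
#' @param sub_value,full_value Metric values (vectorized).
#' @return `sub_value / full_value`, or `NA` where undefined.
#' @export
diversity_ratio <- function(sub_value, full_value) {
  ifelse(is.na(full_value) | full_value <= 0, NA_real_,
         sub_value / full_value)
}

#' Average absolute error of subsampled estimates, by depth bin
#'
#' Per point the error is the relative deviation
#' `100 * |sub - full| / full`; points are grouped into sequencing-depth
#' bins and the mean and standard deviation of the error are reported per
#' bin. Points with an undefined full-dataset value are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param sub_value,full_value Numeric vectors of paired estimates.
#' @param depth Numeric vector of subsample mean depths (X).
#' @param breaks Depth bin boundaries (default 10, 50, 200 -> bins `<10X`,
#'   `10-50X`, `50-200X`, `>200X`).
#' @return Data.frame with `depth_bin`, `mean_abs_error_pct`,
#'   `sd_error_pct`, `n`.
#' @export
average_absolute_error <- function(sub_value, full_value, depth,
                                   breaks = c(10, 50, 200)) {
  stopifnot(length(sub_value) == length(full_value),
            length(sub_value) == length(depth))
  ok <- !is.na(full_value) & full_value > 0 & !is.na(sub_value)
  err <- 100 * abs(sub_value[ok] - full_value[ok]) / full_value[ok]
  bin <- depth_category(depth[ok], breaks)
  agg <- lapply(split(err, bin), function(e)
    c(mean = mean(e), sd = if (length(e) > 1L) stats::sd(e) else 0,
      n = length(e)))
  agg <- agg[vapply(agg, function(z) z[["n"]] > 0, TRUE)]
  out <- data.frame(
    depth_bin = names(agg),
    mean_abs_error_pct = vapply(agg, `[[`, 0, "mean"),
    sd_error_pct = vapply(agg, `[[`, 0, "sd"),
    n = as.integer(vapply(agg, `[[`, 0, "n")),
    row.names = NULL)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Sequencing-depth category labels
#'
#' @param depth Numeric depths (X).
#' @param breaks Bin boundaries (default 10, 50, 200).
#' @return Factor with levels `<10X`, `10-50X`, `50-200X`, `>200X` (for the
#'   default breaks).
#' @export
depth_category <- function(depth, breaks = c(10, 50, 200)) {
  labs <- c(paste0("<", breaks[1], "X"),
            paste0(breaks[-length(breaks)], "-", breaks[-1], "X"),
            paste0(">", breaks[length(breaks)], "X"))
  cut(depth, breaks = c(-Inf, breaks, Inf), labels = labs, right = FALSE)
}

#' Rarefaction series over a fraction grid
#'
#' Profiles the full read set once, then for every fraction x replicate
#' subsamples (exact mode, seeded deterministically from `seed`), re-profiles
#' and forms the diversity ratios against the fixed full-dataset values.
#'
#' @param x A `sim_metagenome`, `recruited_reads` data.frame, or SAM/BAM
#'   path.
#' @param fractions Numeric vector of fractions in `(0, 1]`.
#' @param replicates Replicate subsamples per fraction.
#' @param params A [profile_params()].
#' @param seed Master integer seed.
#' @param ref Reference `genome` (for read-table or file input).
#' @return A data.frame of class `rarefaction_series` with columns
#'   `fraction`, `replicate`, `seed`, `n_reads`, `mean_depth`, `pi`, `anir`,
#'   `ratio_pi`, `ratio_anir`; the full-dataset profile is attached as
#'   attribute `full_profile`.
#' @export
rarefaction_series <- function(x, fractions, replicates = 1L,
                               params = profile_params(), seed = 1L,
                               ref = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must all lie in (0, 1]")
  if (is.character(x)) x <- load_alignments(x, as_genome(ref))
  full <- profile_genome(x, ref = ref, params = params)
  rows <- vector("list", length(fractions) * replicates)
  i <- 0L
  for (f in fractions) for (r in seq_len(replicates)) {
    i <- i + 1L
    s <- child_seed(seed, "subsample", f, r)
    sub <- subsample_fraction(x, f, seed = s)
    p <- profile_genome(sub, ref = ref, params = params)
    rows[[i]] <- data.frame(
      fraction = f, replicate = r, seed = s, n_reads = p$n_reads,
      mean_depth = p$mean_depth, pi = p$pi, anir = p$anir,
      ratio_pi = diversity_ratio(p$pi, full$pi),
      ratio_anir = diversity_ratio(p$anir, full$anir))
  }
  out <- do.call(rbind, rows)
  attr(out, "full_profile") <- full
  class(out) <- c("rarefaction_series", "data.frame")
  out
}

#' @export
print.rarefaction_series <- function(x, ...) {
  full <- attr(x, "full_profile")
  cat(sprintf(
    "<rarefaction_series> %d points (%d fractions x %d replicates)\n",
    nrow(x), length(unique(x$fraction)), max(x$replicate)))
  if (!is.null(full))
    cat(sprintf("  full dataset: %.2fX, pi %s, ANIr %.4f%%\n",
                full$mean_depth,
                ifelse(is.na(full$pi), "NA", sprintf("%.6f", full$pi)),
                full$anir))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.rarefaction_series <- function(x, metric = c("pi", "anir"), ...) {
  metric <- match.arg(metric)
  ratio <- if (metric == "pi") x$ratio_pi else x$ratio_anir
  plot(x$mean_depth, ratio, log = "x",
       xlab = "mean sequencing depth (X)",
       ylab = sprintf("%s diversity ratio (subsample / full)",
                      ifelse(metric == "pi", "pi", "ANIr")), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
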