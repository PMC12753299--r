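#' Configuration for the in silico metagenome design
#'
#' The design crosses strain counts with sequencing error profiles; each cell
#' is one simulated metagenome that is profiled in full and along a
#' subsampling grid. Defaults are a scaled-down version of the original
#' 12-strain-counts x 3-profiles design: a 200 kb ancestor, strain counts
#' {1, 5, 20, 100}, reads sized to roughly 300X full depth and 3 replicate
#' subsamples per fraction. The full-scale design is a parameter change, not
#' a code change.
#'
#' @param genome_length Ancestor length in bp.
#' @param strain_counts Integer vector of community sizes (each <= 100).
#' @param error_profiles Subset of `c("none", "q20", "q30")`.
#' @param n_reads Reads per metagenome.
#' @param read_length Read length in bp.
#' @param fractions Subsampling fraction grid (default the classic 1-90%
#'   grid).
#' @param replicates Replicate subsamples per fraction.
#' @param divergence_range Per-strain divergence range from the ancestor.
#' @param sigma Log-normal abundance shape parameter.
#' @param gc_fraction Ancestor GC content.
#' @param min_cov,min_identity Profiling parameters.
#' @param seed Master seed; per-metagenome seeds are derived from it.
#' @param output_dir Optional directory for result tables and manifest.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(genome_length = 200000L,
                              strain_counts = c(1L, 5L, 20L, 100L),
                              error_profiles = c("none", "q20", "q30"),
                              n_reads = 400000L,
                              read_length = 150L,
                              fractions = c(0.01, 0.05, seq(0.1, 0.9, 0.1)),
                              replicates = 3L,
                              divergence_range = c(0, 0.0249),
                              sigma = 1,
                              gc_fraction = 0.5,
                              min_cov = 5L,
                              min_identity = 0.95,
                              seed = 1L,
                              output_dir = NULL) {
  if (!length(strain_counts) || any(strain_counts < 1) ||
      any(strain_counts > 100))
    stop("'strain_counts' must be non-empty with values in [1, 100]")
  if (!all(error_profiles %in% c("none", "q20", "q30")))
    stop("'error_profiles' must be a subset of none/q20/q30")
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must all lie in (0, 1]")
  structure(list(
    genome_length = as.integer(genome_length),
    strain_counts = as.integer(strain_counts),
    error_profiles = error_profiles, n_reads = as.integer(n_reads),
    read_length = as.integer(read_length), fractions = fractions,
    replicates = as.integer(replicates),
    divergence_range = divergence_range, sigma = sigma,
    gc_fraction = gc_fraction, min_cov = as.integer(min_cov),
    min_identity = min_identity, seed = as.integer(seed),
    output_dir = output_dir), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d bp genome; strains {%s} x profiles {%s} = %d metagenomes\n",
    x$genome_length, paste(x$strain_counts, collapse = ","),
    paste(x$error_profiles, collapse = ","),
    length(x$strain_counts) * length(x$error_profiles)))
  cat(sprintf("  %d reads x %d bp each; %d fractions x %d replicates; seed %d\n",
              x$n_reads, x$read_length, length(x$fractions), x$replicates,
              x$seed))
  invisible(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; missing
#' keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, vals)
}

#' Run the in silico depth-bias design
#'
#' For every (strain count, error profile) cell: derive a strain set from a
#' shared ancestor, sample log-normal abundances, simulate the metagenome,
#' profile it, and run the rarefaction series over the fraction grid. All
#' randomness is derived deterministically from the master seed.
#'
#' @param config An [experiment_config()].
#' @param verbose Log progress to stderr.
#' @return List of class `insilico_design` with `points` (long-format table
#'   of all rarefaction points with metadata), `error_summary` (per
#'   strain-count/profile/depth-bin average absolute errors), `full`
#'   (per-metagenome full-dataset profiles) and `config`. Tables are also
#'   written via [write_report()] when `config$output_dir` is set.
#' @export
run_insilico_design <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  anc <- generate_ancestor(config$genome_length, config$gc_fraction,
                           seed = child_seed(config$seed, "ancestor"))
  params <- profile_params(min_cov = config$min_cov,
                           min_identity = config$min_identity)
  points <- list(); fulls <- list(); errs <- list()
  for (ns in config$strain_counts) {
    ss <- derive_strain_set(anc, ns, config$divergence_range,
                            seed = child_seed(config$seed, "strains", ns))
    ab <- sample_lognormal_abundances(ns, config$sigma,
                                      seed = child_seed(config$seed, "abund", ns))
    for (prof in config$error_profiles) {
      log_("metagenome: %d strain(s), %s errors", ns, prof)
      sim <- simulate_metagenome(
        ss, ab, n_reads = config$n_reads,
        read_length = config$read_length,
        error_profile = error_profile(prof),
        seed = child_seed(config$seed, "sim", ns, prof))
      rs <- rarefaction_series(sim, config$fractions, config$replicates,
                               params = params,
                               seed = child_seed(config$seed, "rarefy", ns, prof))
      full <- attr(rs, "full_profile")
      low_cov <- full$n_sites_pi == 0L
      if (low_cov)
        warning(sprintf(
          "metagenome (%d strains, %s): no site reaches min_cov %d",
          ns, prof, config$min_cov))
      meta <- data.frame(strain_count = ns, error_profile = prof,
                         low_coverage = low_cov)
      points[[length(points) + 1L]] <- cbind(meta, as.data.frame(rs))
      fulls[[length(fulls) + 1L]] <- cbind(meta, as.data.frame(full))
      es <- average_absolute_error(rs$pi, rep(full$pi, nrow(rs)),
                                   rs$mean_depth)
      es_a <- average_absolute_error(rs$anir, rep(full$anir, nrow(rs)),
                                     rs$mean_depth)
      es$metric <- if (nrow(es)) "pi" else character(0)
      es_a$metric <- if (nrow(es_a)) "anir" else character(0)
      e <- rbind(es, es_a)
      if (nrow(e))
        errs[[length(errs) + 1L]] <- cbind(
          data.frame(strain_count = ns, error_profile = prof), e)
    }
  }
  out <- list(points = do.call(rbind, points),
              error_summary = if (length(errs)) do.call(rbind, errs)
                              else NULL,
              full = do.call(rbind, fulls),
              config = config)
  class(out) <- "insilico_design"
  if (!is.null(config$output_dir))
    write_report(list(rarefaction_points = out$points,
                      error_summary = out$error_summary,
                      full_profiles = out$full),
                 config$output_dir, config = config)
  out
}

#' @export
print.insilico_design <- function(x, ...) {
  cat(sprintf("<insilico_design> %d metagenomes, %d rarefaction points\n",
              nrow(x$full), nrow(x$points)))
  print(x$full[, c("strain_count", "error_profile", "mean_depth",
                   "breadth_pct", "anir_pct", "pi")], row.names = FALSE)
  invisible(x)
}

#' Profile externally mapped samples and categorize by depth
#'
#' Consumes alignments produced by an external mapper (one BAM/SAM plus
#' reference per species/sample), profiles each, and returns the observed
#' full-dataset table with sequencing-depth categories — the shape used to
#' compare observed diversity across samples of uneven depth. Missing or
#' unreadable inputs are reported per sample and skipped, not fatal.
#'
#' @param samples Data.frame with columns `sample`, `species`, `alignment`
#'   (SAM/BAM path) and `ref` (FASTA path or `genome`).
#' @param params A [profile_params()].
#' @return Data.frame with `sample`, `species`, `mean_depth`,
#'   `depth_category`, `pi`, `anir`; failed rows are collected in the
#'   `failures` attribute.
#' @export
compare_environments <- function(samples, params = profile_params()) {
  cols <- c("sample", "species", "alignment", "ref")
  if (!all(cols %in% names(samples)))
    stop("'samples' needs columns: ", paste(cols, collapse = ", "))
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(samples))) {
    res <- tryCatch({
      p <- profile_genome(samples$alignment[i],
                          ref = samples$ref[i], params = params)
      data.frame(sample = samples$sample[i], species = samples$species[i],
                 mean_depth = p$mean_depth,
                 depth_category = as.character(depth_category(p$mean_depth)),
                 pi = p$pi, anir = p$anir)
    }, error = function(e) e)
    if (inherits(res, "error"))
      fails[[length(fails) + 1L]] <- data.frame(
        sample = samples$sample[i], species = samples$species[i],
        error = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample = character(), species = character(),
                         mean_depth = numeric(), depth_category = character(),
                         pi = numeric(), anir = numeric())
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  out
}

#' Write result tables and a run manifest
#'
#' Writes each table as TSV plus a `manifest.json` echoing the
#' configuration, seed, package/R versions and wall-clock time. Existing
#' files are overwritten.
#'
#' @param tables Named list of data.frames (NULL entries are skipped;
#'   empty data.frames yield header-only files).
#' @param output_dir Output directory (created if needed).
#' @param config Optional [experiment_config()] to echo into the manifest.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, output_dir, config = NULL) {
  t0 <- Sys.time()
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("cannot create directory: ", output_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(output_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "microdepth",
    package_version = as.character(utils::packageVersion("microdepth")),
    r_version = R.version.string,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) unclass(config[
      setdiff(names(config), "output_dir")]) else NULL,
    tables = basename(paths),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  mp <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}
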