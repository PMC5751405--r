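#' Pipeline configuration
#'
#' Bundles every tunable of the two-tier workflow. A seed is mandatory:
#' it governs the only stochastic stage (the DPGMM refinement sampler)
#' and makes whole runs reproducible.
#'
#' @param seed Integer seed for all randomness in the run.
#' @param min_length Minimum contig length in bp (default 1000).
#' @param epsilon DBSCAN radius in scaled units; `NULL` selects it from
#'   the k-distance curve.
#' @param min_points DBSCAN minimum-points parameter (default 4).
#' @param variance_threshold PCA explained-variance cutoff (default 0.9).
#' @param n_iterations,burn_in DPGMM Gibbs sweeps and burn-in (defaults
#'   300 / 100).
#' @param alpha Fixed DP concentration; `NULL` learns it under a
#'   Gamma(1, 1) prior.
#' @param min_bin_size Minimum contigs per output bin (default 5).
#' @param mode `"full"` for the two-tier workflow or
#'   `"composition_only"` to skip the primary coverage step and refine
#'   the whole sample in tetranucleotide space (ablation).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed, min_length = 1000L, epsilon = NULL,
                       min_points = 4L, variance_threshold = 0.9,
                       n_iterations = 300L, burn_in = 100L, alpha = NULL,
                       min_bin_size = 5L,
                       mode = c("full", "composition_only")) {
  if (missing(seed)) stop("a seed is required for reproducible runs")
  mode <- match.arg(mode)
  stopifnot(min_length >= 1L, min_points >= 1L,
            variance_threshold > 0, variance_threshold <= 1,
            burn_in < n_iterations, min_bin_size >= 1L)
  structure(list(seed = as.integer(seed), min_length = as.integer(min_length),
                 epsilon = epsilon, min_points = as.integer(min_points),
                 variance_threshold = variance_threshold,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), alpha = alpha,
                 min_bin_size = as.integer(min_bin_size), mode = mode),
            class = "run_config")
}

#' Bin contigs with the two-tier workflow
#'
#' Runs feature extraction, primary DBSCAN binning in GC-log(coverage)
#' space and tetranucleotide-space refinement, and returns per-contig
#' assignments with a full accounting of every exclusion.
#'
#' @param contigs A [Biostrings::DNAStringSet] named by contig id.
#' @param coverage Named numeric vector of per-contig coverages.
#' @param config A [run_config()].
#' @return List of class `binning_result` with `assignment` (data.frame
#'   id, bin, status; bin is `NA` unless status is `"binned"`; status is
#'   one of `"binned"`, `"noise"`, `"small_bin"`, `"short"`,
#'   `"zero_coverage"`), `labels` (named integer vector over evaluated
#'   contigs), `features`, `primary`, `counts` (stage accounting) and
#'   `config`.
#' @export
bin_contigs <- function(contigs, coverage, config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  ids <- names(contigs)
  features <- withCallingHandlers(
    build_feature_table(contigs, coverage, config$min_length),
    warning = function(w) invokeRestart("muffleWarning"))
  n_short <- attr(features, "n_short")
  n_zero <- attr(features, "n_zero_coverage")

  primary <- if (config$mode == "composition_only") {
    stats::setNames(rep(0L, nrow(features)), features$id)
  } else {
    primary_bin(features, epsilon = config$epsilon,
                min_points = config$min_points)
  }
  final <- refine_bins(primary, tnf_matrix(features),
                       lengths = stats::setNames(features$length, features$id),
                       variance_threshold = config$variance_threshold,
                       n_iterations = config$n_iterations,
                       burn_in = config$burn_in, alpha = config$alpha,
                       min_bin_size = config$min_bin_size)

  status <- stats::setNames(rep("binned", length(ids)), ids)
  short_ids <- ids[!(ids %in% features$id)]
  # distinguish the two exclusion reasons for unevaluated contigs
  too_short <- Biostrings::width(contigs) < config$min_length
  status[ids[too_short]] <- "short"
  status[setdiff(short_ids, ids[too_short])] <- "zero_coverage"
  evaluated <- features$id
  noise_ids <- evaluated[is.na(primary[evaluated])]
  status[noise_ids] <- "noise"
  dissolved_ids <- evaluated[!is.na(primary[evaluated]) & is.na(final[evaluated])]
  status[dissolved_ids] <- "small_bin"

  assignment <- data.frame(
    id = ids,
    bin = ifelse(ids %in% evaluated, final[ids], NA_integer_),
    status = unname(status[ids]),
    stringsAsFactors = FALSE)
  counts <- list(
    input = length(ids), short = sum(status == "short"),
    zero_coverage = sum(status == "zero_coverage"),
    noise = length(noise_ids), small_bin = length(dissolved_ids),
    binned = sum(status == "binned"),
    n_bins = length(unique(final[!is.na(final)])))
  structure(list(assignment = assignment, labels = final,
                 features = features, primary = primary,
                 counts = counts, config = config),
            class = "binning_result")
}

#' Extract the named label vector from a binning result
#'
#' Covers every input contig; contigs excluded at any stage carry `NA`.
#'
#' @param result A `binning_result` from [bin_contigs()].
#' @return Named integer vector of bin labels.
#' @export
as_assignment <- function(result) {
  stats::setNames(as.integer(result$assignment$bin), result$assignment$id)
}

#' Write one FASTA file per bin
#'
#' Files are named `bin_000.fasta`, `bin_001.fasta`, ... by descending
#' bin size with ties broken by smallest contig id; unclassified contigs
#' go to `unclassified.fasta`.
#'
#' @param contigs A [Biostrings::DNAStringSet] named by contig id.
#' @param labels Named integer vector of bin labels (`NA` =
#'   unclassified) covering the contigs.
#' @param outdir Output directory (created if needed).
#' @return Named character vector mapping bin label (or
#'   `"unclassified"`) to file path, invisibly.
#' @export
write_bins <- function(contigs, labels, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  labels <- labels[names(contigs)]
  bins <- unique(labels[!is.na(labels)])
  sizes <- vapply(bins, function(b) sum(labels == b, na.rm = TRUE), integer(1))
  min_id <- vapply(bins, function(b)
    min(names(contigs)[!is.na(labels) & labels == b]), character(1))
  ord <- order(-sizes, min_id)
  files <- character(0)
  for (i in seq_along(ord)) {
    b <- bins[ord[i]]
    path <- file.path(outdir, sprintf("bin_%03d.fasta", i - 1L))
    Biostrings::writeXStringSet(
      contigs[!is.na(labels) & labels == b], path)
    files[as.character(b)] <- path
  }
  un <- contigs[is.na(labels)]
  if (length(un) > 0L) {
    path <- file.path(outdir, "unclassified.fasta")
    Biostrings::writeXStringSet(un, path)
    files["unclassified"] <- path
  }
  invisible(files)
}

#' Run the full binning pipeline on files
#'
#' Reads contigs and coverage, runs [bin_contigs()], and writes
#' `features.tsv`, `assignments.tsv`, one FASTA per bin,
#' `unclassified.fasta` and `summary.json` (stage counts, bin sizes,
#' parameters, seed) to `out_dir`. Any stage failure is rethrown with
#' the stage name.
#'
#' @param contigs_path FASTA file of assembled contigs.
#' @param coverage_path Two-column coverage TSV.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The `binning_result`, invisibly.
#' @export
run_pipeline <- function(contigs_path, coverage_path, out_dir, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  contigs <- stage("read_contigs", read_contigs(contigs_path))
  coverage <- stage("read_coverage", read_coverage(coverage_path))
  result <- stage("bin_contigs", bin_contigs(contigs, coverage, config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage("write_output", {
    write_features(result$features, file.path(out_dir, "features.tsv"))
    assign_out <- result$assignment
    assign_out$bin <- ifelse(is.na(assign_out$bin), "unclassified",
                             as.character(assign_out$bin))
    write.table(assign_out, file.path(out_dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    labels_all <- as_assignment(result)
    write_bins(contigs, labels_all, out_dir)
    bin_sizes <- table(result$labels[!is.na(result$labels)])
    summary <- list(
      counts = result$counts,
      bin_sizes = as.list(stats::setNames(as.integer(bin_sizes),
                                          names(bin_sizes))),
      parameters = list(
        min_length = config$min_length,
        epsilon = attr(result$primary, "epsilon"),
        min_points = config$min_points,
        variance_threshold = config$variance_threshold,
        n_iterations = config$n_iterations,
        burn_in = config$burn_in,
        min_bin_size = config$min_bin_size,
        mode = config$mode),
      seed = config$seed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(result)
}
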