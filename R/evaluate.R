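#' Confusion matrix of a binning against ground truth
#'
#' Tallies `R[i, j]`, the number (or total weight) of contigs in bin `i`
#' originating from genome `j`, over classified contigs; unclassified
#' contigs are counted separately.
#'
#' @param assignment Named integer vector of bin labels (`NA` =
#'   unclassified), e.g. from [refine_bins()].
#' @param truth Named character vector mapping contig id to genome id;
#'   must cover every assigned contig.
#' @param weights Optional named numeric weights (e.g. contig lengths in
#'   bp) for base-pair-weighted evaluation; default counts each contig
#'   once.
#' @return List of class `bin_confusion` with elements `R` (bins x
#'   genomes matrix), `unclassified` (total weight of unclassified
#'   contigs), `bins`, and `genomes`.
#' @export
confusion_matrix <- function(assignment, truth, weights = NULL) {
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by contig id")
  missing <- setdiff(ids, names(truth))
  if (length(missing) > 0L) {
    stop("contig id(s) missing from ground truth: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  }
  w <- if (is.null(weights)) stats::setNames(rep(1, length(ids)), ids) else weights[ids]
  if (anyNA(w)) stop("weights missing for some contigs")
  genomes <- sort(unique(truth[ids]))
  classified <- !is.na(assignment)
  bins <- sort(unique(assignment[classified]))
  R <- matrix(0, nrow = length(bins), ncol = length(genomes),
              dimnames = list(as.character(bins), genomes))
  if (any(classified)) {
    tab <- tapply(w[classified],
                  list(factor(assignment[classified], levels = bins),
                       factor(truth[ids[classified]], levels = genomes)),
                  sum, default = 0)
    R[] <- tab
  }
  structure(list(R = R, unclassified = sum(w[!classified]),
                 bins = bins, genomes = genomes),
            class = "bin_confusion")
}

#' Binning precision
#'
#' Purity of the output bins: the fraction of classified contigs that
#' belong to the dominant genome of their bin,
#' 100 * sum_i max_j R_ij / sum_ij R_ij. Unclassified contigs do not
#' enter.
#'
#' @param cm A `bin_confusion` from [confusion_matrix()].
#' @return Percentage in [0, 100]; `NA` when nothing was classified.
#' @export
binning_precision <- function(cm) {
  total <- sum(cm$R)
  if (total == 0) return(NA_real_)
  100 * sum(apply(cm$R, 1L, max)) / total
}

#' Binning recall
#'
#' Completeness: the dominant-bin weight of every genome over all
#' evaluated contigs, unclassified ones included in the denominator,
#' 100 * sum_j max_i R_ij / (sum_ij R_ij + unclassified).
#'
#' @param cm A `bin_confusion` from [confusion_matrix()].
#' @return Percentage in [0, 100].
#' @export
binning_recall <- function(cm) {
  denom <- sum(cm$R) + cm$unclassified
  if (denom == 0) stop("empty evaluation set")
  if (nrow(cm$R) == 0L) return(0)
  100 * sum(apply(cm$R, 2L, max)) / denom
}

#' F1 score
#'
#' Harmonic mean of binning precision and recall, on the percentage
#' scale. Returns 0 when both are 0.
#'
#' @param precision,recall Percentages in [0, 100].
#' @return Percentage in [0, 100].
#' @export
binning_f1 <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Species discovered by a binning
#'
#' A genome S is discovered by bin C when strictly more than 50% of the
#' contigs in C come from S and strictly more than 50% of the contigs of
#' S sit in C. The genome total |S| is taken from the full truth table,
#' so contigs dropped before binning (length filter, zero coverage) count
#' against discovery unless `restrict = TRUE` limits totals to the
#' evaluated contigs.
#'
#' @param assignment Named integer vector of bin labels (`NA` =
#'   unclassified).
#' @param truth Named character vector contig id -> genome id (may cover
#'   more contigs than `assignment`).
#' @param weights Optional named numeric weights (see
#'   [confusion_matrix()]).
#' @param restrict Limit genome totals to contigs present in
#'   `assignment` (default `FALSE`).
#' @return data.frame with one row per discovered genome: `genome`,
#'   `bin`, `precision` (bin purity for that genome, %) and `pct_binned`
#'   (% of the genome's contigs in the bin).
#' @export
species_discovered <- function(assignment, truth, weights = NULL,
                               restrict = FALSE) {
  cm <- confusion_matrix(assignment, truth, weights)
  total_ids <- if (restrict) intersect(names(truth), names(assignment)) else names(truth)
  w <- if (is.null(weights)) stats::setNames(rep(1, length(total_ids)), total_ids) else weights[total_ids]
  genome_totals <- tapply(w, truth[total_ids], sum)
  rows <- list()
  row_sums <- if (nrow(cm$R) > 0L) rowSums(cm$R) else numeric(0)
  for (g in cm$genomes) {
    tot <- genome_totals[[g]]
    if (is.null(tot) || is.na(tot) || tot == 0) next
    for (i in seq_len(nrow(cm$R))) {
      r <- cm$R[i, g]
      if (r > 0.5 * row_sums[i] && r > 0.5 * tot) {
        rows[[length(rows) + 1L]] <- data.frame(
          genome = g, bin = cm$bins[i],
          precision = 100 * r / row_sums[i],
          pct_binned = 100 * r / tot,
          stringsAsFactors = FALSE)
        break  # at most one bin can hold > 50% of a genome
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome = character(0), bin = integer(0),
                      precision = numeric(0), pct_binned = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Evaluate a binning against ground truth
#'
#' Convenience wrapper computing the four standard binning measures.
#'
#' @inheritParams species_discovered
#' @return List with `precision`, `recall`, `f1`, `n_species`,
#'   `species` (per-species table) and `confusion`.
#' @export
evaluate_binning <- function(assignment, truth, weights = NULL,
                             restrict = FALSE) {
  cm <- confusion_matrix(assignment, truth, weights)
  p <- binning_precision(cm)
  r <- binning_recall(cm)
  f <- if (is.na(p)) NA_real_ else binning_f1(p, r)
  sp <- species_discovered(assignment, truth, weights, restrict)
  list(precision = p, recall = r, f1 = f,
       n_species = nrow(sp), species = sp, confusion = cm)
}
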