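#' Canonical tetramers
#'
#' The 136 canonical 4-mers: for every 4-mer over {A,C,G,T}, the
#' lexicographically smaller of the 4-mer and its reverse complement.
#' Folding a 256-long tetramer count vector onto these keys is equivalent
#' to pooling the counts of a sequence and its reverse complement.
#'
#' @return Character vector of the 136 canonical tetramers, sorted.
#' @export
canonical_tetramers <- function() {
  .tetramer_tables()$canonical
}

# cached lookup tables: all 256 tetramers, their reverse complements, and
# index pairs used to fold 256-long count vectors to 136 canonical keys
.tetramer_env <- new.env(parent = emptyenv())

.tetramer_tables <- function() {
  if (!is.null(.tetramer_env$tables)) return(.tetramer_env$tables)
  kmers <- names(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString("AAAA"), width = 4))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canonical <- sort(unique(pmin(kmers, rc)))
  idx_self <- match(canonical, kmers)
  idx_rc <- match(rc[idx_self], kmers)
  tables <- list(
    kmers = kmers,
    rc = rc,
    canonical = canonical,
    idx_self = idx_self,
    idx_rc = idx_rc,
    palindrome = idx_rc == idx_self
  )
  .tetramer_env$tables <- tables
  tables
}

#' Read assembled contigs from a FASTA file
#'
#' Contig identifiers are taken as the FASTA header up to the first
#' whitespace; sequences are uppercased. Duplicate identifiers and empty
#' files are errors.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  contigs <- Biostrings::readDNAStringSet(path)
  if (length(contigs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(contigs))
  if (any(ids == "")) stop("empty contig id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  }
  names(contigs) <- ids
  contigs
}

#' Read a per-contig coverage table
#'
#' Expects a two-column tab-separated file (contig id, mean read depth).
#' A header line is auto-detected when the second field of the first line
#' is not numeric. Coverages must be nonnegative numbers.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of coverages.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("coverage file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop("expected two tab-separated columns at line ", bad[1L])
  }
  first_val <- suppressWarnings(as.numeric(fields[[1L]][2L]))
  start <- if (is.na(first_val)) 2L else 1L
  if (start > length(lines)) stop("coverage file has a header but no data rows")
  ids <- vapply(fields[start:length(fields)], `[[`, character(1), 1L)
  vals <- suppressWarnings(
    as.numeric(vapply(fields[start:length(fields)], `[[`, character(1), 2L)))
  line_no <- seq_along(ids) + (start - 1L)
  if (anyNA(vals)) {
    stop("non-numeric coverage at line ", line_no[which(is.na(vals))[1L]])
  }
  if (any(vals < 0)) {
    stop("negative coverage at line ", line_no[which(vals < 0)[1L]])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate contig id(s) in coverage table: ", paste(dup, collapse = ", "))
  }
  stats::setNames(vals, ids)
}

#' Filter contigs by minimum length
#'
#' Retains contigs whose length is at least `min_len` (inclusive), in the
#' original order. Short contigs carry too weak a compositional signal to
#' be binned reliably.
#'
#' @param contigs A [Biostrings::DNAStringSet].
#' @param min_len Minimum length in bp (default 1000).
#' @return The retained subset, with attribute `n_removed`.
#' @export
filter_by_length <- function(contigs, min_len = 1000L) {
  stopifnot(min_len >= 1L)
  keep <- Biostrings::width(contigs) >= min_len
  out <- contigs[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases are excluded from
#' both numerator and denominator.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  counts <- Biostrings::letterFrequency(sequence, c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0) stop("sequence has no unambiguous (A/C/G/T) bases")
  unname((counts[["C"]] + counts[["G"]]) / tot)
}

#' Canonical tetranucleotide profile of a sequence
#'
#' Counts every 4-bp window containing only A/C/G/T (1-bp sliding window),
#' pools each tetramer with its reverse complement under the canonical key
#' (equivalent to aggregating the counts of the sequence and its reverse
#' complement), and normalizes to sum 1.
#'
#' @param sequence Character string or [Biostrings::DNAString], length >= 4.
#' @return Named numeric vector of 136 canonical tetramer frequencies.
#' @export
tetranucleotide_profile <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
  profile <- .fold_tetramer_counts(matrix(counts, nrow = 1,
                                          dimnames = list(NULL, names(counts))))
  drop(profile)
}

# Fold an n x 256 count matrix to n x 136 canonical frequencies (rows sum
# 1). In the pooled counts of a sequence plus its reverse complement every
# tetramer count appears doubled, so after normalization a canonical pair
# carries count(w) + count(revcomp(w)) while a palindromic tetramer
# (its own reverse complement) carries count(w) once.
.fold_tetramer_counts <- function(counts) {
  tb <- .tetramer_tables()
  rc_part <- counts[, tb$idx_rc, drop = FALSE]
  rc_part[, tb$palindrome] <- 0
  folded <- counts[, tb$idx_self, drop = FALSE] + rc_part
  colnames(folded) <- tb$canonical
  totals <- rowSums(folded)
  if (any(totals == 0)) {
    stop("no valid tetramer window (sequence shorter than 4 bp or all ",
         "windows contain ambiguous bases)")
  }
  folded / totals
}

#' Log-transform a coverage value
#'
#' Natural logarithm; defined only for strictly positive coverage.
#'
#' @param coverage Positive numeric vector.
#' @return log(coverage).
#' @export
log_transform_coverage <- function(coverage) {
  if (any(coverage <= 0)) stop("log coverage undefined for coverage <= 0")
  log(coverage)
}

#' Build the per-contig feature table
#'
#' Applies the length filter, drops zero-coverage contigs with a warning,
#' and computes GC content, log coverage and the canonical tetranucleotide
#' profile for every retained contig.
#'
#' @param contigs A [Biostrings::DNAStringSet] named by contig id.
#' @param coverages Named numeric vector of per-contig coverages.
#' @param min_len Minimum contig length in bp (default 1000).
#' @return A data.frame with columns `id`, `length`, `gc`, `coverage`,
#'   `log_coverage` followed by the 136 canonical tetramer frequency
#'   columns; attributes `n_short` and `n_zero_coverage` record exclusions.
#' @export
build_feature_table <- function(contigs, coverages, min_len = 1000L) {
  ids <- names(contigs)
  if (is.null(ids)) stop("contigs must be named by contig id")
  missing <- setdiff(ids, names(coverages))
  if (length(missing) > 0L) {
    stop("contig id(s) missing from coverage table: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  }
  kept <- filter_by_length(contigs, min_len)
  n_short <- attr(kept, "n_removed")
  cov <- coverages[names(kept)]
  zero <- cov <= 0
  if (any(zero)) {
    warning(sum(zero), " contig(s) with zero coverage excluded")
    kept <- kept[!zero]
    cov <- cov[!zero]
  }
  if (length(kept) == 0L) {
    stop("no contigs left after filtering; consider lowering min_len")
  }
  counts <- Biostrings::oligonucleotideFrequency(kept, width = 4)
  tnf <- .fold_tetramer_counts(counts)
  acgt <- Biostrings::letterFrequency(kept, c("A", "C", "G", "T"))
  denom <- rowSums(acgt)
  if (any(denom == 0)) {
    stop("contig(s) with no unambiguous bases: ",
         paste(names(kept)[denom == 0], collapse = ", "))
  }
  gc <- (acgt[, "C"] + acgt[, "G"]) / denom
  out <- data.frame(
    id = names(kept),
    length = Biostrings::width(kept),
    gc = unname(gc),
    coverage = unname(cov),
    log_coverage = log(unname(cov)),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(tnf))
  rownames(out) <- out$id
  attr(out, "n_short") <- n_short
  attr(out, "n_zero_coverage") <- sum(zero)
  out
}

#' Extract the tetranucleotide profile matrix from a feature table
#'
#' @param features Feature table from [build_feature_table()].
#' @return Numeric matrix (contigs x 136), rows named by contig id.
#' @export
tnf_matrix <- function(features) {
  m <- as.matrix(features[, canonical_tetramers(), drop = FALSE])
  rownames(m) <- features$id
  m
}

#' Write a feature table to TSV
#'
#' @param features Feature table from [build_feature_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
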