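#' Reduce tetranucleotide profiles by PCA
#'
#' Mean-centers the columns and keeps the smallest number of principal
#' components whose cumulative explained variance reaches
#' `variance_threshold`, capped at min(10, n - 1, ncol). Returns `NULL`
#' when the input is degenerate (fewer than 2 rows, or zero total
#' variance), signalling the caller to pass the bin through unrefined.
#'
#' @param profiles Numeric matrix (n x p), e.g. from [tnf_matrix()].
#' @param variance_threshold Fraction of variance to retain, in (0, 1].
#' @return Score matrix (n x d) in decreasing-variance order, or `NULL`.
#' @export
pca_reduce <- function(profiles, variance_threshold = 0.9) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) return(NULL)
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= .Machine$double.eps) return(NULL)
  cum <- cumsum(vars) / total
  d <- which(cum >= variance_threshold - 1e-12)[1L]
  if (is.na(d)) d <- length(vars)
  d <- min(d, 10L, nrow(profiles) - 1L, ncol(profiles))
  scores <- pc$x[, seq_len(d), drop = FALSE]
  attr(scores, "explained_variance") <- cum[d]
  scores
}

#' Dirichlet-process Gaussian mixture clustering by collapsed Gibbs sampling
#'
#' Fits an infinite Gaussian mixture (Dirichlet-process mixture with a
#' conjugate Normal-inverse-Wishart base measure) to the rows of `points`
#' with a collapsed Gibbs sampler: every sweep reassigns each point given
#' all others, with probability proportional to existing-component
#' occupancy times the posterior predictive density, or to `alpha` times
#' the prior predictive for a fresh component. The number of occupied
#' components is inferred from the data. The returned assignment is the
#' post-burn-in sample with the highest joint posterior (CRP partition
#' probability times component marginal likelihoods), which is
#' deterministic given the R random seed.
#'
#' @param points Numeric matrix (n x d) of observations.
#' @param n_iterations Number of Gibbs sweeps (default 300).
#' @param burn_in Sweeps discarded before tracking the posterior (default
#'   100; must be < `n_iterations`).
#' @param alpha Fixed Dirichlet-process concentration; `NULL` (default)
#'   places a vague Gamma(1, 1) prior on it, resampled every sweep.
#' @param kappa0 Prior strength on the component mean (pseudo-observation
#'   count, default 0.05: component means are barely tied to the grand
#'   mean).
#' @param nu0 Inverse-Wishart degrees of freedom; default d + 3.
#' @param scale_prior Prior expected component covariance as a fraction
#'   of the pooled per-dimension data variance (default 1: without other
#'   information a cluster is expected to look like the data at hand,
#'   which protects homogeneous inputs from being shredded into
#'   micro-clusters).
#' @param learn_scale Experimental: place a conjugate Wishart hyperprior
#'   on the base-measure scale and resample it every sweep (default
#'   `FALSE`).
#' @param init_singletons Start the chain from singleton components
#'   (default `TRUE`). Merge moves mix far better than split nucleation
#'   under collapsed Gibbs sampling, so an over-segmented start reaches
#'   well-separated structure reliably while homogeneous data still
#'   coalesces to one component.
#' @param diagonal Use the per-dimension (diagonal covariance) base
#'   measure instead of the full Normal-inverse-Wishart (default
#'   `FALSE`; the full model is affordable at the dimensionalities left
#'   after PCA reduction and handles correlated axes).
#' @return List with `assignment` (integer components 1..k, relabeled in
#'   order of first appearance), `k`, `log_posterior`, `alpha` (last
#'   sampled value), and `k_trace` (occupied components per sweep).
#' @export
dpgmm_gibbs <- function(points, n_iterations = 300L, burn_in = 100L,
                        alpha = NULL, kappa0 = 0.05, nu0 = NULL,
                        scale_prior = 1, learn_scale = FALSE,
                        init_singletons = TRUE, diagonal = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  stopifnot(n >= 1L, d >= 1L, burn_in < n_iterations)
  if (any(!is.finite(points))) stop("non-finite values in input matrix")
  if (n == 1L) {
    return(list(assignment = 1L, k = 1L, log_posterior = 0,
                alpha = if (is.null(alpha)) 1 else alpha,
                k_trace = rep(1L, n_iterations)))
  }
  if (is.null(nu0)) nu0 <- d + 3
  m0 <- colMeans(points)
  v <- rep(mean(pmax(apply(points, 2L, var), 1e-8)), d)
  # isotropic initial S0 such that E[Sigma] = scale_prior * diag(v)
  S0 <- diag(scale_prior * v * (nu0 - d - 1), nrow = d)
  learn_alpha <- is.null(alpha)
  alpha0 <- if (learn_alpha) 1 else alpha
  fit <- dpgmm_gibbs_cpp(points, as.integer(n_iterations),
                         as.integer(burn_in), alpha0, learn_alpha,
                         1, 1, m0, kappa0, nu0, S0, isTRUE(diagonal),
                         isTRUE(learn_scale), isTRUE(init_singletons))
  z <- fit$assignment
  relab <- match(z, unique(z))
  list(assignment = relab, k = max(relab),
       log_posterior = fit$log_posterior, alpha = fit$alpha,
       k_trace = fit$k_trace)
}

#' Refine primary bins in tetranucleotide space
#'
#' Each primary bin with at least `2 * min_bin_size` contigs is split by
#' clustering its contigs' tetranucleotide profiles: PCA reduction
#' followed by [dpgmm_gibbs()]. Smaller bins pass through unsplit. Any
#' resulting bin with fewer than `min_bin_size` contigs is dissolved to
#' unclassified; contigs unclassified by the primary step stay
#' unclassified. Refinement never merges primary bins, so the final
#' partition is a strict sub-partition of the primary one.
#'
#' When contig lengths are supplied the centered profiles are
#' variance-stabilized before PCA: each contig's deviation from the bin
#' mean is scaled by `sqrt(length / median length)`. Tetramer
#' frequencies are multinomial proportions, so their sampling noise has
#' variance proportional to 1 / length; without this correction short
#' contigs scatter far from the bin centroid and a Gaussian mixture
#' explains the resulting scale mixture with spurious components.
#'
#' The number of retained principal components is additionally capped at
#' `n / 5` (at least 1): a mixture covariance cannot be estimated from
#' fewer than a handful of points per dimension, and noise-dominated
#' small bins would otherwise be shredded.
#'
#' @param primary Named integer vector of primary bin labels (`NA` =
#'   unclassified), as from [primary_bin()].
#' @param tnf Tetranucleotide profile matrix with rows named by contig id,
#'   covering every contig in `primary`.
#' @param lengths Optional named vector of contig lengths in bp used for
#'   the variance stabilization; `NULL` disables it.
#' @param variance_threshold PCA explained-variance cutoff (default 0.9).
#' @param n_iterations,burn_in,alpha DPGMM sampler settings, see
#'   [dpgmm_gibbs()].
#' @param min_bin_size Minimum contigs per output bin (default 5).
#' @return Named integer vector of final 0-based bin labels (`NA` =
#'   unclassified), relabeled contiguously; attribute `n_dissolved` counts
#'   contigs dropped by the small-bin filter.
#' @export
refine_bins <- function(primary, tnf, lengths = NULL,
                        variance_threshold = 0.9,
                        n_iterations = 300L, burn_in = 100L, alpha = NULL,
                        min_bin_size = 5L) {
  ids <- names(primary)
  if (is.null(ids)) stop("primary labels must be named by contig id")
  if (!all(ids %in% rownames(tnf))) {
    stop("tnf matrix does not cover all contigs in the primary assignment")
  }
  final <- stats::setNames(rep(NA_integer_, length(primary)), ids)
  next_label <- 0L
  n_dissolved <- 0L
  for (b in sort(unique(primary[!is.na(primary)]))) {
    members <- ids[!is.na(primary) & primary == b]
    if (length(members) >= 2L * min_bin_size) {
      prof <- tnf[members, , drop = FALSE]
      if (!is.null(lengths)) {
        centered <- sweep(prof, 2L, colMeans(prof))
        w <- sqrt(lengths[members] / stats::median(lengths[members]))
        prof <- centered * w
      }
      scores <- pca_reduce(prof, variance_threshold)
      sub <- if (is.null(scores)) {
        rep(1L, length(members))
      } else {
        d_cap <- max(1L, length(members) %/% 5L)
        scores <- scores[, seq_len(min(ncol(scores), d_cap)), drop = FALSE]
        dpgmm_gibbs(scores, n_iterations = n_iterations, burn_in = burn_in,
                    alpha = alpha)$assignment
      }
    } else {
      sub <- rep(1L, length(members))
    }
    for (s in unique(sub)) {
      grp <- members[sub == s]
      if (length(grp) < min_bin_size) {
        n_dissolved <- n_dissolved + length(grp)
      } else {
        final[grp] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  attr(final, "n_dissolved") <- n_dissolved
  final
}
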