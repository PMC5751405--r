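#' Standardize the GC / log-coverage plane
#'
#' Per-axis z-scoring with the population standard deviation, so that the
#' Euclidean metric used by DBSCAN weighs the two axes comparably (GC lives
#' in [0,1], log coverage spans several units). A constant axis is mapped
#' to zeros with a warning.
#'
#' @param points Numeric matrix (n x d), n >= 2.
#' @return Scaled matrix of the same shape.
#' @export
scale_features <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points to scale")
  scaled <- apply(points, 2L, function(x) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    if (s == 0) {
      warning("constant axis mapped to zeros")
      return(rep(0, length(x)))
    }
    (x - mu) / s
  })
  matrix(scaled, nrow = nrow(points), dimnames = dimnames(points))
}

#' Density-based clustering (DBSCAN)
#'
#' Core points have at least `min_points` neighbors (the point itself
#' included) within Euclidean radius `epsilon`. Clusters are grown
#' recursively from core points; border points join the cluster that
#' reaches them first under the fixed input-order scan; everything else is
#' noise. Deterministic for a fixed input order.
#'
#' @param points Numeric matrix (n x d).
#' @param epsilon Neighborhood radius, > 0.
#' @param min_points Minimum neighborhood occupancy, >= 1 (self included).
#' @return Integer vector of 0-based cluster labels, `NA` for noise, with
#'   attribute `core` (logical vector of core-point flags).
#' @export
dbscan <- function(points, epsilon, min_points = 4L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1L, epsilon > 0, min_points >= 1L)
  dmat <- as.matrix(dist(points))
  neighbors <- lapply(seq_len(n), function(i) which(dmat[i, ] <= epsilon))
  core <- lengths(neighbors) >= min_points
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    labels[i] <- next_label
    queue <- i
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in neighbors[[p]]) {
        if (is.na(labels[q])) {
          labels[q] <- next_label
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
    next_label <- next_label + 1L
  }
  if (!is.null(rownames(points))) names(labels) <- rownames(points)
  attr(labels, "core") <- core
  labels
}

#' Choose the DBSCAN radius from the k-distance curve
#'
#' Sorts every point's distance to its k-th nearest neighbor (k =
#' `min_points`, self excluded) and returns the value at the knee of the
#' curve, located as the point of maximum perpendicular distance to the
#' chord joining the curve endpoints. A user-supplied `epsilon` overrides
#' the heuristic.
#'
#' @param points Numeric matrix (n x d), n >= min_points + 1.
#' @param min_points DBSCAN minimum-points parameter.
#' @param epsilon Optional user override, returned unchanged.
#' @param floor Lower bound for the returned radius (default 1e-6), guards
#'   degenerate inputs such as duplicated points.
#' @return Positive scalar radius.
#' @export
select_epsilon <- function(points, min_points = 4L, epsilon = NULL,
                           floor = 1e-6) {
  if (!is.null(epsilon)) {
    stopifnot(epsilon > 0)
    return(epsilon)
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < min_points + 1L) {
    stop("need at least min_points + 1 points to choose epsilon")
  }
  dmat <- as.matrix(dist(points))
  kdist <- apply(dmat, 1L, function(dr) sort(dr)[min_points + 1L])
  v <- sort(kdist)
  # perpendicular distance from each curve point to the endpoint chord
  x <- seq_along(v)
  x1 <- x[1L]; y1 <- v[1L]; x2 <- x[n]; y2 <- v[n]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (denom == 0) return(max(v[n], floor))
  d_chord <- abs((y2 - y1) * x - (x2 - x1) * v + x2 * y1 - y2 * x1) / denom
  max(v[which.max(d_chord)], floor)
}

#' Primary binning of contigs in GC-log(coverage) space
#'
#' Scales the (GC, log coverage) plane and runs DBSCAN on it. Noise
#' contigs are left unclassified (`NA`); they are outliers of the density
#' structure and would otherwise contaminate bins.
#'
#' @param features Feature table from [build_feature_table()].
#' @param epsilon DBSCAN radius in scaled units; `NULL` (default) selects
#'   it from the k-distance curve via [select_epsilon()].
#' @param min_points DBSCAN minimum-points parameter (default 4, the
#'   classic heuristic for 2-D data).
#' @return Named integer vector of 0-based primary bin labels (`NA` =
#'   unclassified), with attributes `epsilon` and `min_points`.
#' @export
primary_bin <- function(features, epsilon = NULL, min_points = 4L) {
  stopifnot(nrow(features) >= 1L)
  pts <- cbind(gc = features$gc, log_coverage = features$log_coverage)
  rownames(pts) <- features$id
  if (nrow(pts) == 1L) {
    labels <- stats::setNames(0L, features$id)
    attr(labels, "epsilon") <- epsilon
    attr(labels, "min_points") <- min_points
    return(labels)
  }
  scaled <- scale_features(pts)
  eps <- if (nrow(scaled) >= min_points + 1L) {
    select_epsilon(scaled, min_points, epsilon)
  } else {
    if (is.null(epsilon)) 0.5 else epsilon
  }
  labels <- dbscan(scaled, eps, min_points)
  attr(labels, "core") <- NULL
  attr(labels, "epsilon") <- eps
  attr(labels, "min_points") <- min_points
  labels
}
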