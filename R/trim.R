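#' Partition a cloud into small horizontal blocks
#'
#' Lays a square 2D grid of side `block_side` over the horizontal (x/y)
#' plane and assigns every point to exactly one cell. Steep regions of the
#' back surface — the bulbous head and tail, the flanks — stack many points
#' of different heights into the same small cell, which is what the
#' weighted local density of [weighted_local_density()] picks up.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param block_side cell side in meters (default 0.02).
#' @return an object of class `block_grid`: list with `block_side`, `cells`
#'   (B x 2 integer cell indices), `members` (list of point-index vectors),
#'   `centers` (B x 3, mean of member points), `density` (length B).
#' @export
build_block_grid <- function(cloud, block_side = 0.02) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 1L) stop("build_block_grid: empty cloud")
  if (block_side <= 0) stop("build_block_grid: block_side must be > 0")
  p <- cloud$points
  origin <- c(min(p[, 1]), min(p[, 2]))
  ij <- floor(cbind(p[, 1] - origin[1], p[, 2] - origin[2]) / block_side)
  key <- paste(ij[, 1], ij[, 2])
  grp <- match(key, unique(key))
  members <- split(seq_len(nrow(p)), grp)
  cells <- ij[!duplicated(grp), , drop = FALSE][order(unique(grp)), , drop = FALSE]
  cnt <- tabulate(grp)
  centers <- rowsum(p, grp) / cnt
  density <- vapply(seq_along(members), function(b)
    block_density(p[members[[b]], , drop = FALSE], centers[b, ]), numeric(1))
  structure(list(block_side = block_side, cells = cells, members = members,
                 centers = centers, density = density),
            class = "block_grid")
}

# Mean distance to the block center after discarding the single farthest
# point: (sum d_i - max d_i) / (n - 1); zero for blocks of <= 1 point.
block_density <- function(pts, center) {
  n <- nrow(pts)
  if (n <= 1L) return(0)
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  (sum(d) - max(d)) / (n - 1)
}

#' Weighted local density of one block
#'
#' The mean distance of a block's member points to the block center with the
#' influence of the single farthest point subtracted, i.e.
#' `(sum(d) - max(d)) / (n - 1)` for n >= 2 and 0 otherwise. Robust to one
#' stray outlier per block; invariant to point order.
#'
#' @param grid a `block_grid`.
#' @param block block index in `grid`.
#' @param cloud the cloud the grid was built from.
#' @return non-negative scalar (meters).
#' @export
weighted_local_density <- function(grid, block, cloud) {
  stopifnot(inherits(grid, "block_grid"))
  idx <- grid$members[[block]]
  block_density(cloud$points[idx, , drop = FALSE], grid$centers[block, ])
}

#' Density-based clustering (DBSCAN)
#'
#' Plain DBSCAN over rows of a coordinate matrix: a point is core if its
#' closed eps-neighbourhood (itself included) holds at least `min_samples`
#' points; clusters grow from core points; non-reachable points get label 0
#' (noise).
#'
#' @param x numeric matrix of observations (rows).
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return integer labels, 0 = noise, clusters numbered from 1.
#' @export
dbscan_cluster <- function(x, eps, min_samples) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  d2 <- sqdist_xc(x, x)
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(n)     # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nb[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]; frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Trimming parameters
#'
#' @param block_side block side for [build_block_grid()], meters.
#' @param dbscan_eps DBSCAN radius over block centers, meters.
#' @param dbscan_min_samples DBSCAN core threshold.
#' @param trim_extent span removed beyond each endpoint, meters.
#' @param density_percentile blocks above this percentile of the weighted
#'   local density count as density maxima.
#' @return list of class `trim_params`.
#' @export
trim_params <- function(block_side = 0.02, dbscan_eps = 0.5,
                        dbscan_min_samples = 10L, trim_extent = 0.4,
                        density_percentile = 90) {
  stopifnot(block_side > 0, dbscan_eps > 0, trim_extent > 0,
            dbscan_min_samples >= 1, density_percentile > 0,
            density_percentile < 100)
  structure(list(block_side = block_side, dbscan_eps = dbscan_eps,
                 dbscan_min_samples = as.integer(dbscan_min_samples),
                 trim_extent = trim_extent,
                 density_percentile = density_percentile),
            class = "trim_params")
}

#' Locate the head and tail endpoints of the animal
#'
#' Selects the blocks whose weighted local density exceeds the
#' `density_percentile` of all block densities, clusters their centers with
#' DBSCAN, and among the non-noise blocks returns the centers with minimal
#' and maximal projection onto `body_axis`. The protruding head and tail are
#' the steepest parts of the back surface, so the extreme high-density
#' blocks sit on them.
#'
#' @param grid a `block_grid`.
#' @param params a [trim_params()].
#' @param body_axis unit 3-vector of the body-length direction.
#' @return list with `low` and `high` (3-vectors, the endpoints at minimal /
#'   maximal axis projection), or `NULL` when no usable density maxima exist
#'   (the trim-failure signal; callers may skip trimming).
#' @export
locate_endpoints <- function(grid, params = trim_params(),
                             body_axis = c(1, 0, 0)) {
  stopifnot(inherits(grid, "block_grid"))
  thr <- stats::quantile(grid$density, params$density_percentile / 100,
                         names = FALSE)
  keep <- which(grid$density > thr)
  if (length(keep) < 2L) return(NULL)
  centers <- grid$centers[keep, , drop = FALSE]
  lab <- dbscan_cluster(centers, params$dbscan_eps, params$dbscan_min_samples)
  inlier <- lab != 0L
  if (!any(inlier)) return(NULL)
  proj <- centers[inlier, , drop = FALSE] %*% body_axis
  if (length(proj) < 2L) return(NULL)
  cin <- centers[inlier, , drop = FALSE]
  list(low = cin[which.min(proj), ], high = cin[which.max(proj), ])
}

# Principal horizontal direction of a cloud: leading eigenvector of the
# covariance of (x, y), embedded as a unit 3-vector with z = 0.
horizontal_principal_axis <- function(cloud) {
  xy <- cloud$points[, 1:2, drop = FALSE]
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  c(ev, 0) / sqrt(sum(ev^2))
}

#' Remove the head and tail from a segmented pig cloud
#'
#' Builds the block grid, locates the two density-maximum endpoints along
#' the horizontal principal (body-length) axis, and strips every point whose
#' axis projection lies within `trim_extent` of either endpoint's
#' projection. When endpoint location fails the input is returned unchanged
#' with an empty `removed` part and a warning.
#'
#' The head endpoint is taken to be the one whose surrounding high-density
#' neighbourhood holds more points (a sow's head is bulkier than her tail);
#' it is recorded in the result so the downstream width measurement can map
#' slices to anatomy.
#'
#' @param cloud the segmented pig [point_cloud()].
#' @param params a [trim_params()].
#' @return list of class `trim_result` with `trimmed` and `removed`
#'   point clouds, `head_point`, `tail_point` (3-vectors or NULL), `axis`,
#'   and `trimmed_idx` / `removed_idx` (indices into the input cloud).
#' @export
remove_head_tail <- function(cloud, params = trim_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  axis <- horizontal_principal_axis(cloud)
  grid <- build_block_grid(cloud, params$block_side)
  ends <- locate_endpoints(grid, params, body_axis = axis)
  if (is.null(ends)) {
    warning("remove_head_tail: no usable density maxima; cloud left untrimmed")
    empty <- subset_cloud(cloud, integer(0))
    return(structure(list(trimmed = cloud, removed = empty,
                          head_point = NULL, tail_point = NULL, axis = axis,
                          trimmed_idx = seq_len(n_points(cloud)),
                          removed_idx = integer(0)),
                     class = "trim_result"))
  }
  proj <- as.vector(cloud$points %*% axis)
  p_lo <- sum(ends$low * axis)
  p_hi <- sum(ends$high * axis)
  drop <- (proj <= p_lo + params$trim_extent) |
          (proj >= p_hi - params$trim_extent)
  if (all(drop))
    warning("remove_head_tail: cloud shorter than twice the trim extent; ",
            "all points removed")
  # bulkier end = head: count points within trim range of each endpoint
  n_lo <- sum(proj <= p_lo + params$trim_extent)
  n_hi <- sum(proj >= p_hi - params$trim_extent)
  head_point <- if (n_lo >= n_hi) ends$low else ends$high
  tail_point <- if (n_lo >= n_hi) ends$high else ends$low
  structure(list(trimmed = subset_cloud(cloud, !drop),
                 removed = subset_cloud(cloud, drop),
                 head_point = head_point, tail_point = tail_point,
                 axis = axis,
                 trimmed_idx = which(!drop), removed_idx = which(drop)),
            class = "trim_result")
}
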