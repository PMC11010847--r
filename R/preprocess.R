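#' Voxel-grid down-sampling
#'
#' Partitions space into cubic voxels of side `edgelength`, anchored at the
#' cloud's minimum corner with half-open cells, and replaces the points of
#' each occupied voxel by their arithmetic mean. When colours are present the
#' per-voxel colour is the rounded mean of the member colours. This both
#' thins the cloud and suppresses sensor noise; an edge of 0.03 m is the
#' working default for overhead pig-back captures.
#'
#' @param cloud a [point_cloud()] with at least one point.
#' @param edgelength voxel edge in meters, > 0.
#' @return a [point_cloud()] with one point per occupied voxel. The output
#'   carries an attribute `voxel_counts` (points per occupied voxel).
#' @export
voxel_downsample <- function(cloud, edgelength = 0.03) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 1L) stop("voxel_downsample: empty cloud")
  if (!is.numeric(edgelength) || length(edgelength) != 1L || edgelength <= 0)
    stop("voxel_downsample: `edgelength` must be a positive number")

  p <- cloud$points
  origin <- apply(p, 2, min)
  ijk <- floor(sweep(p, 2, origin) / edgelength)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  grp <- match(key, unique(key))           # first-occurrence order
  cnt <- tabulate(grp)
  means <- rowsum(p, grp) / cnt
  cols <- NULL
  if (has_colors(cloud)) {
    cols <- round(rowsum(cloud$colors + 0, grp) / cnt)
    storage.mode(cols) <- "integer"
  }
  out <- point_cloud(means, colors = cols, source_id = cloud$source_id)
  attr(out, "voxel_counts") <- cnt
  out
}

#' K-means segmentation of a point cloud
#'
#' Lloyd's algorithm on the xyz coordinates only (colour never enters the
#' distance): centroids are initialized as a uniform random choice of K
#' distinct points, each point is assigned to its nearest centroid by
#' Euclidean distance, centroids are updated to cluster means, and iteration
#' stops when no centroid moves more than `tol`. The best of `n_restarts`
#' runs by the sum of squared errors (SSE) is kept; the result is
#' deterministic for a fixed `seed`. A cluster left empty during iteration is
#' reseeded from the point currently farthest from its centroid.
#'
#' @param cloud a [point_cloud()].
#' @param K number of clusters, `1 <= K <= N`.
#' @param seed RNG seed controlling initialization.
#' @param n_restarts independent restarts; best SSE wins.
#' @param tol convergence tolerance on centroid motion, meters.
#' @param max_iter iteration cap per restart.
#' @return an object of class `segmentation`: list with `labels` (1..K),
#'   `centroids` (K x 3), `K`, `sse`.
#' @export
kmeans_cluster <- function(cloud, K, seed = 1L, n_restarts = 10L,
                           tol = 1e-6, max_iter = 300L) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  n <- nrow(p)
  if (K < 1L) stop("kmeans_cluster: K must be >= 1")
  if (K > n) stop("kmeans_cluster: K exceeds the number of points")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- p[sample.int(n, K), , drop = FALSE]
      fit <- lloyd_iterate(p, init, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  structure(list(labels = best$labels, centroids = best$centroids,
                 K = as.integer(K), sse = best$sse),
            class = "segmentation")
}

# Squared Euclidean distances between every row of x (n x 3) and of c (k x 3).
sqdist_xc <- function(x, cent) {
  d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") - 2 * x %*% t(cent)
  d2[d2 < 0] <- 0
  d2
}

# One Lloyd run from the given initial centroids.
lloyd_iterate <- function(p, cent, tol, max_iter) {
  n <- nrow(p); K <- nrow(cent)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_xc(p, cent)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters from the worst-fit point
    repeat {
      sz <- tabulate(labels, nbins = K)
      if (all(sz > 0L)) break
      ownd <- d2[cbind(seq_len(n), labels)]
      far <- which.max(ownd)
      empty <- which(sz == 0L)[1]
      cent[empty, ] <- p[far, ]
      labels[far] <- empty
      d2[, empty] <- rowSums(sweep(p, 2, cent[empty, ])^2)
    }
    newc <- rowsum(p, labels) / tabulate(labels, nbins = K)
    move <- sqrt(max(rowSums((newc - cent)^2)))
    cent <- newc
    if (move <= tol) break
  }
  d2 <- sqdist_xc(p, cent)
  labels <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = cent, sse = sse)
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: K = %d, SSE = %.6g, cluster sizes: %s\n",
              x$K, x$sse, paste(tabulate(x$labels, x$K), collapse = ", ")))
  invisible(x)
}

#' Elbow selection of the cluster count
#'
#' Runs [kmeans_cluster()] for every K in `k_range` and picks the interior K
#' where the SSE curve bends most sharply: the K maximizing the second-order
#' difference SSE(K-1) - 2 SSE(K) + SSE(K+1). This operationalizes "the K
#' where the SSE suddenly stops improving".
#'
#' @param cloud a [point_cloud()].
#' @param k_range integer vector of candidate K (>= 3 values, consecutive).
#' @param seed RNG seed passed to each K-means run.
#' @param n_restarts restarts per K.
#' @return list with `K` (chosen) and `sse_curve` (named numeric, one SSE
#'   per candidate K).
#' @export
elbow_select_k <- function(cloud, k_range = 1:8, seed = 1L, n_restarts = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L)
    stop("elbow_select_k: need at least 3 candidate values of K")
  if (min(k_range) < 1L || max(k_range) > n_points(cloud))
    stop("elbow_select_k: k_range must lie within [1, N]")
  sse <- vapply(k_range, function(k)
    kmeans_cluster(cloud, k, seed = seed, n_restarts = n_restarts)$sse,
    numeric(1))
  names(sse) <- k_range
  curv <- sse[-c(length(sse) - 1L, length(sse))] -
    2 * sse[-c(1L, length(sse))] + sse[-(1:2)]
  chosen <- k_range[which.max(curv) + 1L]
  list(K = chosen, sse_curve = sse)
}

#' Extract the pig cluster from a segmented scene
#'
#' With the camera overhead, the animal's back is the raised surface between
#' the floor and the lens, so the pig cluster is the one whose mean elevation
#' toward the camera is greatest (ties broken by point count). The elevation
#' of a point is its coordinate along `camera_axis`, signed so that positive
#' means closer to the camera.
#'
#' @param cloud the segmented [point_cloud()].
#' @param seg a `segmentation` from [kmeans_cluster()] on the same cloud.
#' @param camera_axis `"x"`, `"y"` or `"z"`; default `"z"` (camera above).
#' @param camera_sign `"+"` if the camera lies toward increasing coordinate
#'   values along that axis, `"-"` otherwise.
#' @return the pig [point_cloud()], colours carried through, with attribute
#'   `cluster` giving the selected label.
#' @export
extract_pig_cluster <- function(cloud, seg, camera_axis = "z",
                                camera_sign = "+") {
  stopifnot(inherits(cloud, "point_cloud"), inherits(seg, "segmentation"))
  if (length(seg$labels) != n_points(cloud))
    stop("extract_pig_cluster: segmentation does not match cloud size")
  axis <- match(match.arg(camera_axis, c("x", "y", "z")), c("x", "y", "z"))
  sgn <- if (identical(camera_sign, "-") || identical(camera_sign, -1)) -1 else 1
  elev <- sgn * cloud$points[, axis]
  mean_elev <- tapply(elev, seg$labels, mean)
  sizes <- tabulate(seg$labels, seg$K)
  # greatest mean elevation; ties (to 1e-12) broken by larger cluster
  ord <- order(-round(mean_elev, 12), -sizes[as.integer(names(mean_elev))])
  pick <- as.integer(names(mean_elev))[ord[1]]
  out <- subset_cloud(cloud, seg$labels == pick)
  attr(out, "cluster") <- pick
  out
}
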