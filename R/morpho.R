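#' Fit an oriented bounding box (OBB)
#'
#' PCA box: the axes are the principal directions of the cloud's covariance
#' and the extents are the projection ranges along them. Deterministic up to
#' axis sign; signs are fixed so the long axis has a positive x component.
#' Rows of `axes` are ordered by decreasing extent, so row 1 is the
#' body-length direction for an elongated back cloud.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @return object of class `oriented_box`: list with `center` (3-vector),
#'   `axes` (3 x 3 orthonormal, rows = box axes), `extents` (full side
#'   lengths, non-increasing).
#' @export
fit_obb <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  if (nrow(p) < 3L) stop("fit_obb: need at least 3 points")
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  axes <- t(ev$vectors)                     # rows = candidate axes
  proj <- p %*% t(axes)
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  extents <- hi - lo
  ord <- order(extents, decreasing = TRUE)
  axes <- axes[ord, , drop = FALSE]
  extents <- extents[ord]
  lo <- lo[ord]; hi <- hi[ord]
  if (extents[2] < 1e-9)
    stop("fit_obb: degenerate geometry (points are collinear)")
  for (i in 1:3) {
    s <- sign(axes[i, 1])
    if (s == 0) s <- sign(axes[i, 2] + axes[i, 3] / 2)
    if (s < 0) { axes[i, ] <- -axes[i, ]; tmp <- lo[i]; lo[i] <- -hi[i]; hi[i] <- -tmp }
  }
  center <- as.vector(((lo + hi) / 2) %*% axes)
  structure(list(center = center, axes = axes, extents = extents),
            class = "oriented_box")
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf("oriented_box: extents %.3f x %.3f x %.3f m\n",
              x$extents[1], x$extents[2], x$extents[3]))
  invisible(x)
}

#' Correct the horizontal pose of a back cloud
#'
#' If the angle (in the horizontal plane) between the OBB long axis and the
#' x axis exceeds `threshold_deg`, the cloud is rotated about the vertical
#' axis through its centroid so the body axis lies along x; otherwise it is
#' returned unchanged. Pitch and roll are left untouched: only the
#' horizontal tilt matters for slicing the back along x.
#'
#' @param cloud a [point_cloud()].
#' @param threshold_deg tolerated residual angle in degrees (default 1).
#' @return list of class `pose_result`: `corrected` (the cloud),
#'   `applied_deg` (signed rotation actually applied, 0 when under
#'   threshold), `center` (pivot used). Apply the same transform to
#'   companion points with [apply_pose()].
#' @export
correct_pose <- function(cloud, threshold_deg = 1.0) {
  box <- fit_obb(cloud)
  a <- box$axes[1, ]
  if (sqrt(a[1]^2 + a[2]^2) < 1e-9)
    stop("correct_pose: body axis is vertical; no horizontal pose defined")
  theta <- atan2(a[2], a[1]) * 180 / pi      # in (-90, 90] since a[1] >= 0
  if (theta > 90) theta <- theta - 180
  center <- colMeans(cloud$points)
  if (abs(theta) <= threshold_deg) {
    return(structure(list(corrected = cloud, applied_deg = 0,
                          center = center), class = "pose_result"))
  }
  out <- transform_cloud(cloud, rotation = rotz(-theta), center = center)
  structure(list(corrected = out, applied_deg = theta, center = center),
            class = "pose_result")
}

#' Apply a pose correction to companion points
#'
#' Maps auxiliary coordinates (e.g. the head endpoint recorded during
#' trimming) through the same rotation that [correct_pose()] applied to the
#' cloud.
#'
#' @param pose a `pose_result`.
#' @param pts 3-vector or N x 3 matrix.
#' @return transformed coordinates, same shape as `pts`.
#' @export
apply_pose <- function(pose, pts) {
  single <- is.null(dim(pts))
  m <- if (single) matrix(pts, ncol = 3) else as.matrix(pts)
  m <- sweep(m, 2, pose$center)
  m <- m %*% t(rotz(-pose$applied_deg))
  m <- sweep(m, 2, pose$center, "+")
  if (single) as.vector(m) else m
}

#' Shoulder, abdominal and hip widths by three-section slicing
#'
#' The pose-corrected back cloud is split into three equal sections along x.
#' Each section is divided into `n_bins_per_section` x bins; the width of a
#' bin is `max(y) - min(y)` over its points and the width of a section is
#' the maximum over its non-empty bins. Sections are mapped to anatomy by
#' proximity to the head endpoint when one is supplied (nearest section =
#' shoulder, farthest = hip); without a head endpoint the section at low x
#' is called the shoulder.
#'
#' @param cloud pose-corrected [point_cloud()].
#' @param n_bins_per_section x bins per section (default 20).
#' @param head_point optional 3-vector locating the head end, already mapped
#'   through the same pose correction as the cloud.
#' @return object of class `body_measurements`: list with `shoulder`,
#'   `abdomen`, `hip` (meters), `section_bounds` (4 x coordinates), and
#'   `section_widths` (widths in x order, before anatomical mapping).
#' @export
measure_widths <- function(cloud, n_bins_per_section = 20L,
                           head_point = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  x <- cloud$points[, 1]; y <- cloud$points[, 2]
  if (length(x) < 9L) stop("measure_widths: too few points")
  bounds <- seq(min(x), max(x), length.out = 4L)
  nb <- as.integer(n_bins_per_section)
  edges <- seq(min(x), max(x), length.out = 3L * nb + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > 3L * nb] <- 3L * nb
  wid <- rep(NA_real_, 3L * nb)
  agg_max <- tapply(y, bin, max)
  agg_min <- tapply(y, bin, min)
  wid[as.integer(names(agg_max))] <- agg_max - agg_min
  section_widths <- vapply(1:3, function(s) {
    w <- wid[((s - 1L) * nb + 1L):(s * nb)]
    w <- w[!is.na(w)]
    if (!length(w))
      stop("measure_widths: section ", s, " contains no points")
    max(w)
  }, numeric(1))
  mids <- (bounds[-4] + bounds[-1]) / 2
  ord <- 1:3
  if (!is.null(head_point)) ord <- order(abs(mids - head_point[1]))
  # ord[1] = section nearest the head (shoulder), ord[3] = farthest (hip);
  # the abdomen is always the middle section.
  structure(list(shoulder = section_widths[ord[1]],
                 abdomen = section_widths[2],
                 hip = section_widths[ord[3]],
                 section_bounds = bounds,
                 section_widths = section_widths),
            class = "body_measurements")
}

#' @export
print.body_measurements <- function(x, ...) {
  cat(sprintf("body_measurements: shoulder %.3f m, abdomen %.3f m, hip %.3f m\n",
              x$shoulder, x$abdomen, x$hip))
  invisible(x)
}

#' Mean relative error, in percent
#'
#' `100 * mean(|true - est| / |true|)` — the accuracy metric used to compare
#' tape-measured and point-cloud-extracted body widths.
#'
#' @param true_vals reference values (all nonzero).
#' @param est_vals estimates, same length.
#' @return percentage (scalar).
#' @export
mean_relative_error <- function(true_vals, est_vals) {
  if (length(true_vals) != length(est_vals) || length(true_vals) < 1L)
    stop("mean_relative_error: inputs must have equal length >= 1")
  if (any(true_vals == 0)) stop("mean_relative_error: zero reference value")
  100 * mean(abs(true_vals - est_vals) / abs(true_vals))
}

#' Weight-regression error metrics
#'
#' @param true_w true weights, kg (> 0).
#' @param pred_w predicted weights, kg.
#' @return list with `mae` (kg), `mape` (percent), `rmse` (kg).
#' @export
regression_metrics <- function(true_w, pred_w) {
  if (length(true_w) != length(pred_w) || length(true_w) < 1L)
    stop("regression_metrics: inputs must have equal length >= 1")
  d <- true_w - pred_w
  list(mae = mean(abs(d)),
       mape = 100 * mean(abs(d) / true_w),
       rmse = sqrt(mean(d^2)))
}
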