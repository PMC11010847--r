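#' Point cloud container
#'
#' The universal currency of the pipeline: an N x 3 matrix of coordinates in
#' meters (columns x, y, z), optionally carrying an N x 3 matrix of 8-bit RGB
#' colours, plus a free-text provenance label.
#'
#' Conventions used throughout the package: the z axis is vertical (height
#' above the pen floor), the camera looks straight down from above, and the
#' x/y plane is horizontal. Point order is meaningful only for file
#' round-trips; every downstream operation is order-insensitive.
#'
#' @param points numeric N x 3 matrix (x, y, z), meters; all values finite.
#' @param colors optional integer N x 3 matrix (red, green, blue) in 0-255.
#' @param source_id free-text provenance label.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, source_id = "") {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (!identical(dim(colors), c(nrow(points), 3L)))
      stop("`colors` must be an N x 3 matrix matching `points`")
    if (nrow(colors) > 0L && (any(!is.finite(colors)) ||
        any(colors < 0) || any(colors > 255)))
      stop("colour values must lie in [0, 255]")
    storage.mode(colors) <- "integer"
    colnames(colors) <- c("red", "green", "blue")
  }
  structure(list(points = points, colors = colors,
                 source_id = as.character(source_id)[1]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Does a cloud carry per-point colours?
#' @param cloud a `point_cloud`.
#' @return logical.
#' @export
has_colors <- function(cloud) !is.null(cloud$colors)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, %s", n_points(x),
              if (has_colors(x)) "with RGB" else "no colour"))
  if (nzchar(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat("\n")
  if (n_points(x) > 0L) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent (m): x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Subset a point cloud by index
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index over points.
#' @return a `point_cloud` with the selected points (colours carried through).
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              colors = if (has_colors(cloud)) cloud$colors[idx, , drop = FALSE],
              source_id = cloud$source_id)
}

#' Apply a rigid transform to a cloud
#'
#' @param cloud a `point_cloud`.
#' @param rotation 3 x 3 rotation matrix (applied as `p %*% t(R)`).
#' @param translation length-3 offset added after rotation.
#' @param center optional pivot: points are rotated about this location.
#' @return the transformed `point_cloud`.
#' @export
transform_cloud <- function(cloud, rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  p <- sweep(cloud$points, 2, center)
  p <- p %*% t(rotation)
  p <- sweep(p, 2, center + translation, "+")
  point_cloud(p, colors = cloud$colors, source_id = cloud$source_id)
}

#' Rotation matrix about the vertical axis
#'
#' @param deg angle in degrees (counter-clockwise seen from above).
#' @return 3 x 3 rotation matrix about z.
#' @export
rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` under a deterministic RNG stream and restores the caller's
#' random-number state afterwards, so seeded internals never disturb user
#' code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
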