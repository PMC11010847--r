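# Shared helpers for the pigback test suite.

# A reproducible random cloud in a box.
random_cloud <- function(n, seed, with_colors = FALSE, scale = 1) {
  pigback::with_seed(seed, {
    pts <- matrix(stats::runif(3 * n, -scale, scale), n, 3)
    cols <- if (with_colors)
      matrix(sample.int(256, 3 * n, replace = TRUE) - 1L, n, 3)
    point_cloud(pts, colors = cols)
  })
}

# Brute-force voxel down-sampling oracle: direct per-voxel mean.
voxel_oracle <- function(cloud, edgelength) {
  p <- cloud$points
  origin <- apply(p, 2, min)
  ijk <- floor(sweep(p, 2, origin) / edgelength)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  out <- t(vapply(unique(key), function(k) {
    colMeans(p[key == k, , drop = FALSE])
  }, numeric(3)))
  rownames(out) <- NULL
  out
}

# Exhaustive K-means optimum: minimum SSE over every assignment of n points
# to K labels (points then clustered to the label means). Only for tiny n.
exhaustive_kmeans_sse <- function(p, K) {
  n <- nrow(p)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == K) {
      sse <- 0
      for (g in unique(labels)) {
        q <- p[labels == g, , drop = FALSE]
        sse <- sse + sum(sweep(q, 2, colMeans(q))^2)
      }
      if (sse < best) best <- sse
    }
    # next assignment in base K
    i <- 1L
    while (i <= n && labels[i] == K) { labels[i] <- 1L; i <- i + 1L }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}

# Fraction of the points of `sample` carrying an animal label.
animal_mask <- function(sample) sample$labels %in% c("head", "pig", "tail")

# Segment a scene with K-means and return recall / contamination of the
# extracted cluster against the generator labels.
scene_recall_contamination <- function(sample, K = 3, seed = 5,
                                       n_restarts = 10) {
  seg <- kmeans_cluster(sample$cloud, K, seed = seed, n_restarts = n_restarts)
  pig <- extract_pig_cluster(sample$cloud, seg)
  in_pig <- seg$labels == attr(pig, "cluster")
  is_animal <- animal_mask(sample)
  c(recall = sum(in_pig & is_animal) / sum(is_animal),
    contamination = sum(in_pig & !is_animal) / sum(in_pig))
}

# Full measurement chain on one scene: filter -> segment(K=3) -> extract ->
# trim -> pose -> measure. Returns the three widths plus pose diagnostics.
measure_scene <- function(sample, edgelength = 0.03, seed = 5) {
  ds <- voxel_downsample(sample$cloud, edgelength)
  seg <- kmeans_cluster(ds, 3, seed = seed, n_restarts = 10)
  pig <- extract_pig_cluster(ds, seg)
  tr <- remove_head_tail(pig, trim_params())
  pose <- correct_pose(tr$trimmed)
  head_pt <- if (!is.null(tr$head_point)) apply_pose(pose, tr$head_point)
  m <- measure_widths(pose$corrected, head_point = head_pt)
  resid <- correct_pose(pose$corrected)
  list(widths = c(shoulder = m$shoulder, abdomen = m$abdomen, hip = m$hip),
       residual_deg = abs(resid$applied_deg), pose = pose, trim = tr)
}
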