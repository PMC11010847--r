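test_that("voxel_downsample matches the brute-force oracle", {
  for (s in 1:6) {
    pc <- random_cloud(500, seed = 10 + s, scale = 0.5)
    edge <- c(0.03, 0.05, 0.11)[s %% 3 + 1]
    out <- voxel_downsample(pc, edge)
    oracle <- voxel_oracle(pc, edge)
    # same voxel means regardless of ordering
    ord_a <- order(out$points[, 1], out$points[, 2], out$points[, 3])
    ord_b <- order(oracle[, 1], oracle[, 2], oracle[, 3])
    expect_equal(unname(out$points[ord_a, ]), unname(oracle[ord_b, ]),
                 tolerance = 1e-12)
    expect_equal(sum(attr(out, "voxel_counts")), n_points(pc))
  }
})

test_that("voxel_downsample averages colours and shrinks the cloud", {
  pc <- random_cloud(800, seed = 21, with_colors = TRUE, scale = 0.3)
  out <- voxel_downsample(pc, 0.1)
  expect_lt(n_points(out), n_points(pc))
  expect_true(has_colors(out))
  expect_true(all(out$colors >= 0 & out$colors <= 255))
  # a cloud already sparser than the grid is untouched (means of singletons)
  sparse <- point_cloud(matrix(c(0, 0, 0, 1, 1, 1, 2, 0, 1), 3, 3,
                               byrow = TRUE))
  expect_equal(n_points(voxel_downsample(sparse, 0.5)), 3)
  expect_error(voxel_downsample(pc, -1), "edgelength")
})

test_that("kmeans_cluster attains the exhaustive optimum on tiny instances", {
  for (s in 1:6) {
    n <- 6L + (s %% 7L)
    K <- 2L + (s %% 2L)
    pc <- random_cloud(n, seed = 30 + s)
    seg <- kmeans_cluster(pc, K, seed = 1, n_restarts = 30)
    opt <- exhaustive_kmeans_sse(pc$points, K)
    expect_equal(seg$sse, opt, tolerance = 1e-8)
  }
})

test_that("kmeans_cluster is deterministic and labels are consistent", {
  pc <- random_cloud(300, seed = 40)
  a <- kmeans_cluster(pc, 4, seed = 7)
  b <- kmeans_cluster(pc, 4, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_equal(a$sse, b$sse)
  # every point is assigned to its nearest centroid and SSE adds up
  d2 <- outer(rowSums(pc$points^2), rowSums(a$centroids^2), "+") -
    2 * pc$points %*% t(a$centroids)
  expect_true(all(abs(d2[cbind(seq_len(300), a$labels)] -
                        apply(d2, 1, min)) < 1e-9))
  expect_equal(a$sse, sum(d2[cbind(seq_len(300), a$labels)]),
               tolerance = 1e-9)
  expect_error(kmeans_cluster(pc, 0), "K")
  expect_error(kmeans_cluster(pc, 301), "K")
})

test_that("kmeans_cluster matches stats::kmeans on well-separated blobs", {
  pts <- with_seed(8, rbind(matrix(rnorm(150, 0, 0.05), 50, 3),
                            matrix(rnorm(150, 2, 0.05), 50, 3),
                            matrix(rnorm(150, -2, 0.05), 50, 3)))
  pc <- point_cloud(pts)
  seg <- kmeans_cluster(pc, 3, seed = 2)
  ref <- with_seed(3, stats::kmeans(pts, 3, nstart = 10))
  expect_equal(seg$sse, ref$tot.withinss, tolerance = 1e-6)
})

test_that("elbow_select_k is invariant to rigid translation", {
  pc <- random_cloud(200, seed = 50)
  shifted <- transform_cloud(pc, translation = c(5, -3, 11))
  a <- elbow_select_k(pc, 1:6, seed = 4, n_restarts = 5)
  b <- elbow_select_k(shifted, 1:6, seed = 4, n_restarts = 5)
  expect_identical(a$K, b$K)
  expect_equal(unname(a$sse_curve), unname(b$sse_curve), tolerance = 1e-6)
  expect_error(elbow_select_k(pc, 1:2), "3")
})

test_that("extract_pig_cluster picks the cluster nearest the camera", {
  # two slabs: one high (animal), one low (floor)
  pts <- with_seed(55, rbind(
    cbind(runif(80), runif(80), 1 + runif(80, 0, 0.02)),
    cbind(runif(120), runif(120), runif(120, 0, 0.02))))
  pc <- point_cloud(pts)
  seg <- kmeans_cluster(pc, 2, seed = 1)
  pig <- extract_pig_cluster(pc, seg)
  expect_true(all(pig$points[, 3] > 0.5))
  # with the camera below (sign "-"), the floor is picked instead
  low <- extract_pig_cluster(pc, seg, camera_sign = "-")
  expect_true(all(low$points[, 3] < 0.5))
  expect_error(extract_pig_cluster(subset_cloud(pc, 1:10), seg), "match")
})
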