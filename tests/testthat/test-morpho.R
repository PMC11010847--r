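test_that("fit_obb recovers an axis-aligned box and its rotated copy", {
  pts <- with_seed(70, cbind(runif(500, -1, 1), runif(500, -0.3, 0.3),
                             runif(500, -0.1, 0.1)))
  box <- fit_obb(point_cloud(pts))
  expect_equal(abs(box$axes[1, ]), c(1, 0, 0), tolerance = 0.05)
  expect_true(all(diff(box$extents) <= 1e-12))   # non-increasing
  expect_equal(box$extents[1], diff(range(pts[, 1])), tolerance = 0.05)
  # rotating the cloud rotates the box but not its extents
  rot <- transform_cloud(point_cloud(pts), rotation = rotz(25))
  box2 <- fit_obb(rot)
  expect_equal(box2$extents, box$extents, tolerance = 1e-6)
  expect_error(fit_obb(point_cloud(cbind(0:5, 0, 0))), "collinear|degenerate")
})

test_that("correct_pose undoes a known yaw and is idempotent", {
  base <- make_pig(pig_spec(yaw_deg = 0, noise_sigma = 0.002, seed = 3))$cloud
  for (yaw in c(-25, 8, 17)) {
    tilted <- transform_cloud(base, rotation = rotz(yaw))
    pose <- correct_pose(tilted)
    expect_equal(abs(pose$applied_deg), abs(yaw), tolerance = 1.0)
    # after correction the residual is under the threshold: second pass no-op
    again <- correct_pose(pose$corrected)
    expect_equal(again$applied_deg, 0)
    expect_equal(again$corrected$points, pose$corrected$points)
  }
})

test_that("correct_pose leaves small tilts alone (1 degree threshold)", {
  base <- make_pig(pig_spec(yaw_deg = 0, noise_sigma = 0.001, seed = 4))$cloud
  aligned <- correct_pose(base)$corrected          # canonical orientation
  slight <- transform_cloud(aligned, rotation = rotz(0.5))
  pose <- correct_pose(slight)
  expect_equal(pose$applied_deg, 0)
  expect_identical(pose$corrected$points, slight$points)
})

test_that("apply_pose maps companion points through the same transform", {
  pc <- make_pig(pig_spec(yaw_deg = 20, seed = 5))$cloud
  pose <- correct_pose(pc)
  mapped <- apply_pose(pose, pc$points)
  expect_equal(mapped, unname(pose$corrected$points), tolerance = 1e-9,
               ignore_attr = TRUE)
  one <- apply_pose(pose, pc$points[7, ])
  expect_equal(unname(one), unname(mapped[7, ]), tolerance = 1e-12)
})

test_that("measure_widths recovers the constructed section widths", {
  spec <- pig_spec(shoulder_width = 0.42, abdomen_width = 0.50,
                   hip_width = 0.40, yaw_deg = 0, noise_sigma = 0.001,
                   seed = 6)
  sample <- make_pig(spec)
  trim <- remove_head_tail(sample$cloud)
  pose <- correct_pose(trim$trimmed)
  hp <- apply_pose(pose, trim$head_point)
  m <- measure_widths(pose$corrected, head_point = hp)
  truth <- sample$truth$widths
  expect_equal(m$shoulder, unname(truth["shoulder"]), tolerance = 0.04)
  expect_equal(m$abdomen, unname(truth["abdomen"]), tolerance = 0.04)
  expect_equal(m$hip, unname(truth["hip"]), tolerance = 0.04)
  # head at the other end swaps shoulder and hip but never the abdomen
  far <- hp; far[1] <- -far[1]
  m2 <- measure_widths(pose$corrected, head_point = far)
  expect_equal(m2$shoulder, m$hip)
  expect_equal(m2$hip, m$shoulder)
  expect_equal(m2$abdomen, m$abdomen)
})

test_that("mean_relative_error reproduces the reference accuracies", {
  ref <- reference_body_measurements()
  expect_equal(round(mean_relative_error(ref$true_shoulder,
                                         ref$extracted_shoulder), 3), 3.144)
  expect_equal(round(mean_relative_error(ref$true_hip,
                                         ref$extracted_hip), 3), 3.820)
  expect_equal(mean_relative_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_relative_error(2, 1), 50)
  expect_error(mean_relative_error(c(1, 0), c(1, 1)), "zero")
  expect_error(mean_relative_error(1:3, 1:2), "length")
})

test_that("regression_metrics computes MAE, MAPE and RMSE", {
  m <- regression_metrics(c(100, 200), c(110, 190))
  expect_equal(m$mae, 10)
  expect_equal(m$mape, 100 * mean(c(10 / 100, 10 / 200)))
  expect_equal(m$rmse, 10)
  expect_error(regression_metrics(1, numeric(0)), "length")
})
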