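test_that("pig_spec validates its ranges", {
  expect_s3_class(pig_spec(), "pig_spec")
  expect_error(pig_spec(shoulder_width = 0.1), "width")
  expect_error(pig_spec(abdomen_width = 0.9), "width")
  expect_error(pig_spec(body_length = 0.5), "body_length")
  expect_error(pig_spec(noise_sigma = -1), "noise_sigma")
})

test_that("make_pig is deterministic and labelled consistently", {
  spec <- pig_spec(seed = 11)
  a <- make_pig(spec)
  b <- make_pig(spec)
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$cloud$colors, b$cloud$colors)
  expect_identical(a$labels, b$labels)
  expect_length(a$labels, n_points(a$cloud))
  expect_setequal(unique(a$labels), c("head", "pig", "tail"))
  expect_true(has_colors(a$cloud))
})

test_that("make_pig geometry matches the spec", {
  spec <- pig_spec(body_length = 2.0, shoulder_width = 0.42,
                   abdomen_width = 0.5, hip_width = 0.38,
                   back_height = 0.85, yaw_deg = 0, noise_sigma = 0,
                   seed = 12)
  s <- make_pig(spec)
  p <- s$cloud$points
  # overall length close to body_length, back ridge at back_height
  expect_equal(diff(range(p[, 1])), 2.0, tolerance = 0.05)
  expect_equal(max(p[, 3]), 0.85, tolerance = 0.02)
  # widest sampled chord of the noise-free torso approaches the abdomen
  # control width from below (finite sampling never quite reaches +-w/2)
  torso <- p[s$labels == "pig", ]
  chord <- max(torso[, 2]) - min(torso[, 2])
  expect_lte(chord, 0.5 + 1e-9)
  expect_gt(chord, 0.45)
  # head apex sits at negative x (snout), tail apex at positive x
  expect_lt(s$truth$head_apex[1], s$truth$tail_apex[1])
  # yaw rotates the principal axis by the requested angle
  yawed <- make_pig(pig_spec(yaw_deg = 25, seed = 12))
  box <- fit_obb(yawed$cloud)
  ang <- atan2(box$axes[1, 2], box$axes[1, 1]) * 180 / pi
  expect_equal(abs(ang), 25, tolerance = 1.5)
})

test_that("allometric_weight scales as the volume proxy", {
  small <- pig_spec(body_length = 1.2, shoulder_width = 0.25,
                    abdomen_width = 0.25, hip_width = 0.25,
                    back_height = 0.40)
  big <- pig_spec(body_length = 2.1, shoulder_width = 0.45,
                  abdomen_width = 0.45, hip_width = 0.45,
                  back_height = 0.70)
  r <- (2.1 * 0.45 * 0.70) / (1.2 * 0.25 * 0.40)
  expect_equal(allometric_weight(big) / allometric_weight(small), r,
               tolerance = 1e-9)
  # noiseless call is deterministic; noisy call is seed-reproducible
  expect_identical(allometric_weight(big), allometric_weight(big))
  expect_identical(allometric_weight(big, noise_sd = 5, seed = 1),
                   allometric_weight(big, noise_sd = 5, seed = 1))
})

test_that("make_scene adds labelled background around the animal", {
  spec <- sample_pig_spec(201)
  sc <- make_scene(spec)
  expect_equal(length(sc$labels), n_points(sc$cloud))
  expect_true(all(c("floor", "fence") %in% sc$labels))
  animal <- sc$labels %in% c("head", "pig", "tail")
  # the platform raises the whole animal above floor and rail
  expect_gt(min(sc$cloud$points[animal, 3]),
            max(sc$cloud$points[sc$labels == "floor", 3]))
  # the truth record survives the scene assembly
  expect_named(sc$truth$widths, c("shoulder", "abdomen", "hip"))
  expect_error(make_scene(spec, n_fences = 5), "n_fences")
})

test_that("the crate layout has four equal-count components", {
  sc <- make_scene(sample_pig_spec(202), n_fences = 2)
  animal <- sc$labels %in% c("head", "pig", "tail")
  n_animal <- sum(animal)
  # background: one floor patch plus two fence slabs (gate and sill), each
  # holding as many points as the animal
  expect_equal(sum(sc$labels == "floor"), n_animal)
  expect_equal(sum(sc$labels == "fence"), 2 * n_animal)
})

test_that("cohort colour modes behave as documented", {
  size_cohort <- make_cohort(12, seed = 9, color_mode = "size",
                             points_per_m2 = 400)
  w <- vapply(size_cohort, function(s) allometric_weight(s$truth$spec),
              numeric(1))
  bright <- vapply(size_cohort, function(s) mean(s$cloud$colors), numeric(1))
  expect_gt(stats::cor(w, bright), 0.9)      # colour encodes size
  expect_gt(stats::sd(w), 0)                 # animals actually differ
  # determinism of the whole cohort
  again <- make_cohort(12, seed = 9, color_mode = "size",
                       points_per_m2 = 400)
  expect_identical(size_cohort[[3]]$cloud$points, again[[3]]$cloud$points)
})
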