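# Synthetic pig-back scenes with per-point ground truth.
#
# Geometry convention: before yaw the animal lies along x, centered at the
# origin, snout toward negative x; z is height above the floor (z = 0). The
# animal spans `body_length` nose to tail; the first HEAD_SPAN meters are the
# head/neck region and the last TAIL_SPAN meters the tail/rump region — the
# parts the trimming stage is meant to discard — and the torso between them
# is what the width measurement sees.

HEAD_SPAN <- 0.4
TAIL_SPAN <- 0.4

#' Specification of one synthetic sow
#'
#' Dimensions emulate adult crossbred sows recorded from above in a driving
#' channel: total length 1.75-2.1 m, back widths 0.30-0.50 m, back height
#' 0.70-0.95 m, body mass roughly 150-350 kg.
#'
#' @param body_length nose-to-tail length, meters (1.0-2.2).
#' @param shoulder_width,abdomen_width,hip_width section widths, meters
#'   (0.2-0.7).
#' @param back_height spine height above the floor, meters.
#' @param head_bulge,tail_bulge lateral radii of the head/tail protrusions,
#'   meters.
#' @param noise_sigma per-coordinate Gaussian measurement noise, meters.
#' @param points_per_m2 sampling density of the animal surface.
#' @param yaw_deg horizontal orientation of the body axis.
#' @param base_color length-3 RGB (0-255) of the hide.
#' @param color_gradient per-meter RGB drift along the body (length 3).
#' @param seed RNG seed for sampling and noise.
#' @return list of class `pig_spec`.
#' @export
pig_spec <- function(body_length = 1.9, shoulder_width = 0.40,
                     abdomen_width = 0.44, hip_width = 0.41,
                     back_height = 0.80, head_bulge = 0.13,
                     tail_bulge = 0.10, noise_sigma = 0.005,
                     points_per_m2 = 4000, yaw_deg = 0,
                     base_color = c(190, 155, 145),
                     color_gradient = c(-10, -8, -6), seed = 1L) {
  widths <- c(shoulder_width, abdomen_width, hip_width)
  if (any(widths <= 0.2) || any(widths >= 0.7))
    stop("pig_spec: widths must lie in (0.2, 0.7) m")
  if (body_length <= 1.0 || body_length >= 2.2)
    stop("pig_spec: body_length must lie in (1.0, 2.2) m")
  if (noise_sigma < 0) stop("pig_spec: noise_sigma must be >= 0")
  if (back_height <= 0 || points_per_m2 <= 0)
    stop("pig_spec: back_height and points_per_m2 must be > 0")
  structure(list(body_length = body_length, shoulder_width = shoulder_width,
                 abdomen_width = abdomen_width, hip_width = hip_width,
                 back_height = back_height, head_bulge = head_bulge,
                 tail_bulge = tail_bulge, noise_sigma = noise_sigma,
                 points_per_m2 = points_per_m2, yaw_deg = yaw_deg,
                 base_color = base_color, color_gradient = color_gradient,
                 seed = as.integer(seed)),
            class = "pig_spec")
}

# Half-width profile of the torso as a function of the relative torso
# coordinate t in [0, 1]. Piecewise linear with the section control widths
# attained at the three section midpoints and slight waists at the section
# boundaries, so the maximum chord of each third equals its control width.
torso_width_profile <- function(spec, t) {
  s <- spec$shoulder_width; a <- spec$abdomen_width; h <- spec$hip_width
  nodes_t <- c(0, 1 / 6, 1 / 3, 1 / 2, 2 / 3, 5 / 6, 1)
  nodes_w <- c(0.94 * s, s, 0.97 * min(s, a), a, 0.97 * min(a, h), h, 0.94 * h)
  stats::approx(nodes_t, nodes_w, xout = t, rule = 2)$y
}

# Sample `n` points uniformly on the upper shell of an ellipsoid cap with
# horizontal semi-axes (au, ay), vertical semi-axis az, base height z0,
# centered at (uc, 0).
sample_blob <- function(n, uc, au, ay, az, z0) {
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    m <- 2 * (n - nrow(pts)) + 16
    du <- stats::runif(m, -au, au)
    dy <- stats::runif(m, -ay, ay)
    r2 <- (du / au)^2 + (dy / ay)^2
    ok <- r2 <= 1
    z <- z0 + az * sqrt(pmax(0, 1 - r2[ok]))
    pts <- rbind(pts, cbind(uc + du[ok], dy[ok], z))
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic pig-back cloud with ground truth
#'
#' The torso is the upper shell of a tapered elliptical cylinder whose
#' half-width follows [pig_spec()]'s shoulder/abdomen/hip controls; bulbous
#' ellipsoid caps form the head and tail. Gaussian coordinate noise, a yaw
#' rotation and an RGB gradient are applied; every point carries a label in
#' `{head, tail, pig}` and the sample records the true section widths, the
#' cap apices and the allometric weight.
#'
#' @param spec a [pig_spec()].
#' @return object of class `scene_sample`: list with `cloud`
#'   ([point_cloud()]), `labels` (character, per point), `truth` (list:
#'   `widths`, `weight`, `yaw_deg`, `head_apex`, `tail_apex`, `spec`).
#' @export
make_pig <- function(spec) {
  stopifnot(inherits(spec, "pig_spec"))
  L <- spec$body_length
  torso_len <- L - HEAD_SPAN - TAIL_SPAN
  with_seed(spec$seed, {
    # torso surface
    n_torso <- max(50L, round(spec$points_per_m2 * torso_len *
                                max(spec$abdomen_width, spec$shoulder_width,
                                    spec$hip_width)))
    u <- stats::runif(n_torso, HEAD_SPAN, L - TAIL_SPAN)
    t <- (u - HEAD_SPAN) / torso_len
    w <- torso_width_profile(spec, t)
    keep <- stats::runif(n_torso) <= w / max(w)    # uniform over footprint
    u <- u[keep]; w <- w[keep]
    y <- stats::runif(length(u), -1, 1) * w / 2
    sag <- 0.35 * w
    z <- spec$back_height - sag + sag * sqrt(pmax(0, 1 - (2 * y / w)^2))
    torso <- cbind(u, y, z)

    # head / tail caps
    az_h <- 0.9 * spec$head_bulge
    az_t <- 0.9 * spec$tail_bulge
    z0_h <- spec$back_height - 0.06 - az_h
    z0_t <- spec$back_height - 0.05 - az_t
    n_head <- max(30L, round(spec$points_per_m2 * pi * (HEAD_SPAN / 2) *
                               spec$head_bulge))
    n_tail <- max(30L, round(spec$points_per_m2 * pi * (TAIL_SPAN / 2) *
                               spec$tail_bulge))
    head <- sample_blob(n_head, uc = HEAD_SPAN / 2, au = HEAD_SPAN / 2,
                        ay = spec$head_bulge, az = az_h, z0 = z0_h)
    tail <- sample_blob(n_tail, uc = L - TAIL_SPAN / 2, au = TAIL_SPAN / 2,
                        ay = spec$tail_bulge, az = az_t, z0 = z0_t)

    pts <- rbind(head, torso, tail)
    labels <- c(rep("head", nrow(head)), rep("pig", nrow(torso)),
                rep("tail", nrow(tail)))
    # colours: base + per-meter gradient along the body + texture noise
    n <- nrow(pts)
    cols <- matrix(rep(spec$base_color, each = n), n, 3) +
      outer(pts[, 1], spec$color_gradient) +
      matrix(stats::rnorm(3 * n, 0, 5), n, 3)
    cols <- pmin(pmax(round(cols), 0), 255)

    # center along x, add noise, apply yaw
    pts[, 1] <- pts[, 1] - L / 2
    if (spec$noise_sigma > 0)
      pts <- pts + matrix(stats::rnorm(3 * n, 0, spec$noise_sigma), n, 3)
    R <- rotz(spec$yaw_deg)
    pts <- pts %*% t(R)

    head_apex <- as.vector(R %*% c(-L / 2, 0, z0_h))
    tail_apex <- as.vector(R %*% c(L / 2, 0, z0_t))
    cloud <- point_cloud(pts, colors = cols, source_id = "synthetic pig")
    truth <- list(widths = c(shoulder = spec$shoulder_width,
                             abdomen = spec$abdomen_width,
                             hip = spec$hip_width),
                  weight = allometric_weight(spec),
                  yaw_deg = spec$yaw_deg,
                  head_apex = head_apex, tail_apex = tail_apex, spec = spec)
    structure(list(cloud = cloud, labels = labels, truth = truth),
              class = "scene_sample")
  })
}

#' Assemble a weighing-station scene around a synthetic pig
#'
#' The animal stands on a raised weighing platform (`platform_height` above
#' the floor, as in a scale crate); the surroundings an overhead depth
#' camera would return are added with per-point labels extended to
#' `{floor, fence}`:
#'
#' * `n_fences = 0`: platform pig plus the visible floor strip beside the
#'   crate (the crate footprint itself is shadowed).
#' * `n_fences = 1` (default, the *chute* layout): additionally one low
#'   side rail along the channel. The rail height (0.5 m) stays well below
#'   the platform-raised back, and the floor strip next to the rail is cut
#'   away (stereo shadow at the rail base), so the three components —
#'   floor low, rail mid, animal high — are mutually compact for a
#'   Euclidean segmenter.
#' * `n_fences = 2` (the *crate* layout): a raised entry gate slab ahead of
#'   the snout and a low trough sill opposite the visible floor patch. The
#'   four component centroids form a near-regular tetrahedron with 1.8 m
#'   sides and equal point counts, so the scene's SSE-vs-K curve bends
#'   exactly at the constructed component count — the calibration scene for
#'   K selection.
#'
#' @param spec a [pig_spec()].
#' @param floor_z floor height, meters (must be below the back).
#' @param n_fences 0, 1 or 2 fence slabs (chute rail, or gate + sill).
#' @param platform_height height of the weighing platform, meters.
#' @param bg_points_per_m2 sampling density of floor and rail in the chute
#'   layout (the crate layout matches background counts to the animal's).
#' @param seed RNG seed for the background (the pig uses `spec$seed`).
#' @return a `scene_sample` (see [make_pig()]).
#' @export
make_scene <- function(spec, floor_z = 0, n_fences = 1L,
                       platform_height = 0.6, bg_points_per_m2 = 1200,
                       seed = spec$seed + 1L) {
  n_fences <- as.integer(n_fences)
  if (!n_fences %in% 0:2) stop("make_scene: n_fences must be 0, 1 or 2")
  if (platform_height < 0) stop("make_scene: platform_height must be >= 0")
  pig <- make_pig(spec)
  ppts <- pig$cloud$points
  z_shift <- floor_z + platform_height
  ppts[, 3] <- ppts[, 3] + z_shift
  half_w <- max(spec$shoulder_width, spec$abdomen_width, spec$hip_width) / 2
  half_len <- spec$body_length / 2 + 0.15
  clip <- function(cols) pmin(pmax(round(cols), 0), 255)
  shade <- function(base, n, sd = 6)
    clip(matrix(rep(base, each = n), n, 3) +
           matrix(stats::rnorm(3 * n, 0, sd), n, 3))
  with_seed(seed, {
    if (n_fences == 2L) {
      # crate layout: gate, floor patch and sill equidistant (1.8 m) from
      # the animal centroid and from each other, equal point counts
      d <- 1.8
      n_p <- nrow(ppts)
      # the platform lift is adjusted so the animal centroid sits exactly
      # d/sqrt(2) above the floor: the four centroids then form a regular
      # tetrahedron with side d whatever the sampled body height
      extra <- floor_z + d / sqrt(2) - mean(ppts[, 3])
      ppts[, 3] <- ppts[, 3] + extra
      z_shift <- z_shift + extra
      ctr <- colMeans(ppts)
      y_off <- d / 2
      # raised entry gate ahead of the snout (vertical slab, normal x)
      gate <- cbind(ctr[1] - d + stats::rnorm(n_p, 0, 0.005),
                    ctr[2] + stats::runif(n_p, -0.45, 0.45),
                    ctr[3] + stats::runif(n_p, -0.375, 0.375))
      # visible floor patch to one side
      fl <- cbind(ctr[1] - d / 2 + stats::runif(n_p, -0.6, 0.6),
                  ctr[2] - y_off + stats::runif(n_p, -0.5, 0.5),
                  floor_z + stats::rnorm(n_p, 0, 0.005))
      # low trough sill opposite (vertical slab, normal y)
      sill <- cbind(ctr[1] - d / 2 + stats::runif(n_p, -0.6, 0.6),
                    ctr[2] + y_off + stats::rnorm(n_p, 0, 0.005),
                    floor_z + stats::runif(n_p, 0, 0.25))
      pts <- rbind(ppts, fl, gate, sill)
      cols <- rbind(pig$cloud$colors, shade(c(120, 120, 122), n_p),
                    shade(c(150, 110, 80), n_p), shade(c(135, 125, 90), n_p))
      labels <- c(pig$labels, rep("floor", n_p), rep("fence", 2L * n_p))
    } else {
      # chute layout: floor strip on the open side, optional side rail
      rail_gap <- 0.15
      rail_h <- 0.5
      occl <- 0.3         # stereo shadow along the rail base
      rail_y <- max(half_w, max(ppts[, 2])) + rail_gap
      y_min <- -(half_w + 0.6)
      n_f <- round(bg_points_per_m2 * 2 * half_len * (rail_y - y_min))
      fx <- stats::runif(n_f, -half_len, half_len)
      fy <- stats::runif(n_f, y_min, rail_y)
      body <- cbind(fx, fy, 0) %*% t(rotz(-spec$yaw_deg))
      shadow <- abs(body[, 1]) <= spec$body_length / 2 + 0.06 &
        abs(body[, 2]) <= half_w + 0.06
      keep <- !shadow
      if (n_fences == 1L) keep <- keep & fy <= rail_y - occl
      nf <- sum(keep)
      fl <- cbind(fx[keep], fy[keep],
                  floor_z + stats::rnorm(nf, 0, spec$noise_sigma))
      pts <- rbind(ppts, fl)
      cols <- rbind(pig$cloud$colors, shade(c(120, 120, 122), nf))
      labels <- c(pig$labels, rep("floor", nf))
      if (n_fences == 1L) {
        n_w <- round(bg_points_per_m2 * 2 * half_len * rail_h)
        rail <- cbind(stats::runif(n_w, -half_len, half_len),
                      rail_y + stats::rnorm(n_w, 0, spec$noise_sigma),
                      floor_z + stats::runif(n_w, 0, rail_h))
        pts <- rbind(pts, rail)
        cols <- rbind(cols, shade(c(150, 110, 80), n_w))
        labels <- c(labels, rep("fence", n_w))
      }
    }
    cloud <- point_cloud(pts, colors = cols, source_id = "synthetic scene")
    truth <- pig$truth
    truth$head_apex[3] <- truth$head_apex[3] + z_shift
    truth$tail_apex[3] <- truth$tail_apex[3] + z_shift
    structure(list(cloud = cloud, labels = labels, truth = truth),
              class = "scene_sample")
  })
}

#' Allometric ground-truth weight of a synthetic sow
#'
#' A generic power law on a volume proxy,
#' `weight = a * (body_length * mean_width * back_height)^b + noise`, with
#' defaults placing the sampled cohort in the 150-350 kg adult-sow range.
#' It exists to make weight a recoverable function of shape in tests; it
#' makes no claim to real sow allometry.
#'
#' @param spec a [pig_spec()].
#' @param a coefficient (> 0).
#' @param b exponent (> 0).
#' @param noise_sd Gaussian noise on the weight, kg.
#' @param seed RNG seed for the noise.
#' @return weight in kg.
#' @export
allometric_weight <- function(spec, a = 380, b = 1, noise_sd = 0,
                              seed = spec$seed) {
  stopifnot(a > 0, b > 0)
  vol <- spec$body_length * spec$back_height *
    mean(c(spec$shoulder_width, spec$abdomen_width, spec$hip_width))
  w <- a * vol^b
  if (noise_sd > 0) w <- w + with_seed(seed, stats::rnorm(1, 0, noise_sd))
  w
}

#' Draw one random pig spec from the cohort distributions
#'
#' Samples a [pig_spec()] from the seeded adult-sow distributions used by
#' [make_cohort()]: length 1.75-2.1 m, widths roughly 0.30-0.55 m, back
#' height 0.70-0.95 m, yaw uniform in `[-yaw_max, yaw_max]` degrees. In
#' `"size"` colour mode the hide brightness is a monotone function of the
#' animal's deterministic weight; `"independent"` draws it at random.
#'
#' @param seed integer seed; one seed, one animal.
#' @param noise_sigma coordinate noise, meters.
#' @param points_per_m2 surface sampling density.
#' @param yaw_max maximal absolute yaw, degrees.
#' @param color_mode `"size"` or `"independent"`.
#' @return a [pig_spec()].
#' @export
sample_pig_spec <- function(seed, noise_sigma = 0.005, points_per_m2 = 4000,
                            yaw_max = 30, color_mode = "size") {
  with_seed(seed, {
    s <- stats::runif(1, 0.32, 0.48)
    spec <- pig_spec(
      body_length = stats::runif(1, 1.75, 2.1),
      shoulder_width = s,
      abdomen_width = min(0.55, s * stats::runif(1, 0.95, 1.18)),
      hip_width = s * stats::runif(1, 0.88, 1.1),
      back_height = stats::runif(1, 0.70, 0.95),
      head_bulge = stats::runif(1, 0.11, 0.15),
      tail_bulge = stats::runif(1, 0.08, 0.12),
      noise_sigma = noise_sigma,
      points_per_m2 = points_per_m2,
      yaw_deg = stats::runif(1, -yaw_max, yaw_max),
      seed = sample.int(1e7, 1))
    det_w <- allometric_weight(spec)
    bright <- if (color_mode == "size") {
      70 + (min(max(det_w, 140), 400) - 140) / 260 * 150
    } else {
      stats::runif(1, 70, 220)
    }
    spec$base_color <- c(bright, 0.82 * bright, 0.75 * bright)
    spec
  })
}

#' Generate a cohort of synthetic sows
#'
#' Independent animals drawn from seeded spec distributions. In the
#' `"size"` colour mode the hide brightness is a monotone function of the
#' deterministic weight, so per-point RGB carries size information (the
#' regime in which colour features should help a regressor); `"independent"`
#' draws brightness at random as a negative control.
#'
#' @param n number of animals.
#' @param seed master seed.
#' @param color_mode `"size"` or `"independent"`.
#' @param weight_noise_sd kg of noise added to the recorded true weight.
#' @param noise_sigma,points_per_m2,yaw_max forwarded to the spec sampler.
#' @return list of `scene_sample` (pig-only clouds, as after segmentation).
#' @export
make_cohort <- function(n, seed = 1L, color_mode = c("size", "independent"),
                        weight_noise_sd = 4, noise_sigma = 0.005,
                        points_per_m2 = 4000, yaw_max = 30) {
  color_mode <- match.arg(color_mode)
  stopifnot(n >= 1)
  seeds <- with_seed(seed, sample.int(2^30, n))
  lapply(seq_len(n), function(i) {
    spec <- sample_pig_spec(seeds[i], noise_sigma = noise_sigma,
                            points_per_m2 = points_per_m2, yaw_max = yaw_max,
                            color_mode = color_mode)
    smp <- make_pig(spec)
    smp$truth$weight <- allometric_weight(spec, noise_sd = weight_noise_sd,
                                          seed = seeds[i] + 7L)
    smp
  })
}
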