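# The measurement core: ray-safety projection, inscribed disc, cylinder
# verification, diameter growth, and the azimuth optimization.

test_that("all interior rays through a solid cube are safe and contiguous", {
  occ <- array(1L, c(30, 30, 30))
  model <- bone_model(occ, spacing = 1)
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    map <- ray_safety_map(model, dir, min_len = 20)
    # rays through the cube interior (away from the projected boundary)
    core <- abs(map$us) < 12
    corev <- abs(map$vs) < 12
    expect_true(all(map$safe[core, corev]))
    lens <- (map$exit - map$entry)[core, corev]
    expect_true(all(abs(lens - 29) <= 1.5))
  }
})

test_that("rays crossing an internal air gap are unsafe", {
  occ <- array(1L, c(20, 20, 40))
  occ[, , 19:22] <- 0L  # transverse gap: two disjoint slabs
  model <- bone_model(occ, spacing = 1)
  map <- ray_safety_map(model, c(0, 0, 1), min_len = 10, gap_tol = 0)
  expect_false(any(map$safe))
  # along x the slabs are solid and long enough
  map_x <- ray_safety_map(model, c(1, 0, 0), min_len = 10)
  expect_true(any(map_x$safe))
})

test_that("the safe region along the true axis is the waist disc", {
  ph <- coarse_bicone(azimuth = 0)
  map <- ray_safety_map(ph$model, ph$truth$true_axis, min_len = 40)
  disc <- max_inscribed_disc(map)
  expect_identical(disc$flag, "ok")
  # eroded by at most ~1 voxel, never larger than the waist + 1 pixel
  expect_lt(disc$radius, 2 + map$pixel_pitch)
  expect_gt(disc$radius, 2 - 2 * min(ph$model$spacing))
  # disc centre projects near the channel axis
  rel <- disc$center - ph$truth$true_center
  off <- rel - dot3(rel, ph$truth$true_axis) * ph$truth$true_axis
  expect_lt(vnorm(off), 2 * min(ph$model$spacing))
})

test_that("inscribed disc of a rasterized disc recovers centre and radius", {
  n <- 41; r <- 10
  safe <- outer(seq_len(n) - 21, seq_len(n) - 21,
                function(i, j) i^2 + j^2 <= r^2)
  disc <- max_inscribed_disc(fake_safety_map(safe, pitch = 0.5))
  expect_equal(disc$center_px, c(21L, 21L))
  expect_equal(disc$radius, r * 0.5, tolerance = 0.5 * 0.5)  # half a pixel
})

test_that("a single safe pixel admits a half-pitch disc", {
  safe <- matrix(FALSE, 9, 9); safe[5, 5] <- TRUE
  disc <- max_inscribed_disc(fake_safety_map(safe, pitch = 2))
  expect_equal(disc$center_px, c(5L, 5L))
  expect_equal(disc$radius, 1)  # half of the 2 mm pitch
})

test_that("no safe pixels yields a flagged zero-radius result", {
  disc <- max_inscribed_disc(fake_safety_map(matrix(FALSE, 5, 5)))
  expect_identical(disc$flag, "no_corridor")
  expect_equal(disc$radius, 0)
})

test_that("seed hint selects the containing component", {
  safe <- matrix(FALSE, 40, 20)
  safe[3:12, 6:15] <- TRUE    # large block, centred ~(7.5, 10.5)
  safe[30:33, 9:12] <- TRUE   # small block
  map <- fake_safety_map(safe, pitch = 1)
  big <- max_inscribed_disc(map)
  expect_true(big$center_px[1] <= 12)
  # hint placed on the small component (u,v in mm relative to map centre)
  hint_uv <- c(map$us[31], map$vs[10])
  hint <- map$center + hint_uv[1] * map$u + hint_uv[2] * map$v
  small <- max_inscribed_disc(map, seed_hint = hint)
  expect_true(small$center_px[1] >= 30)
  expect_lt(small$radius, big$radius)
})

test_that("inscribed disc matches exhaustive search on random maps", {
  set.seed(99)
  for (k in 1:50) {
    n1 <- sample(8:32, 1); n2 <- sample(8:32, 1)
    safe <- matrix(stats::runif(n1 * n2) < stats::runif(1, 0.3, 0.8), n1, n2)
    if (!any(safe)) next
    oracle <- brute_force_disc(safe)
    disc <- max_inscribed_disc(fake_safety_map(safe, pitch = 1))
    # integer-radius semantics: all pixel centres within r are safe
    expect_equal(ceiling(disc$dist_px) - 1, oracle$radius)
  }
})

test_that("cylinder verification accepts contained and rejects oversized screws", {
  ph <- coarse_bicone(azimuth = 0)
  axis <- ph$truth$true_axis; ctr <- ph$truth$true_center
  span <- c(-38, 38)
  expect_true(verify_cylinder(ph$model, axis, ctr, 1, span))
  # the end diameter exceeds the waist: must breach
  expect_false(verify_cylinder(ph$model, axis, ctr, 12, span))
  expect_false(verify_cylinder(ph$model, axis, ctr, 6, span))
})

test_that("verification verdicts are stable under 8x oversampling", {
  ph <- coarse_bicone(azimuth = 0)
  axis <- ph$truth$true_axis; ctr <- ph$truth$true_center
  set.seed(5)
  vox <- min(ph$model$spacing)
  n <- 40; clear_cases <- 0
  for (k in seq_len(n)) {
    d <- stats::runif(1, 0.5, 9)
    off <- stats::runif(1, -1.5, 1.5)
    bas <- plane_basis(axis)
    c2 <- ctr + off * bas$u
    span <- sort(stats::runif(2, -35, 35))
    if (diff(span) < 5) span <- span + c(-3, 3)
    # radial clearance between the cylinder's outer extent and the
    # narrowest channel radius it spans
    t_narrow <- if (span[1] < 0 && span[2] > 0) 0 else min(abs(span))
    margin <- abs((abs(off) + d / 2) - (2 + 0.1 * t_narrow))
    v1 <- verify_cylinder(ph$model, axis, c2, d, span)
    v8 <- verify_cylinder(ph$model, axis, c2, d, span, oversample = 8)
    if (margin > 1.1 * vox) {
      expect_identical(v1, v8)
      clear_cases <- clear_cases + 1
    }
  }
  expect_gt(clear_cases, 10)  # the draw covers plenty of clear-cut cases
})

test_that("diameter growth recovers a known channel and matches the disc route", {
  ph <- coarse_cylinder(diameter = 6)
  d <- grow_cylinder(ph$model, ph$truth$true_axis, ph$truth$true_center,
                     step = 0.1)
  # surface localization is good to half a voxel, so the diameter is good
  # to one voxel plus the growth step
  expect_lte(abs(d - 6), 0.1 + min(ph$model$spacing) + 1e-6)
  # growth route vs distance-transform route on random bicones
  set.seed(21)
  for (k in 1:8) {
    waist <- stats::runif(1, 3.2, 6)
    ph2 <- make_channel_phantom(phantom_spec(
      shape = "bicone", channel_waist_diameter = waist,
      channel_end_diameter = waist + stats::runif(1, 0, 6),
      channel_elevation = stats::runif(1, 5, 30),
      channel_azimuth = stats::runif(1, -10, 10), voxel_spacing = 1))
    dg <- grow_cylinder(ph2$model, ph2$truth$true_axis,
                        ph2$truth$true_center, step = 0.5)
    map <- ray_safety_map(ph2$model, ph2$truth$true_axis, min_len = 40)
    disc <- max_inscribed_disc(map)
    expect_lt(abs(dg - 2 * disc$radius), 0.5 + 2 * min(ph2$model$spacing))
  }
})

test_that("an unsafe central ray is rejected by the growth procedure", {
  ph <- coarse_bicone(azimuth = 0)
  bas <- plane_basis(ph$truth$true_axis)
  off_center <- ph$truth$true_center + 8 * bas$u  # inside the moat
  expect_error(grow_cylinder(ph$model, ph$truth$true_axis, off_center),
               "unsafe")
})

test_that("azimuth optimization recovers an aligned cylinder channel", {
  ph <- coarse_cylinder(diameter = 6, elevation = 15, azimuth = 0)
  frame <- app_from_landmarks(ph$landmarks)
  res <- optimize_corridor(ph$model, frame, fluoro_config(alpha = 15))
  expect_identical(res$flag, "ok")
  expect_lt(abs(res$iad - 6), 2 * min(ph$model$spacing))
  expect_lt(abs(res$ial - 80), 2 * min(ph$model$spacing))
  expect_lt(abs(res$azimuth_at_max - 0), 1)
  expect_lt(abs(res$aip - ph$truth$true_aip), 1)
  # oracle consistency: result passes, 2 voxels larger fails
  mid <- (res$center_entry + res$center_exit) / 2
  half <- vnorm(res$center_exit - res$center_entry) / 2
  inset <- 0.75 * min(ph$model$spacing)
  span <- c(-half + inset, half - inset)
  expect_true(verify_cylinder(ph$model, res$axis, mid, res$iad, span))
  expect_false(verify_cylinder(ph$model, res$axis, mid,
                               res$iad + 2 * min(ph$model$spacing), span))
})

test_that("no corridor is flagged when the angle constraint excludes the channel", {
  ph <- coarse_cylinder(diameter = 6, elevation = 15, azimuth = 0)
  frame <- app_from_landmarks(ph$landmarks)
  res <- optimize_corridor(ph$model, frame,
                           fluoro_config(alpha = 45, azimuth_range = 10,
                                         azimuth_step = 2))
  expect_identical(res$flag, "no_corridor")
  expect_equal(res$iad, 0)
})

test_that("corridor measurements are invariant under rigid motion of the scene", {
  spec <- phantom_spec(voxel_spacing = 1, channel_azimuth = 8)
  ph0 <- make_channel_phantom(spec)
  set.seed(17)
  R <- rotation_matrix(rnorm(3), 24)
  ph1 <- make_channel_phantom(spec, rotation = R, translation = c(-30, 12, 44))
  cfg <- fluoro_config(alpha = 15)
  r0 <- optimize_corridor(ph0$model, app_from_landmarks(ph0$landmarks), cfg)
  r1 <- optimize_corridor(ph1$model, app_from_landmarks(ph1$landmarks), cfg)
  vox <- min(spec$voxel_spacing)
  expect_lt(abs(r0$iad - r1$iad), vox)
  expect_lt(abs(r0$ial - r1$ial), 2 * vox)
  expect_lt(abs(r0$aip - r1$aip), 1.5)
})

test_that("recovered diameter converges to the waist as the grid refines", {
  errs <- vapply(c(1, 0.5, 0.25), function(sp) {
    ph <- make_channel_phantom(phantom_spec(voxel_spacing = sp,
                                            channel_azimuth = 8))
    map <- ray_safety_map(ph$model, ph$truth$true_axis, min_len = 40)
    disc <- max_inscribed_disc(map)
    px <- disc$center_px
    entry <- map$entry[px[1], px[2]]; exit <- map$exit[px[1], px[2]]
    mid <- disc$center + (entry + exit) / 2 * ph$truth$true_axis
    inset <- 0.75 * sp
    span <- c(entry + inset, exit - inset) - (entry + exit) / 2
    iad <- 2 * disc$radius
    while (iad > 0 && !verify_cylinder(ph$model, ph$truth$true_axis, mid,
                                       iad, span))
      iad <- iad - map$pixel_pitch / 2
    abs(iad - 4)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})
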