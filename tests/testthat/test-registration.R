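test_that("en-face stacking recovers known photo-frame rotations", {
  lm0 <- data.frame(label = c("L1", "L2", "L3"),
                    x_mm = c(2, 8, 5), y_mm = c(2, 3, 9))
  px <- matrix(0.5, 40, 40)
  rot_photo <- function(lm, deg) {
    # the photo frame rotates by +deg about landmark L1: coordinates of the
    # (fixed) tissue landmarks in the new frame rotate by +deg about L1
    tf <- similarity_transform(deg, 1, c(0, 0))
    anchor <- unlist(lm[1, c("x_mm", "y_mm")])
    p <- apply_transform(tf, sweep(as.matrix(lm[, c("x_mm", "y_mm")]), 2, anchor))
    data.frame(label = lm$label, x_mm = p[, 1] + anchor[1], y_mm = p[, 2] + anchor[2])
  }
  photos <- list(
    planar_image(px, 0.25, 0, lm0),
    planar_image(px, 0.25, 1, rot_photo(lm0, 10)),
    planar_image(px, 0.25, 2, rot_photo(lm0, 10 + 5)))
  res <- stack_enface_photos(photos)
  expect_equal(res$transforms[[1]]$rotation_deg, 0)
  expect_equal(res$transforms[[2]]$rotation_deg, -10, tolerance = 1e-6)
  # chained rotations accumulate
  expect_equal(res$transforms[[3]]$rotation_deg, -15, tolerance = 1e-6)
  expect_true(all(vapply(res$transforms, function(t) t$scale, numeric(1)) == 1))
  # aligned identical photos give identity transforms
  aligned <- list(planar_image(px, 0.25, 0, lm0), planar_image(px, 0.25, 1, lm0))
  res2 <- stack_enface_photos(aligned)
  expect_equal(res2$transforms[[2]]$rotation_deg, 0, tolerance = 1e-12)
  expect_equal(res2$transforms[[2]]$translation_mm, c(0, 0), tolerance = 1e-12)
  expect_identical(dim(res2$volume$voxels)[3], 2L)
  # missing shared landmarks name the offending pair
  lonely <- planar_image(px, 0.25, 1, data.frame(label = "Q1", x_mm = 1, y_mm = 1))
  expect_error(stack_enface_photos(list(photos[[1]], lonely)), "1 and 2")
})

test_that("landmark fits map every photo into the first photo's frame", {
  b <- cached_phantom("deformed", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 1, rng_seed = 11))
  res <- stack_enface_photos(b$enface_photos)
  lm1 <- as.matrix(b$enface_photos[[1]]$landmarks[, c("x_mm", "y_mm")])
  for (k in seq_along(b$enface_photos)) {
    lmk <- as.matrix(b$enface_photos[[k]]$landmarks[, c("x_mm", "y_mm")])
    expect_equal(apply_transform(res$transforms[[k]], lmk), lm1, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("B-spline registration recovers a known warp of ~1 mm", {
  fixed <- one_slice_stack(list(lumen = circle_contour(c(0, 0), 3, 90),
                                outer_wall = circle_contour(c(0, 0), 4.5, 90)))
  g <- bspline_grid_for_bbox(c(-12, -12), c(12, 12), 24)
  set.seed(5)
  warp <- bspline_transform(g$origin_mm, g$spacing_mm, g$shape,
                            matrix(stats::runif(prod(g$shape), -1, 1), g$shape[1]),
                            matrix(stats::runif(prod(g$shape), -1, 1), g$shape[1]))
  moving <- transform_contours(fixed, invert_transform(warp))
  tfs <- register_contours_bspline(fixed, moving,
                                   bspline_params(iterations = 400, seed = 3))
  reg <- transform_contours(moving, tfs)
  for (st in c("lumen", "outer_wall")) {
    post <- mean(dist_to_polygon(
      resample_contour(stack_get(reg, 0, st), 0.05)[, 1],
      resample_contour(stack_get(reg, 0, st), 0.05)[, 2],
      stack_get(fixed, 0, st)))
    expect_lt(post, 0.2)
  }
  expect_lt(attr(tfs[["0"]], "metric_after"), attr(tfs[["0"]], "metric_before"))
})

test_that("registering a stack onto itself stays near the identity", {
  fixed <- one_slice_stack(list(lumen = circle_contour(c(0, 0), 3, 90)))
  tfs <- register_contours_bspline(fixed, fixed,
                                   bspline_params(iterations = 100, seed = 2))
  expect_lt(max(abs(c(tfs[["0"]]$coef_x, tfs[["0"]]$coef_y))), 0.05)
})

test_that("metric decreases monotonically over accepted iterations", {
  fixed <- one_slice_stack(list(lumen = circle_contour(c(0, 0), 5, 90)))
  moving <- one_slice_stack(list(lumen = circle_contour(c(0.5, 0), 5, 90)))
  tfs <- register_contours_bspline(fixed, moving,
                                   bspline_params(iterations = 300, seed = 4))
  trace <- attr(tfs[["0"]], "trace")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) <= 0))
  expect_lt(attr(tfs[["0"]], "metric_after"), attr(tfs[["0"]], "metric_before"))
})

test_that("non-overlapping stacks demand rigid pre-registration", {
  fixed <- one_slice_stack(list(lumen = circle_contour(c(0, 0), 2, 45)))
  moving <- one_slice_stack(list(lumen = circle_contour(c(50, 50), 2, 45)))
  expect_error(register_contours_bspline(fixed, moving), "rigid pre-registration")
})

test_that("resample_volume handles identity, shifts and constants", {
  set.seed(12)
  vol <- volume_image(array(stats::rnorm(1000), c(10, 10, 10)), c(1, 1, 1))
  same <- resample_volume(vol)
  expect_equal(same$voxels, vol$voxels, tolerance = 1e-12)
  # translation by exactly one voxel: shifted array, zero-filled boundary
  sh <- resample_volume(vol, function(p) cbind(p[, 1] - 1, p[, 2], p[, 3]))
  expect_equal(sh$voxels[2:10, , ], vol$voxels[1:9, , ], tolerance = 1e-12)
  expect_true(all(sh$voxels[1, , ] == 0))
  # constant volume stays constant under an in-domain warp
  cv <- volume_image(array(7, c(8, 8, 8)), c(1, 1, 1))
  w <- resample_volume(cv, function(p) p + 0.3)
  interior <- w$voxels[2:7, 2:7, 2:7]
  expect_equal(interior, array(7, dim(interior)), tolerance = 1e-12)
})
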