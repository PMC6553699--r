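test_that("phantom spec invariants are enforced with named messages", {
  expect_error(phantom_spec(n_sections = 1), "n_sections")
  expect_error(phantom_spec(section_spacing_mm = 0), "section_spacing_mm")
  expect_error(phantom_spec(wss_baseline_pa = 0), "wss_baseline_pa")
  expect_error(phantom_spec(wss_baseline_pa = 1,
                            wss_circumferential_amplitude_pa = 2), "amplitude")
  expect_error(phantom_spec(lumen_radius_profile = function(z) 3 - z),
               "lumen_radius_profile")
})

test_that("zero deformation gives identity truth transforms and matching contours", {
  b <- cached_phantom("zero", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 0, rng_seed = 3))
  for (s in 0:3) {
    expect_equal(stack_get(b$invivo_contours, s, "lumen"),
                 stack_get(b$enface_wall_contours, s, "lumen"), tolerance = 1e-12)
    expect_equal(stack_get(b$histology_contours, s, "lumen"),
                 stack_get(b$enface_contours, s, "lumen"), tolerance = 1e-12)
  }
  sims <- b$truth_transforms$histology_to_enface
  expect_true(all(vapply(sims, function(t)
    t$rotation_deg == 0 && t$scale == 1 && all(t$translation_mm == 0), logical(1))))
  p <- matrix(stats::runif(10, -3, 3), 5)
  expect_equal(apply_transform(b$truth_transforms$invivo_to_enface, p), p,
               tolerance = 1e-12)
})

test_that("truth transforms map modality contours back onto the en-face geometry", {
  b <- cached_phantom("deformed", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 1, rng_seed = 11))
  for (s in c(0, 2, 3)) {
    iv <- apply_transform(b$truth_transforms$invivo_to_enface,
                          stack_get(b$invivo_contours, s, "lumen"))
    expect_equal(iv, stack_get(b$enface_wall_contours, s, "lumen"), tolerance = 1e-6)
    ex <- apply_transform(b$truth_transforms$exvivo_to_enface,
                          stack_get(b$exvivo_contours, s, "outer_wall"))
    expect_equal(ex, stack_get(b$enface_wall_contours, s, "outer_wall"),
                 tolerance = 1e-6)
    h <- apply_transform(b$truth_transforms$histology_to_enface[[as.character(s)]],
                         stack_get(b$histology_contours, s, "media"))
    expect_equal(h, stack_get(b$enface_contours, s, "media"), tolerance = 1e-9)
  }
})

test_that("truth bin values are the closed-form field integrals", {
  # constant field: exactly the baseline everywhere
  spec <- phantom_spec(n_sections = 3, wss_axial_gradient_pa_per_mm = 0,
                       wss_circumferential_amplitude_pa = 0, wss_baseline_pa = 2,
                       deformation_magnitude_mm = 0)
  expect_equal(phantom_truth_bins(spec)$mean_wss_pa, rep(2, 24))
  # linear field: baseline + g * z at each section (z = 3 -> 5 Pa for g = 1, b = 2)
  spec_lin <- phantom_spec(n_sections = 10, wss_axial_gradient_pa_per_mm = 1,
                           wss_circumferential_amplitude_pa = 0, wss_baseline_pa = 2,
                           deformation_magnitude_mm = 0)
  tr <- phantom_truth_bins(spec_lin)
  expect_equal(tr$mean_wss_pa[tr$z_mm == 3], rep(5, 8))
  # cos component: sector integrals, zero when summed over all bins
  spec_cos <- phantom_spec(n_sections = 2, wss_axial_gradient_pa_per_mm = 0,
                           wss_circumferential_amplitude_pa = 1, wss_baseline_pa = 2,
                           deformation_magnitude_mm = 0)
  tc <- phantom_truth_bins(spec_cos)
  expect_equal(mean(tc$mean_wss_pa[tc$slice_index == 0]), 2, tolerance = 1e-12)
  # the two bins adjacent to theta = 0 carry the largest sector mean
  expect_equal(max(tc$mean_wss_pa), 2 + sin(pi / 4) / (pi / 4), tolerance = 1e-12)
})

test_that("same seed gives a bit-identical bundle; different seed differs", {
  s <- function(seed) phantom_spec(n_sections = 3, rng_seed = seed,
                                   deformation_magnitude_mm = 0.8)
  b1 <- generate_phantom(s(5)); b2 <- generate_phantom(s(5))
  expect_identical(b1$wss_surface$vertices, b2$wss_surface$vertices)
  expect_identical(stack_get(b1$invivo_contours, 1, "lumen"),
                   stack_get(b2$invivo_contours, 1, "lumen"))
  expect_identical(b1$enface_photos[[2]]$landmarks, b2$enface_photos[[2]]$landmarks)
  b3 <- generate_phantom(s(6))
  expect_false(identical(stack_get(b1$invivo_contours, 1, "lumen"),
                         stack_get(b3$invivo_contours, 1, "lumen")))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(generate_phantom(s(5))); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("rasterized occupancy volumes match analytic areas and conventions", {
  cs <- one_slice_stack(list(lumen = circle_contour(c(0, 0), 5, 360)))
  rv <- rasterize_contours_to_volume(cs, c(0.1, 0.1, 1))
  expect_equal(sum(rv$voxels) * 0.01, 25 * pi, tolerance = 0.02)
  # brute-force point-in-polygon cross-check on the occupied plane
  k <- which(apply(rv$voxels, 3, sum) > 0)
  expect_length(k, 1)
  # contour exactly midway between voxel planes rasterizes to neither
  mid <- contour_stack(list(
    list(slice_index = 0L, z_mm = 0, structure = "lumen",
         points = circle_contour(c(0, 0), 3, 90)),
    list(slice_index = 1L, z_mm = 0.5, structure = "lumen",
         points = circle_contour(c(0, 0), 6, 90)),
    list(slice_index = 2L, z_mm = 1, structure = "lumen",
         points = circle_contour(c(0, 0), 3, 90))), check_simple = FALSE)
  rv2 <- rasterize_contours_to_volume(mid, c(0.2, 0.2, 1))
  # planes at z = 0 and 1 take their own radius-3 contours; the radius-6
  # contour sits exactly midway and contributes to neither plane
  expect_identical(dim(rv2$voxels)[3], 2L)
  areas <- apply(rv2$voxels, 3, sum) * 0.04
  expect_equal(areas, rep(9 * pi, 2), tolerance = 0.03)
  expect_error(rasterize_contours_to_volume(contour_stack(list()), c(1, 1, 1)),
               "empty")
})
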