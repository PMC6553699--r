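test_that("radial bin assignment follows the half-open CCW convention", {
  p <- projection_params()
  deg <- function(d) c(cos(d * pi / 180), sin(d * pi / 180))
  expect_identical(assign_radial_bin(deg(10), c(0, 0), p), 0L)
  # boundary angle belongs to the higher-index wedge
  expect_identical(assign_radial_bin(deg(45), c(0, 0), p), 1L)
  expect_identical(assign_radial_bin(deg(0), c(0, 0), p), 0L)
  expect_identical(assign_radial_bin(deg(359.999), c(0, 0), p), 7L)
  expect_error(assign_radial_bin(c(1, 1), c(1, 1), p), "centerpoint")
  # configurable angular origin
  p90 <- projection_params(bin_zero_deg = 90)
  expect_identical(assign_radial_bin(deg(100), c(0, 0), p90), 0L)
})

test_that("uniform random points fill all wedges exactly once and evenly", {
  set.seed(77)
  n <- 10000L
  ang <- stats::runif(n, 0, 2 * pi)
  r <- stats::runif(n, 0.1, 2)
  pts <- cbind(1 + r * cos(ang), -2 + r * sin(ang))
  bins <- assign_radial_bin(pts, c(1, -2))
  expect_identical(length(bins), n)
  expect_true(all(bins %in% 0:7))
  counts <- tabulate(bins + 1, 8)
  expect_identical(sum(counts), n)
  # each wedge holds 1250 up to sampling error (~4 sd)
  expect_true(all(abs(counts - 1250) < 4 * sqrt(1250 * 7 / 8)))
})

test_that("projection reduces constant, linear and circumferential fields correctly", {
  # constant field: every non-empty bin is exactly (2, 2, 2)
  bconst <- cached_phantom("const", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 0,
                 wss_axial_gradient_pa_per_mm = 0,
                 wss_circumferential_amplitude_pa = 0, wss_baseline_pa = 2))
  pr <- project_wss_to_section(bconst$wss_surface, 2, c(0, 0))
  expect_equal(pr$mean_wss_pa, rep(2, 8))
  expect_equal(pr$min_wss_pa, rep(2, 8))
  expect_equal(pr$max_wss_pa, rep(2, 8))
  # linear axial field: symmetric window -> field value at the section z
  blin <- cached_phantom("lin8", function() linear_field_spec())
  for (z in c(0, 3, 7)) {
    pr <- project_wss_to_section(blin$wss_surface, z, c(0, 0))
    expect_equal(pr$mean_wss_pa, rep(3 + z, 8), tolerance = 1e-9)
  }
  # 2 + cos(theta): closed-form 45-degree sector averages
  bcos <- cached_phantom("cos", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 0,
                 wss_axial_gradient_pa_per_mm = 0,
                 wss_circumferential_amplitude_pa = 1, wss_baseline_pa = 2))
  pr <- project_wss_to_section(bcos$wss_surface, 2, c(0, 0))
  b <- 0:7; t1 <- 2 * pi * b / 8; t2 <- 2 * pi * (b + 1) / 8
  analytic <- 2 + (sin(t2) - sin(t1)) / (t2 - t1)
  expect_equal(pr$mean_wss_pa, analytic, tolerance = 0.01)
})

test_that("per-bin statistics respect min <= mean <= max and empty-bin semantics", {
  blin <- cached_phantom("lin8", function() linear_field_spec())
  pr <- project_wss_to_section(blin$wss_surface, 3, c(0, 0))
  expect_true(all(pr$min_wss_pa <= pr$mean_wss_pa + 1e-12))
  expect_true(all(pr$mean_wss_pa <= pr$max_wss_pa + 1e-12))
  # vertex-weighted global mean equals the mean over in-window vertices
  sel <- abs(blin$wss_surface$vertices[, 3] - 3) <= 0.3 + 1e-9
  expect_equal(sum(pr$mean_wss_pa * pr$n_vertices) / sum(pr$n_vertices),
               mean(blin$wss_surface$wss_pa[sel]), tolerance = 1e-12)
  # centerpoint near the ring leaves the wedges facing away empty (NA, not 0)
  pr_off <- project_wss_to_section(blin$wss_surface, 3, c(4, 0))
  expect_true(any(pr_off$empty))
  expect_true(all(is.na(pr_off$mean_wss_pa[pr_off$empty])))
  expect_error(project_wss_to_section(blin$wss_surface, 99, c(0, 0)), "window")
})

test_that("plaque thickness matches analytic and brute-force oracles", {
  params <- projection_params()
  conc <- plaque_thickness_per_bin(circle_contour(c(0, 0), 2, 360),
                                   circle_contour(c(0, 0), 3, 360), c(0, 0), params)
  expect_equal(conc$thickness_mm, rep(1, 8), tolerance = 1e-3)
  # zero-thickness limit
  zero <- plaque_thickness_per_bin(circle_contour(c(0, 0), 2, 360),
                                   circle_contour(c(0, 0), 2, 360), c(0, 0), params)
  expect_equal(zero$thickness_mm, rep(0, 8), tolerance = 1e-9)
  # offset lumen: sinusoidal pattern, checked against a dense point-cloud oracle
  lum <- circle_contour(c(0.5, 0), 2, 360)
  med <- circle_contour(c(0, 0), 3, 360)
  th <- plaque_thickness_per_bin(lum, med, c(0.5, 0), params)
  cloud <- resample_contour(med, 0.002)
  oracle <- vapply(0:7, function(b) {
    smp <- resample_contour(lum, 0.01)
    keep <- assign_radial_bin(smp, c(0.5, 0), params) == b
    mean(vapply(which(keep), function(i)
      min(sqrt((cloud[, 1] - smp[i, 1])^2 + (cloud[, 2] - smp[i, 2])^2)),
      numeric(1)))
  }, numeric(1))
  expect_equal(th$thickness_mm, oracle, tolerance = 1e-2)
  expect_equal(min(th$thickness_mm) + max(th$thickness_mm),
               2 * mean(range(th$thickness_mm)), tolerance = 1e-9)
  # intersecting contours are rejected
  expect_error(plaque_thickness_per_bin(circle_contour(c(2, 0), 2, 90),
                                        circle_contour(c(0, 0), 3, 90),
                                        c(2, 0), params), "intersect")
})

test_that("thickness is invariant under rigid motion of both contours", {
  params <- projection_params()
  lum <- circle_contour(c(0.5, 0), 2, 180)
  med <- circle_contour(c(0, 0), 3, 180)
  th0 <- plaque_thickness_per_bin(lum, med, c(0.5, 0), params)
  tf <- similarity_transform(25, 1, c(7, -3))
  # rotate bin origin along so the same sectors are compared
  params_rot <- projection_params(bin_zero_deg = 25)
  th1 <- plaque_thickness_per_bin(apply_transform(tf, lum), apply_transform(tf, med),
                                  as.numeric(apply_transform(tf, matrix(c(0.5, 0), 1))),
                                  params_rot)
  expect_equal(th1$thickness_mm, th0$thickness_mm, tolerance = 1e-6)
})

test_that("bin table assembly counts rows and rejects duplicates", {
  mk_section <- function(id, s) list(
    specimen_id = id, slice_index = s, z_mm = s,
    wss = data.frame(bin_index = 0:7, mean_wss_pa = 1, min_wss_pa = 1,
                     max_wss_pa = 1, n_vertices = 10L, empty = FALSE))
  secs <- c(lapply(0:11, function(s) mk_section("CEA1", s)),
            lapply(0:10, function(s) mk_section("CEA2", s)))
  tb <- build_bin_table(secs)
  expect_identical(nrow(tb), 184L)
  expect_identical(nrow(build_bin_table(secs[1])), 8L)
  expect_identical(nrow(build_bin_table(list())), 0L)
  expect_error(build_bin_table(c(secs, secs[1])), "duplicate")
})
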