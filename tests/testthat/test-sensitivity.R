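test_that("Wilcoxon signed-rank matches literal sign enumeration for n <= 10", {
  # frozen spec example: n = 5, all differences positive
  expect_equal(wilcoxon_signed_rank(1:5, rep(0, 5)), 0.0625)
  expect_warning(p <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(p, 1)
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    a <- round(stats::rnorm(n), 2)
    b <- round(stats::rnorm(n), 2)
    expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_enum_oracle(a, b),
                 tolerance = 1e-12, info = paste("rep", rep))
  }
  # ties in |d| are handled identically to the enumeration oracle
  a <- c(2, -2, 1, -1, 3)
  expect_equal(wilcoxon_signed_rank(a, rep(0, 5)), wilcoxon_enum_oracle(a, rep(0, 5)))
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("Wilcoxon normal approximation agrees with the reference implementation", {
  set.seed(23)
  a <- stats::rnorm(40, 0.2); b <- stats::rnorm(40)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  res <- pearson_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * stats::pt(-abs(r_oracle * sqrt(2 / (1 - r_oracle^2))), df = 2),
               tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("relocation shifts a linear field by exactly g * dz", {
  b <- cached_phantom("lin8", function() linear_field_spec())
  sections <- lapply(0:7, function(s) list(specimen_id = "P1", slice_index = s,
                                           z_mm = s, centerpoint = c(0, 0)))
  base <- relocate_and_reproject(b$wss_surface, sections, dz_mm = 0)
  # dz = 0 reproduces the baseline bin table exactly
  direct <- build_bin_table(lapply(sections, function(s) {
    s$wss <- project_wss_to_section(b$wss_surface, s$z_mm, s$centerpoint)
    s
  }))
  expect_equal(as.data.frame(base), as.data.frame(direct), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (dz in c(0.3, 0.6, -0.6)) {
    rel <- relocate_and_reproject(b$wss_surface, sections, dz_mm = dz)
    d <- delta_wss(base, rel)
    expect_equal(unname(d$grand["dmean_pa"]), abs(dz), tolerance = 1e-9)
    # per-bin sign convention: positive dz lowers sampled values by g * dz
    expect_equal(as.data.frame(rel)$mean_wss_pa,
                 as.data.frame(base)$mean_wss_pa - dz, tolerance = 1e-9)
  }
  # relocation by dz then -dz returns the baseline exactly
  once <- relocate_surface(b$wss_surface, 0.6)
  back <- relocate_surface(once, -0.6)
  expect_equal(back$vertices, b$wss_surface$vertices, tolerance = 1e-12)
})

test_that("constant fields are relocation-invariant and deltas are monotone in |dz|", {
  bconst <- cached_phantom("const", function()
    phantom_spec(n_sections = 4, deformation_magnitude_mm = 0,
                 wss_axial_gradient_pa_per_mm = 0,
                 wss_circumferential_amplitude_pa = 0, wss_baseline_pa = 2))
  sections <- lapply(0:3, function(s) list(specimen_id = "PC", slice_index = s,
                                           z_mm = s, centerpoint = c(0, 0)))
  base <- relocate_and_reproject(bconst$wss_surface, sections, dz_mm = 0)
  rel <- relocate_and_reproject(bconst$wss_surface, sections, dz_mm = 0.6)
  expect_equal(as.data.frame(rel)$mean_wss_pa, as.data.frame(base)$mean_wss_pa)
  # monotone on the linear-gradient phantom, bin-wise
  blin <- cached_phantom("lin8", function() linear_field_spec())
  slin <- lapply(0:7, function(s) list(specimen_id = "P1", slice_index = s,
                                       z_mm = s, centerpoint = c(0, 0)))
  b0 <- relocate_and_reproject(blin$wss_surface, slin, dz_mm = 0)
  d3 <- delta_wss(b0, relocate_and_reproject(blin$wss_surface, slin, dz_mm = 0.3))
  d6 <- delta_wss(b0, relocate_and_reproject(blin$wss_surface, slin, dz_mm = 0.6))
  expect_true(all(d6$per_bin$dmean_pa >= d3$per_bin$dmean_pa - 1e-12))
})

test_that("correlation sweep finds the constructed WSS-thickness anticorrelation", {
  bc <- cached_phantom("coupled", function()
    phantom_spec(n_sections = 5, deformation_magnitude_mm = 0,
                 wss_axial_gradient_pa_per_mm = 0.1,
                 wss_circumferential_amplitude_pa = 1.5, wss_baseline_pa = 2.5,
                 thickness_wss_coupling = 0.5, rng_seed = 2))
  sections <- lapply(0:4, function(s) {
    th <- plaque_thickness_per_bin(stack_get(bc$histology_contours, s, "lumen"),
                                   stack_get(bc$histology_contours, s, "media"),
                                   c(0, 0))
    list(specimen_id = "PC", slice_index = s, z_mm = s, centerpoint = c(0, 0),
         thickness = th)
  })
  tabs <- list()
  for (dz in c(-0.3, 0, 0.3))
    tabs[[as.character(dz)]] <- relocate_and_reproject(bc$wss_surface_enface,
                                                       sections, dz_mm = dz)
  sw <- correlation_sweep(tabs, "mean")
  expect_identical(nrow(sw), 15L)  # 5 locations x 3 relocations
  expect_true(all(sw$r < 0))
  expect_true(all(sw$p_value < 0.05))
  expect_equal(sw$delta_r[sw$dz_mm == 0], rep(0, 5))
  # locations with < 3 usable bins are skipped
  crippled <- tabs
  t0 <- as.data.frame(crippled[["0"]])
  t0$plaque_thickness_mm[t0$slice_index == 4 & t0$bin_index > 1] <- NA
  crippled[["0"]] <- bin_table(t0)
  sw2 <- correlation_sweep(crippled, "mean")
  expect_false(any(sw2$slice_index == 4 & sw2$dz_mm == 0))
  expect_true(any(attr(sw2, "skipped")$slice_index == 4))
})
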