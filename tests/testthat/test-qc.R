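test_that("Dice coefficient matches hand-countable cases and brute force", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  # two 10x10 squares overlapping in a 10x5 strip -> 2*50/200 = 0.5
  c2 <- matrix(FALSE, 20, 20); c2[1:10, 6:15] <- TRUE
  expect_equal(dice_coefficient(a, c2), 0.5)
  expect_equal(dice_coefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice_coefficient(a, matrix(FALSE, 20, 20)), "empty")
  expect_error(dice_coefficient(a, matrix(TRUE, 5, 5)), "shapes differ")
  # contour path equals brute-force pixel counting on random masks
  set.seed(3)
  for (rep in 1:3) {
    sq1 <- unit_square(stats::runif(1), stats::runif(1), 10)
    sq2 <- unit_square(stats::runif(1, 3, 7), stats::runif(1, -2, 2), 10)
    pts <- rbind(sq1, sq2)
    bbox <- list(lo = apply(pts, 2, min) - 0.1, hi = apply(pts, 2, max) + 0.1)
    m1 <- rasterize_contour_mask(sq1, 0.05, bbox)
    m2 <- rasterize_contour_mask(sq2, 0.05, bbox)
    expect_equal(dice_from_contours(sq1, sq2, 0.05),
                 2 * sum(m1 & m2) / (sum(m1) + sum(m2)), tolerance = 1e-3)
  }
})

test_that("Hausdorff distance matches analytic circles and the all-pairs oracle", {
  c0 <- circle_contour(c(0, 0), 5, 720)
  expect_equal(hausdorff_distance(c0, c0), 0)
  expect_equal(hausdorff_distance(c0, circle_contour(c(0.3, 0), 5, 720)), 0.3,
               tolerance = 1e-3)
  expect_equal(hausdorff_distance(c0, circle_contour(c(0, 0), 6, 720)), 1,
               tolerance = 1e-3)
  expect_error(hausdorff_distance(matrix(numeric(), 0, 2), c0), "empty")
  # O(n^2) dense point-pair oracle on small irregular contours
  set.seed(6)
  a <- circle_contour(c(0, 0), 3, 24) + matrix(stats::runif(48, -0.3, 0.3), 24)
  b <- circle_contour(c(0.4, -0.2), 3.2, 20) + matrix(stats::runif(40, -0.3, 0.3), 20)
  pa <- resample_contour(a, 0.005); pb <- resample_contour(b, 0.005)
  dmat_max <- function(p, q) max(vapply(seq_len(nrow(p)), function(i)
    min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), numeric(1)))
  oracle <- max(dmat_max(pa, pb), dmat_max(pb, pa))
  expect_equal(hausdorff_distance(a, b, 0.02), oracle, tolerance = 5e-3)
})

test_that("exclusion bookkeeping implements set-union semantics", {
  mk_section <- function(id, s) list(
    specimen_id = id, slice_index = s, z_mm = s,
    wss = data.frame(bin_index = 0:7, mean_wss_pa = 1, min_wss_pa = 1,
                     max_wss_pa = 1, n_vertices = 1L, empty = FALSE))
  tb <- build_bin_table(lapply(0:11, function(s) mk_section("CEA1", s)))
  # no flags: everything included
  no_flags <- data.frame(specimen_id = character(), slice_index = integer(),
                         bin_index = integer(), error_type = character())
  t0 <- apply_exclusions(tb, no_flags)
  expect_true(all(t0$included))
  expect_equal(exclusion_tally(t0)$remaining_fraction, 1)
  # overlapping flag lists: 24 type1, 8 type2, 5 type3 with stated overlaps
  set.seed(9)
  all_keys <- expand.grid(slice_index = 0:11, bin_index = 0:7)
  pick <- function(n, from = seq_len(nrow(all_keys))) sample(from, n)
  i1 <- pick(24)
  i2 <- c(i1[1:3], pick(5, setdiff(seq_len(nrow(all_keys)), i1)))   # 3 overlap type1
  i3 <- c(i2[4], pick(4, setdiff(seq_len(nrow(all_keys)), c(i1, i2))))  # 1 overlap type2
  flags <- rbind(
    data.frame(specimen_id = "CEA1", all_keys[i1, ], error_type = "type1"),
    data.frame(specimen_id = "CEA1", all_keys[i2, ], error_type = "type2"),
    data.frame(specimen_id = "CEA1", all_keys[i3, ], error_type = "type3"))
  tf <- apply_exclusions(tb, flags)
  tally <- exclusion_tally(tf)
  union_oracle <- length(unique(c(i1, i2, i3)))
  expect_identical(tally$excluded, union_oracle)
  expect_identical(tally$remaining, 96L - union_oracle)
  expect_identical(tally$type1, 24L)
  expect_identical(tally$type2, 8L)
  expect_identical(tally$type3, 5L)
  # a double-flagged bin appears once in exclusions but in both type tallies
  key <- paste("CEA1", all_keys$slice_index[i2[1]], all_keys$bin_index[i2[1]])
  row <- tf[paste(tf$specimen_id, tf$slice_index, tf$bin_index) == key, ]
  expect_identical(row$error_flags, "type1,type2")
  expect_false(row$included)
  # unknown bin keys are rejected
  bad <- data.frame(specimen_id = "CEA9", slice_index = 0L, bin_index = 0L,
                    error_type = "type1")
  expect_error(apply_exclusions(tb, bad), "unknown bins")
})

test_that("QC summary reproduces Table-1-style cross-specimen arithmetic", {
  expect_equal(qc_cross_specimen_average(c(0.83, 0.81)), 0.82)
  expect_equal(qc_cross_specimen_average(c(0.90, 0.89)), 0.90)
  expect_equal(qc_cross_specimen_average(c(0.65, 0.75)), 0.70)
  expect_equal(qc_cross_specimen_average(c(0.59, 0.55)), 0.57)
  expect_equal(qc_cross_specimen_average(0.73), 0.73)  # single specimen
})

test_that("qc_summary aggregates per-section metrics before/after exclusion", {
  mk_section <- function(id, s) list(
    specimen_id = id, slice_index = s, z_mm = s,
    wss = data.frame(bin_index = 0:7, mean_wss_pa = 1, min_wss_pa = 1,
                     max_wss_pa = 1, n_vertices = 1L, empty = FALSE))
  tb <- build_bin_table(lapply(0:3, function(s) mk_section("P", s)))
  # slices 0 and 1 carry type2-flagged bins (poorly registered sections)
  flags <- data.frame(specimen_id = "P", slice_index = c(0L, 1L),
                      bin_index = c(2L, 5L), error_type = "type2")
  tb <- apply_exclusions(tb, flags)
  metrics <- data.frame(specimen_id = "P", slice_index = 0:3,
                        dsc_type2 = c(0.5, 0.6, 0.9, 0.9),
                        hd_type2_mm = c(2, 1.5, 0.5, 0.5),
                        dsc_type3 = c(0.8, 0.8, 0.8, 0.8),
                        hd_type3_mm = c(1, 1, 1, 1))
  s <- qc_summary(metrics, tb)
  t2 <- s$per_specimen[s$per_specimen$error_type == "type2", ]
  expect_equal(t2$dsc_before, mean(c(0.5, 0.6, 0.9, 0.9)))
  expect_equal(t2$dsc_after, 0.9)   # only clean sections 2, 3 remain
  expect_equal(t2$hd_after_mm, 0.5)
  # exclusion improves the aggregate in the expected direction
  expect_gt(t2$dsc_after, t2$dsc_before)
  expect_lt(t2$hd_after_mm, t2$hd_before_mm)
  t3 <- s$per_specimen[s$per_specimen$error_type == "type3", ]
  expect_equal(t3$dsc_after, t3$dsc_before)  # no type3 flags -> unchanged
})
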