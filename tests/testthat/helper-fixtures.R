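# Shared fixtures, all generated in code.

unit_square <- function(x0 = 0, y0 = 0, side = 1)
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))

# one-slice contour stack from a named list of contours
one_slice_stack <- function(contours, z = 0, slice = 0L)
  contour_stack(lapply(names(contours), function(st)
    list(slice_index = slice, z_mm = z, structure = st,
         points = contours[[st]])), check_simple = FALSE)

# simple multi-slice lumen stack: circles with per-slice center/radius
tube_stack <- function(centers, radii, z = seq_along(radii) - 1, n = 90)
  contour_stack(lapply(seq_along(radii), function(i)
    list(slice_index = i - 1L, z_mm = z[i], structure = "lumen",
         points = circle_contour(centers[i, ], radii[i], n))),
    check_simple = FALSE)

# memoised phantoms: heavy bundles built once per test run
.phantom_cache <- new.env()
cached_phantom <- function(key, spec_fn) {
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- generate_phantom(spec_fn())
  .phantom_cache[[key]]
}

linear_field_spec <- function(n_sections = 8, g = 1, baseline = 3, seed = 1)
  phantom_spec(n_sections = n_sections, deformation_magnitude_mm = 0,
               wss_axial_gradient_pa_per_mm = g,
               wss_circumferential_amplitude_pa = 0, wss_baseline_pa = baseline,
               rng_seed = seed)

# brute-force two-sided Wilcoxon signed-rank p by literal sign enumeration
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b; d <- d[d != 0]; n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d)); w <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
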