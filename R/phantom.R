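# Synthetic single-lumen tube phantoms with known ground-truth transforms and
# an analytic WSS field, so every pipeline stage is testable without patient
# data. The WSS magnitude on the lumen at axial position z and en-face angle
# theta is baseline + gradient * z + amplitude * cos(theta). Modality contours
# are the en-face geometry carried through the inverses of known similarity +
# B-spline truth chains; landmark correspondences come from the similarity
# components only (fiducials anchor the rigid steps, contours carry the
# non-rigid tissue deformation).

#' Stenotic lumen radius profile
#'
#' Gaussian narrowing `r0 - depth * exp(-((z - center_z) / width)^2)`,
#' emulating a stenosed carotid segment.
#' @param r0 nominal radius, mm.
#' @param depth narrowing depth, mm (`< r0`).
#' @param center_z stenosis center, mm.
#' @param width Gaussian width, mm.
#' @return function of z returning the radius in mm.
#' @export
stenotic_radius_profile <- function(r0 = 3, depth = 1.8, center_z = 5.5, width = 3) {
  function(z) r0 - depth * exp(-((z - center_z) / width)^2)
}

#' Constant profile helper
#' @param value constant value returned for every z.
#' @return function of z.
#' @export
constant_profile <- function(value) function(z) rep(value, length(z))

#' Phantom specification
#'
#' Defines the stated world a synthetic specimen is drawn from. Deterministic
#' for a fixed `rng_seed`.
#'
#' @param n_sections number of 1 mm transverse sections (>= 2; default 12).
#' @param section_spacing_mm axial spacing between sections (default 1.0).
#' @param lumen_radius_profile function of z (mm) returning the lumen radius
#'   (must stay positive over the meshed range, including the axial overhang).
#' @param wall_thickness_profile function of z returning the lumen-to-media
#'   wall thickness, mm.
#' @param wss_axial_gradient_pa_per_mm axial WSS gradient g (Pa/mm).
#' @param wss_circumferential_amplitude_pa amplitude of the `cos(theta)` WSS
#'   component (Pa); must not exceed the baseline.
#' @param wss_baseline_pa strictly positive baseline WSS (Pa).
#' @param deformation_magnitude_mm bound d on the truth B-spline control-point
#'   displacements (and scale of the photo-frame jitter); 0 gives identity
#'   truth transforms everywhere.
#' @param rng_seed integer seed.
#' @param thickness_wss_coupling k >= 0: wall thickness becomes
#'   `wall_thickness_profile(z) - k * (wss - baseline)`, making plaque
#'   thickness anti-proportional to local WSS (0 disables the coupling).
#' @param invivo_similarity,exvivo_similarity optional
#'   [similarity_transform()]s fixing the similarity part of the respective
#'   truth chains (defaults: drawn from the RNG, identities when
#'   `deformation_magnitude_mm == 0`).
#' @param reference_slice_index slice anchoring cross-modality similarity
#'   fits (stands in for the first slice cranial to the bifurcation; default:
#'   middle slice).
#' @param n_theta circumferential contour/mesh sampling (default 72).
#' @param mesh_dz_mm axial mesh sampling of the WSS surface (default 0.1).
#' @param mesh_overhang_mm axial mesh extension beyond the first/last section
#'   (default 1.0, accommodating the projection window plus the largest
#'   relocation studied).
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_sections = 12L, section_spacing_mm = 1.0,
                         lumen_radius_profile = stenotic_radius_profile(),
                         wall_thickness_profile = constant_profile(1.5),
                         wss_axial_gradient_pa_per_mm = 0.1,
                         wss_circumferential_amplitude_pa = 0.5,
                         wss_baseline_pa = 2.0,
                         deformation_magnitude_mm = 0.5,
                         rng_seed = 1L,
                         thickness_wss_coupling = 0,
                         invivo_similarity = NULL, exvivo_similarity = NULL,
                         reference_slice_index = NULL,
                         n_theta = 72L, mesh_dz_mm = 0.1, mesh_overhang_mm = 1.0) {
  if (n_sections < 2) stop("invalid phantom spec: n_sections must be >= 2")
  if (section_spacing_mm <= 0) stop("invalid phantom spec: section_spacing_mm must be > 0")
  if (wss_baseline_pa <= 0) stop("invalid phantom spec: wss_baseline_pa must be > 0")
  if (wss_baseline_pa - abs(wss_circumferential_amplitude_pa) < 0)
    stop("invalid phantom spec: baseline - |circumferential amplitude| must be >= 0 (non-negative WSS)")
  if (deformation_magnitude_mm < 0)
    stop("invalid phantom spec: deformation_magnitude_mm must be >= 0")
  z_lo <- -mesh_overhang_mm
  z_hi <- (n_sections - 1) * section_spacing_mm + mesh_overhang_mm
  zz <- seq(z_lo, z_hi, by = mesh_dz_mm / 2)
  if (any(lumen_radius_profile(zz) <= 0))
    stop("invalid phantom spec: lumen_radius_profile(z) must be > 0 over the meshed range")
  if (is.null(reference_slice_index))
    reference_slice_index <- as.integer(floor(n_sections / 2))
  structure(list(n_sections = as.integer(n_sections),
                 section_spacing_mm = section_spacing_mm,
                 lumen_radius_profile = lumen_radius_profile,
                 wall_thickness_profile = wall_thickness_profile,
                 wss_axial_gradient_pa_per_mm = wss_axial_gradient_pa_per_mm,
                 wss_circumferential_amplitude_pa = wss_circumferential_amplitude_pa,
                 wss_baseline_pa = wss_baseline_pa,
                 deformation_magnitude_mm = deformation_magnitude_mm,
                 rng_seed = as.integer(rng_seed),
                 thickness_wss_coupling = thickness_wss_coupling,
                 invivo_similarity = invivo_similarity,
                 exvivo_similarity = exvivo_similarity,
                 reference_slice_index = reference_slice_index,
                 n_theta = as.integer(n_theta), mesh_dz_mm = mesh_dz_mm,
                 mesh_overhang_mm = mesh_overhang_mm),
            class = "phantom_spec")
}

# wall thickness at (theta, z); strictly positive or generation fails
.phantom_thickness <- function(spec, theta, z) {
  wss_dev <- spec$wss_axial_gradient_pa_per_mm * z +
    spec$wss_circumferential_amplitude_pa * cos(theta)
  t <- spec$wall_thickness_profile(z) - spec$thickness_wss_coupling * wss_dev
  if (any(t <= 0))
    stop("invalid phantom spec: wall thickness becomes non-positive; reduce thickness_wss_coupling")
  t
}

#' Closed-form per-bin mean WSS of the phantom field
#'
#' Analytic integration of `baseline + g z + A cos(theta)` over each bin's
#' angular sector (the axial window is symmetric about the section, so the
#' axial term contributes `g z_section` exactly).
#' @param spec a [phantom_spec()].
#' @param params a [projection_params()].
#' @return data.frame with `slice_index`, `z_mm`, `bin_index`, `mean_wss_pa`.
#' @export
phantom_truth_bins <- function(spec, params = projection_params()) {
  zs <- (seq_len(spec$n_sections) - 1) * spec$section_spacing_mm
  nb <- params$n_bins
  th0 <- params$bin_zero_deg * pi / 180
  rows <- lapply(seq_along(zs), function(i) {
    b <- seq_len(nb) - 1L
    t1 <- th0 + 2 * pi * b / nb; t2 <- th0 + 2 * pi * (b + 1) / nb
    sector <- (sin(t2) - sin(t1)) / (t2 - t1)
    data.frame(slice_index = i - 1L, z_mm = zs[i], bin_index = b,
               mean_wss_pa = spec$wss_baseline_pa +
                 spec$wss_axial_gradient_pa_per_mm * zs[i] +
                 spec$wss_circumferential_amplitude_pa * sector)
  })
  do.call(rbind, rows)
}

# draw a random similarity scaled to the deformation regime (identity at d=0)
.draw_similarity <- function(d) {
  if (d == 0) return(similarity_transform(0, 1, c(0, 0)))
  similarity_transform(stats::runif(1, -25, 25),
                       stats::runif(1, 0.9, 1.15),
                       stats::runif(2, -2, 2))
}

# 4x4 single-patch truth B-spline over the given bbox with coefficients
# drawn uniformly in [-d, d]; zero matrix when d = 0
.draw_bspline <- function(lo, hi, d, margin = 5) {
  h <- max(hi - lo) + 2 * margin
  origin <- c(mean(c(lo[1], hi[1])), mean(c(lo[2], hi[2]))) - 1.5 * h
  coef_x <- matrix(if (d > 0) stats::runif(16, -d, d) else 0, 4, 4)
  coef_y <- matrix(if (d > 0) stats::runif(16, -d, d) else 0, 4, 4)
  bspline_transform(origin, c(h, h), c(4L, 4L), coef_x, coef_y)
}

#' Generate a synthetic specimen bundle
#'
#' Builds en-face photos with landmarks, histology / in vivo / ex vivo contour
#' stacks, the WSS lumen surface (in the in vivo domain), ground-truth
#' transform chains and the closed-form per-bin WSS means. Applying the truth
#' chains to each modality's contours reproduces the en-face contours to
#' numerical tolerance. Bit-identical for a fixed `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param params a [projection_params()] used for the truth bin values.
#' @return list of class `phantom_bundle`; see the package vignette for the
#'   component layout.
#' @export
generate_phantom <- function(spec, params = projection_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(spec$rng_seed)

  n <- spec$n_sections
  zs <- (seq_len(n) - 1) * spec$section_spacing_mm
  d <- spec$deformation_magnitude_mm
  theta <- 2 * pi * (seq_len(spec$n_theta) - 1) / spec$n_theta

  # --- en-face (world frame) geometry ---------------------------------------
  mk_entries <- function(structures) {
    out <- list()
    for (i in seq_len(n)) {
      z <- zs[i]
      r <- spec$lumen_radius_profile(z)
      t_th <- .phantom_thickness(spec, theta, z)
      geo <- list(
        lumen = cbind(r * cos(theta), r * sin(theta)),
        intima = cbind((r + 0.5 * t_th) * cos(theta), (r + 0.5 * t_th) * sin(theta)),
        media = cbind((r + t_th) * cos(theta), (r + t_th) * sin(theta)))
      geo$outer_wall <- geo$media
      for (st in structures)
        out[[length(out) + 1]] <- list(slice_index = i - 1L, z_mm = z,
                                       structure = st, points = geo[[st]])
    }
    out
  }
  enface_hist <- contour_stack(mk_entries(c("lumen", "intima", "media")),
                               check_simple = FALSE)
  enface_wall <- contour_stack(mk_entries(c("lumen", "outer_wall")),
                               check_simple = FALSE)

  r_max <- max(vapply(zs, function(z)
    spec$lumen_radius_profile(z) + max(.phantom_thickness(spec, theta, z)), numeric(1)))
  lm_radius <- r_max + 2
  lm_angles <- c(15, 105, 195, 285) * pi / 180
  lm_world <- cbind(lm_radius * cos(lm_angles), lm_radius * sin(lm_angles))
  lm_labels <- paste0("L", seq_len(nrow(lm_world)))

  # --- en-face photos with per-photo rigid jitter ---------------------------
  half_extent <- lm_radius + 3
  pixel_size <- 0.2
  npix <- as.integer(ceiling(2 * half_extent / pixel_size))
  photos <- vector("list", n)
  photo_truth <- vector("list", n)  # photo frame -> world
  jitter_scale <- min(1, d)
  for (i in seq_len(n)) {
    rot <- if (i == 1) 0 else stats::runif(1, -10, 10) * jitter_scale
    jit <- if (i == 1) c(0, 0) else stats::runif(2, -1, 1) * jitter_scale
    # world -> photo: rotate, then shift the geometry into the positive quadrant
    H <- similarity_transform(rot, 1, c(half_extent + jit[1], half_extent + jit[2]))
    G <- invert_transform(H)  # photo -> world
    photo_truth[[i]] <- G
    lm_photo <- apply_transform(H, lm_world)
    px_centers_x <- (seq_len(npix) - 0.5) * pixel_size
    world_pts <- apply_transform(G, cbind(rep(px_centers_x, times = npix),
                                          rep(px_centers_x, each = npix)))
    rr <- sqrt(rowSums(world_pts^2))
    ang <- atan2(world_pts[, 2], world_pts[, 1])
    r_lum <- spec$lumen_radius_profile(zs[i])
    r_med <- r_lum + .phantom_thickness(spec, ang, zs[i])
    val <- ifelse(rr < r_lum, 0.15, ifelse(rr < r_med, 0.65, 0.95))
    # pixels matrix: rows = y, cols = x
    pixels <- matrix(val, npix, npix, byrow = TRUE)
    photos[[i]] <- planar_image(pixels, pixel_size, zs[i],
                                data.frame(label = lm_labels,
                                           x_mm = lm_photo[, 1], y_mm = lm_photo[, 2]))
  }

  # --- truth chains ----------------------------------------------------------
  pts_all <- do.call(rbind, lapply(enface_hist$entries, `[[`, "points"))
  lo <- apply(pts_all, 2, min); hi <- apply(pts_all, 2, max)
  sim_ex <- if (!is.null(spec$exvivo_similarity)) spec$exvivo_similarity else .draw_similarity(d)
  sim_iv <- if (!is.null(spec$invivo_similarity)) spec$invivo_similarity else .draw_similarity(d)
  bsp_ex <- .draw_bspline(lo, hi, d)
  bsp_iv <- .draw_bspline(lo, hi, d)
  chain_ex <- transform_chain(list(sim_ex, bsp_ex))      # exvivo -> enface
  chain_ie <- transform_chain(list(sim_iv, bsp_iv))      # invivo -> exvivo
  hist_sims <- stats::setNames(lapply(seq_len(n), function(i) {
    if (d == 0) similarity_transform(0, 1, c(0, 0))
    else similarity_transform(stats::runif(1, -15, 15), stats::runif(1, 0.92, 1.0),
                              stats::runif(2, -1, 1))
  }), as.character(seq_len(n) - 1L))                     # histology -> enface

  inv_chain_ex <- invert_transform(chain_ex)
  inv_chain_ie <- invert_transform(chain_ie)
  exvivo_contours <- transform_contours(enface_wall, inv_chain_ex)
  invivo_contours <- transform_contours(exvivo_contours, inv_chain_ie)
  histology_contours <- transform_contours(enface_hist,
                                           lapply(hist_sims, invert_transform))

  # --- landmark tables (similarity-only correspondences) --------------------
  ref <- spec$reference_slice_index
  lm_df <- function(pts, slice) data.frame(slice_index = slice, label = lm_labels,
                                           x_mm = pts[, 1], y_mm = pts[, 2])
  lm_exvivo <- apply_transform(invert_transform(sim_ex), lm_world)
  lm_invivo <- apply_transform(invert_transform(sim_iv), lm_exvivo)
  landmarks <- list(
    enface = lm_df(lm_world, ref),
    exvivo = lm_df(lm_exvivo, ref),
    invivo = lm_df(lm_invivo, ref),
    histology = do.call(rbind, lapply(seq_len(n), function(i)
      lm_df(apply_transform(invert_transform(hist_sims[[i]]), lm_world), i - 1L))))

  # --- WSS lumen surface in the in vivo domain ------------------------------
  mesh_z <- seq(-spec$mesh_overhang_mm,
                (n - 1) * spec$section_spacing_mm + spec$mesh_overhang_mm,
                by = spec$mesh_dz_mm)
  th_mid <- 2 * pi * (seq_len(spec$n_theta) - 0.5) / spec$n_theta
  nt <- spec$n_theta
  verts <- do.call(rbind, lapply(mesh_z, function(z) {
    r <- spec$lumen_radius_profile(z)
    cbind(r * cos(th_mid), r * sin(th_mid), z)
  }))
  wss <- as.numeric(vapply(mesh_z, function(z)
    spec$wss_baseline_pa + spec$wss_axial_gradient_pa_per_mm * z +
      spec$wss_circumferential_amplitude_pa * cos(th_mid), numeric(nt)))
  if (any(wss < 0)) stop("invalid phantom spec: WSS field becomes negative on the mesh")
  faces <- do.call(rbind, lapply(seq_len(length(mesh_z) - 1), function(k) {
    base <- (k - 1) * nt
    j <- seq_len(nt); jn <- c(seq_len(nt)[-1], 1L)
    rbind(cbind(base + j, base + jn, base + nt + j),
          cbind(base + jn, base + nt + jn, base + nt + j))
  }))
  wss_enface <- surface_field(verts, faces, wss)
  chain_iv_to_enface <- transform_chain(list(chain_ie, chain_ex))
  wss_invivo <- transform_surface(wss_enface, invert_transform(chain_iv_to_enface))

  structure(list(
    spec = spec,
    section_z_mm = zs,
    enface_photos = photos,
    enface_contours = enface_hist,
    enface_wall_contours = enface_wall,
    histology_contours = histology_contours,
    invivo_contours = invivo_contours,
    exvivo_contours = exvivo_contours,
    wss_surface = wss_invivo,
    wss_surface_enface = wss_enface,
    landmarks = landmarks,
    truth_transforms = list(photo_to_world = photo_truth,
                            histology_to_enface = hist_sims,
                            invivo_to_exvivo = chain_ie,
                            exvivo_to_enface = chain_ex,
                            invivo_to_enface = chain_iv_to_enface),
    truth_bin_values = phantom_truth_bins(spec, params)),
    class = "phantom_bundle")
}

#' Rasterize a contour stack to a binary occupancy volume
#'
#' Voxel centers inside the lumen polygon of their plane's contour become 1.
#' A contour contributes to a voxel plane only when it lies strictly within
#' half a z-spacing of that plane (nearest-slice convention): a contour
#' exactly midway between two planes rasterizes to neither.
#'
#' @param contours a [contour_stack()] (the lumen structure is used).
#' @param spacing_mm length-3 voxel spacing.
#' @return binary [volume_image()].
#' @export
rasterize_contours_to_volume <- function(contours, spacing_mm) {
  if (!inherits(contours, "contour_stack") || !length(contours$entries))
    stop("empty contour stack")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing must be 3 positive values")
  lum <- Filter(function(e) e$structure == "lumen", contours$entries)
  if (!length(lum)) stop("no lumen contours to rasterize")
  for (e in lum) validate_contour(e$points, paste("slice", e$slice_index, "lumen"))
  pts <- do.call(rbind, lapply(lum, `[[`, "points"))
  zc <- vapply(lum, `[[`, numeric(1), "z_mm")
  lo <- c(apply(pts, 2, min) - 2 * spacing_mm[1:2], min(zc))
  hi <- c(apply(pts, 2, max) + 2 * spacing_mm[1:2], max(zc))
  nx <- as.integer(ceiling((hi[1] - lo[1]) / spacing_mm[1])) + 1L
  ny <- as.integer(ceiling((hi[2] - lo[2]) / spacing_mm[2])) + 1L
  nz <- as.integer(floor((hi[3] - lo[3]) / spacing_mm[3] + 1e-9)) + 1L
  gx <- lo[1] + (seq_len(nx) - 1) * spacing_mm[1]
  gy <- lo[2] + (seq_len(ny) - 1) * spacing_mm[2]
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    zk <- lo[3] + (k - 1) * spacing_mm[3]
    dz <- abs(zc - zk)
    j <- which.min(dz)
    if (dz[j] < spacing_mm[3] / 2 - 1e-12) {
      inside <- point_in_polygon(rep(gx, times = ny), rep(gy, each = nx),
                                 lum[[j]]$points)
      vox[, , k] <- matrix(as.numeric(inside), nx, ny)
    }
  }
  volume_image(vox, spacing_mm, lo)
}
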