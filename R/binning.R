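# Radial binning: projection of the WSS surface field onto histology sections
# through the +/-0.3 mm axial window, subdivision into 8 radial sectors about
# the centerline point, per-bin WSS statistics, plaque thickness and component
# areas.

#' Projection parameters
#'
#' @param axial_halfwidth_mm half-width of the axial averaging window about a
#'   section's z (default 0.3 mm, the in vivo axial resolution / 2 slice).
#' @param n_bins number of radial sectors (default 8).
#' @param bin_zero_deg direction of bin 0's lower edge, degrees counter-
#'   clockwise from the +x axis (default 0).
#' @return parameter list of class `projection_params`.
#' @export
projection_params <- function(axial_halfwidth_mm = 0.3, n_bins = 8L,
                              bin_zero_deg = 0) {
  if (axial_halfwidth_mm <= 0) stop("axial_halfwidth_mm must be > 0")
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(axial_halfwidth_mm = axial_halfwidth_mm,
                 n_bins = as.integer(n_bins), bin_zero_deg = bin_zero_deg),
            class = "projection_params")
}

#' Assign points to radial bins
#'
#' The bin index is `floor(n_bins * theta / 2pi)` where `theta` is the
#' counter-clockwise angle of `point - centerpoint` from the bin-zero
#' direction, normalized to `[0, 2pi)`. Wedges are half-open: a point exactly
#' on a boundary belongs to the higher-index wedge whose lower edge it lies
#' on.
#'
#' @param points n x 2 matrix (or length-2 vector), mm.
#' @param centerpoint length-2 numeric, mm.
#' @param params a [projection_params()].
#' @return integer vector of bin indices in `0 .. n_bins - 1`.
#' @export
assign_radial_bin <- function(points, centerpoint, params = projection_params()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  dx <- points[, 1] - centerpoint[1]; dy <- points[, 2] - centerpoint[2]
  if (any(dx == 0 & dy == 0))
    stop("point coincides with the centerpoint; angle undefined")
  theta <- atan2(dy, dx) - params$bin_zero_deg * pi / 180
  theta <- theta %% (2 * pi)
  bin <- as.integer(floor(params$n_bins * theta / (2 * pi)))
  bin[bin == params$n_bins] <- 0L  # guard against theta == 2*pi round-off
  bin
}

#' Project the WSS surface onto one section's radial bins
#'
#' Selects all mesh vertices whose z lies within the axial window
#' `|z_vertex - z_mm| <= axial_halfwidth_mm`, assigns each to a radial bin by
#' its in-plane position relative to the centerpoint (nearest-neighbour value
#' pick-up: every vertex keeps its own scalar), and reduces each bin to
#' mean/min/max. Bins without vertices are empty (`NA`), never zero.
#'
#' @param field a [surface_field()] already transformed into the en-face
#'   domain.
#' @param z_mm section z location.
#' @param centerpoint length-2 bin origin (centerline point of this section).
#' @param params a [projection_params()].
#' @return data.frame with `bin_index`, `mean_wss_pa`, `min_wss_pa`,
#'   `max_wss_pa`, `n_vertices`, `empty`.
#' @export
project_wss_to_section <- function(field, z_mm, centerpoint,
                                   params = projection_params()) {
  tol <- 1e-9
  sel <- abs(field$vertices[, 3] - z_mm) <= params$axial_halfwidth_mm + tol
  if (!any(sel))
    stop(sprintf("no mesh vertices in the axial window [%g, %g] mm",
                 z_mm - params$axial_halfwidth_mm, z_mm + params$axial_halfwidth_mm))
  pts <- field$vertices[sel, 1:2, drop = FALSE]
  wss <- field$wss_pa[sel]
  bins <- assign_radial_bin(pts, centerpoint, params)
  out <- data.frame(bin_index = seq_len(params$n_bins) - 1L,
                    mean_wss_pa = NA_real_, min_wss_pa = NA_real_,
                    max_wss_pa = NA_real_, n_vertices = 0L, empty = TRUE)
  for (b in unique(bins)) {
    v <- wss[bins == b]
    row <- b + 1L
    out$mean_wss_pa[row] <- mean(v)
    out$min_wss_pa[row] <- min(v)
    out$max_wss_pa[row] <- max(v)
    out$n_vertices[row] <- length(v)
    out$empty[row] <- FALSE
  }
  out
}

#' Per-bin plaque thickness
#'
#' Plaque thickness of a bin is the mean shortest Euclidean distance from
#' densely resampled lumen boundary points to the media boundary, over the
#' lumen points falling in that radial bin.
#'
#' @param lumen,media closed contours (media must enclose the lumen; the
#'   degenerate media == lumen case yields zero thickness).
#' @param centerpoint bin origin.
#' @param params a [projection_params()].
#' @param sample_spacing_mm lumen resampling arc spacing (<= 0.05 mm).
#' @return data.frame with `bin_index`, `thickness_mm`, `n_samples`.
#' @export
plaque_thickness_per_bin <- function(lumen, media, centerpoint,
                                     params = projection_params(),
                                     sample_spacing_mm = 0.05) {
  lumen <- validate_contour(lumen, "lumen", check_simple = FALSE)
  media <- validate_contour(media, "media", check_simple = FALSE)
  samples <- resample_contour(lumen, sample_spacing_mm)
  sd <- polygon_signed_distance(samples[, 1], samples[, 2], media)
  if (any(sd > 1e-6))
    stop("lumen and media contours intersect (lumen not enclosed by media)")
  d <- abs(sd)
  bins <- assign_radial_bin(samples, centerpoint, params)
  out <- data.frame(bin_index = seq_len(params$n_bins) - 1L,
                    thickness_mm = NA_real_, n_samples = 0L)
  for (b in unique(bins)) {
    row <- b + 1L
    out$thickness_mm[row] <- mean(d[bins == b])
    out$n_samples[row] <- sum(bins == b)
  }
  out
}

#' Area enclosed by a contour
#'
#' Shoelace polygon area, positive regardless of vertex orientation; used to
#' express plaque component sizes in mm^2.
#' @param contour simple closed contour.
#' @return area in mm^2.
#' @export
component_area <- function(contour) {
  contour <- validate_contour(contour, "component contour")
  abs(polygon_signed_area(contour))
}

#' Assemble the per-bin table for a set of processed sections
#'
#' @param sections list of lists, each with `specimen_id`, `slice_index`,
#'   `z_mm`, `wss` (output of [project_wss_to_section()]) and optionally
#'   `thickness` (output of [plaque_thickness_per_bin()]); all produced with
#'   the same [projection_params()].
#' @return a [bin_table()] with `sum(sections) * n_bins` rows; all bins start
#'   unflagged/included (see [apply_exclusions()]).
#' @export
build_bin_table <- function(sections) {
  if (!length(sections)) {
    df <- data.frame(specimen_id = character(), slice_index = integer(),
                     z_mm = numeric(), bin_index = integer(),
                     mean_wss_pa = numeric(), min_wss_pa = numeric(),
                     max_wss_pa = numeric(), plaque_thickness_mm = numeric(),
                     error_flags = character(), included = logical())
    return(bin_table(df))
  }
  rows <- lapply(sections, function(s) {
    th <- if (!is.null(s$thickness)) s$thickness$thickness_mm else NA_real_
    data.frame(specimen_id = s$specimen_id, slice_index = as.integer(s$slice_index),
               z_mm = s$z_mm, bin_index = s$wss$bin_index,
               mean_wss_pa = s$wss$mean_wss_pa, min_wss_pa = s$wss$min_wss_pa,
               max_wss_pa = s$wss$max_wss_pa, plaque_thickness_mm = th,
               error_flags = "", included = TRUE)
  })
  bin_table(do.call(rbind, rows))
}
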