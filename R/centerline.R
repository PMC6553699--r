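# Vessel centerline: per-slice maximal inscribed circles (the slice
# restriction of the maximally-inscribed-sphere criterion) plus moving-average
# smoothing along z. Candidate centers come from the Voronoi diagram of the
# densified contour (medial-axis vertices), refined by direct maximization of
# the distance-to-boundary function.

#' Maximal inscribed circle of a closed contour
#'
#' Finds the interior point maximizing the distance to the contour. Candidates
#' are interior Voronoi vertices of the densely resampled boundary (the
#' discrete medial axis); the best candidate is polished with Nelder-Mead on
#' the exact distance-to-boundary function (negated outside).
#'
#' @param contour closed contour (n x 2 matrix, mm).
#' @param boundary_spacing_mm resampling density for the Voronoi seed points.
#' @return list with `center` (length-2) and `radius_mm`.
#' @export
max_inscribed_circle_center <- function(contour, boundary_spacing_mm = 0.2) {
  poly <- validate_contour(contour, "lumen contour", check_simple = FALSE)
  bnd <- resample_contour(poly, boundary_spacing_mm)
  # deterministic micro-jitter: exactly co-circular seeds degenerate the
  # Delaunay triangulation underlying the Voronoi diagram
  jit <- boundary_spacing_mm * 1e-5
  bnd <- bnd + jit * cbind(sin(7.1 * seq_len(nrow(bnd))), cos(11.3 * seq_len(nrow(bnd))))
  # interior Voronoi vertices of the boundary samples (discrete medial axis);
  # fall back to a coarse interior grid if the triangulation still fails
  vor <- tryCatch({
    utils::capture.output(v <- suppressMessages(
      deldir::deldir(bnd[, 1], bnd[, 2], suppressMsge = TRUE)))
    v
  }, error = function(e) NULL)
  if (!is.null(vor)) {
    vx <- c(vor$dirsgs$x1, vor$dirsgs$x2); vy <- c(vor$dirsgs$y1, vor$dirsgs$y2)
  } else {
    gx <- seq(min(poly[, 1]), max(poly[, 1]), length.out = 40)
    gy <- seq(min(poly[, 2]), max(poly[, 2]), length.out = 40)
    vx <- rep(gx, times = 40); vy <- rep(gy, each = 40)
  }
  keep <- point_in_polygon(vx, vy, poly)
  vx <- vx[keep]; vy <- vy[keep]
  objective <- function(p) {
    d <- dist_to_polygon(p[1], p[2], poly)
    if (!point_in_polygon(p[1], p[2], poly)) -d else d
  }
  if (length(vx)) {
    d <- dist_to_polygon(vx, vy, poly)
    start <- c(vx[which.max(d)], vy[which.max(d)])
  } else start <- colMeans(poly)
  opt <- stats::optim(start, function(p) -objective(p), method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  r <- -opt$value
  if (r <= 0) stop("degenerate contour: no interior point found")
  list(center = as.numeric(opt$par), radius_mm = r)
}

#' Per-section lumen centerline
#'
#' Computes one maximal-inscribed-circle centerpoint per section and smooths
#' the in-plane coordinates with a centered moving average along z (end slices
#' where the full window does not fit keep their raw centers). If smoothing
#' pushes a point outside its lumen contour, the unsmoothed point is kept for
#' that slice.
#'
#' @param lumen_contours a [contour_stack()] with a lumen contour on every
#'   slice (>= 2 slices).
#' @param smoothing_window odd window length in slices (1 = no smoothing;
#'   default 3).
#' @return data.frame with `slice_index`, `x_mm`, `y_mm`, `z_mm`, `radius_mm`,
#'   class `centerline`.
#' @export
compute_centerline <- function(lumen_contours, smoothing_window = 3) {
  slices <- stack_slices(lumen_contours)
  if (length(slices) < 2) stop("centerline needs at least 2 sections")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1)
    stop("smoothing_window must be a positive odd integer")
  raw <- lapply(slices, function(s) {
    ct <- stack_get(lumen_contours, s, "lumen")
    if (is.null(ct)) stop("slice ", s, " is missing a lumen contour")
    mic <- max_inscribed_circle_center(ct)
    c(mic$center, mic$radius_mm)
  })
  raw <- do.call(rbind, raw)
  n <- length(slices); half <- (smoothing_window - 1) / 2
  sm <- raw[, 1:2, drop = FALSE]
  if (half > 0) {
    # smooth only where the full centered window fits; end slices keep their
    # raw centers (truncated windows would bias a drifting centerline)
    for (i in seq_len(n)) {
      if (i - half < 1 || i + half > n) next
      win <- (i - half):(i + half)
      sm[i, ] <- colMeans(raw[win, 1:2, drop = FALSE])
    }
    for (i in seq_len(n)) {
      ct <- stack_get(lumen_contours, slices[i], "lumen")
      if (!point_in_polygon(sm[i, 1], sm[i, 2], ct)) sm[i, ] <- raw[i, 1:2]
    }
  }
  out <- data.frame(slice_index = slices, x_mm = sm[, 1], y_mm = sm[, 2],
                    z_mm = vapply(slices, function(s) stack_z(lumen_contours, s),
                                  numeric(1)),
                    radius_mm = raw[, 3])
  class(out) <- c("centerline", "data.frame")
  out
}

#' Write / read a centerline CSV
#' @param centerline data.frame from [compute_centerline()].
#' @param path CSV path.
#' @export
write_centerline <- function(centerline, path) .write_csv(as.data.frame(centerline), path)

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("centerline file does not exist: ", path)
  out <- utils::read.csv(path)
  class(out) <- c("centerline", "data.frame")
  out
}
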