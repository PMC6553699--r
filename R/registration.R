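# Registration: landmark-based similarity fitting (Umeyama closed form),
# rigid en-face stack assembly, contour-driven 2D B-spline free-form
# deformation optimized by stochastic gradient descent on a rasterized
# signed-distance metric, and volume resampling.

#' Least-squares similarity transform from point correspondences
#'
#' Closed-form 2D Umeyama fit: the similarity (rotation, isotropic scale,
#' translation) minimizing `sum ||T(moving_i) - fixed_i||^2`. With
#' `allow_scale = FALSE` the fit is rigid (scale fixed at 1), as used for
#' en-face stack assembly where all photos share one calibrated pixel size.
#'
#' @param fixed_points,moving_points index-matched n x 2 matrices (n >= 2).
#' @param allow_scale estimate isotropic scale (default TRUE).
#' @return a [similarity_transform()] with attribute `rms_mm` (root mean
#'   square residual).
#' @export
fit_similarity_from_landmarks <- function(fixed_points, moving_points,
                                          allow_scale = TRUE) {
  fixed_points <- as.matrix(fixed_points); moving_points <- as.matrix(moving_points)
  if (nrow(fixed_points) != nrow(moving_points))
    stop("fixed and moving point lists must have equal length")
  n <- nrow(fixed_points)
  if (n < 2) stop("need at least 2 point pairs for a 2D similarity fit")
  pm <- colMeans(moving_points); qm <- colMeans(fixed_points)
  X <- sweep(moving_points, 2, pm); Y <- sweep(fixed_points, 2, qm)
  ssx <- sum(X^2)
  if (ssx < 1e-18) stop("degenerate configuration: moving points are coincident")
  a <- sum(X * Y)                                   # sum x.y
  b <- sum(X[, 1] * Y[, 2] - X[, 2] * Y[, 1])       # sum cross(x, y)
  theta <- atan2(b, a)
  s <- if (allow_scale) sqrt(a^2 + b^2) / ssx else 1
  if (allow_scale && s < 1e-12)
    stop("degenerate configuration: fixed points are coincident")
  rot_deg <- theta * 180 / pi
  trans <- qm - s * as.numeric(.rot2(rot_deg) %*% pm)
  tf <- similarity_transform(rot_deg, s, trans)
  res <- apply_transform(tf, moving_points) - fixed_points
  attr(tf, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Assemble the en-face photo stack by landmark-based rigid registration
#'
#' Photo `k` is registered to photo `k - 1` with a rigid (rotation +
#' translation, scale 1) landmark fit over their shared labels; transforms are
#' accumulated so every photo lives in photo 1's frame, and a 3D grayscale
#' volume is resampled at a common pixel size.
#'
#' @param photos list of [planar_image()]s, ordered caudal to cranial; each
#'   adjacent pair must share at least two landmark labels.
#' @param pixel_size_mm output in-plane pixel size (defaults to the first
#'   photo's).
#' @return list with `volume` (a [volume_image()]) and `transforms` (one
#'   accumulated [similarity_transform()] per photo, photo-frame -> stack
#'   frame; the first is the identity).
#' @export
stack_enface_photos <- function(photos, pixel_size_mm = NULL) {
  stopifnot(length(photos) >= 1)
  if (is.null(pixel_size_mm)) pixel_size_mm <- photos[[1]]$pixel_size_mm
  acc <- vector("list", length(photos))
  acc[[1]] <- similarity_transform(0, 1, c(0, 0))
  if (length(photos) > 1) {
    for (k in 2:length(photos)) {
      prev <- photos[[k - 1]]$landmarks; cur <- photos[[k]]$landmarks
      shared <- intersect(prev$label, cur$label)
      if (length(shared) < 2)
        stop("photos ", k - 1, " and ", k, " share fewer than 2 landmark labels")
      fixed <- as.matrix(prev[match(shared, prev$label), c("x_mm", "y_mm")])
      moving <- as.matrix(cur[match(shared, cur$label), c("x_mm", "y_mm")])
      step <- fit_similarity_from_landmarks(fixed, moving, allow_scale = FALSE)
      prev_acc <- acc[[k - 1]]
      # accumulate: photo k -> photo k-1 -> stack frame
      rot <- prev_acc$rotation_deg + step$rotation_deg
      trans <- apply_transform(prev_acc, matrix(step$translation_mm, 1))
      acc[[k]] <- similarity_transform(rot, 1, as.numeric(trans))
    }
  }
  # common output grid covering all transformed photo footprints
  corners <- do.call(rbind, lapply(seq_along(photos), function(k) {
    d <- dim(photos[[k]]$pixels); px <- photos[[k]]$pixel_size_mm
    cs <- rbind(c(0, 0), c(d[2] * px, 0), c(0, d[1] * px), c(d[2] * px, d[1] * px))
    apply_transform(acc[[k]], cs)
  }))
  lo <- apply(corners, 2, min); hi <- apply(corners, 2, max)
  nx <- as.integer(ceiling((hi[1] - lo[1]) / pixel_size_mm))
  ny <- as.integer(ceiling((hi[2] - lo[2]) / pixel_size_mm))
  gx <- lo[1] + (seq_len(nx) - 0.5) * pixel_size_mm
  gy <- lo[2] + (seq_len(ny) - 0.5) * pixel_size_mm
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  vox <- array(0, dim = c(nx, ny, length(photos)))
  for (k in seq_along(photos)) {
    src <- apply_transform(invert_transform(acc[[k]]), grid)
    vox[, , k] <- matrix(.bilinear_image(photos[[k]]$pixels, src,
                                         photos[[k]]$pixel_size_mm), nx, ny)
  }
  zs <- vapply(photos, `[[`, numeric(1), "z_mm")
  dz <- if (length(zs) > 1) stats::median(diff(zs)) else 1
  vol <- volume_image(vox, c(pixel_size_mm, pixel_size_mm, dz),
                      c(gx[1], gy[1], zs[1]))
  list(volume = vol, transforms = acc)
}

# bilinear sample of an image matrix (rows = y, cols = x, pixel centers at
# (c - 0.5) * px) at world points; outside -> 0
.bilinear_image <- function(pixels, pts, px) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  cx <- pts[, 1] / px + 0.5; cy <- pts[, 2] / px + 0.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- pixels[cbind(r[ok], c[ok])]
    out
  }
  v00 <- get(y0, x0); v10 <- get(y0, x0 + 1)
  v01 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# --- signed distance maps ----------------------------------------------------

# Rasterize the signed distance (negative inside) to a set of contours on a
# regular grid. Returns list(gx, gy, map, pixel) with map[nx, ny].
.distance_map <- function(contours, lo, hi, pixel_mm) {
  gx <- seq(lo[1], hi[1], by = pixel_mm)
  gy <- seq(lo[2], hi[2], by = pixel_mm)
  pts_x <- rep(gx, times = length(gy)); pts_y <- rep(gy, each = length(gx))
  # unsigned min distance over all contours: the metric only needs a smooth
  # field whose zero level set is the union of the fixed contours
  map <- rep(Inf, length(pts_x))
  for (ct in contours) map <- pmin(map, dist_to_polygon(pts_x, pts_y, ct))
  list(gx = gx, gy = gy, map = matrix(map, length(gx), length(gy)),
       pixel = pixel_mm, lo = lo)
}

# bilinear lookup in a distance map (clamped at borders)
.dm_value <- function(dm, pts) {
  tx <- (pts[, 1] - dm$gx[1]) / dm$pixel + 1
  ty <- (pts[, 2] - dm$gy[1]) / dm$pixel + 1
  nx <- length(dm$gx); ny <- length(dm$gy)
  tx <- pmin(pmax(tx, 1), nx - 1e-9); ty <- pmin(pmax(ty, 1), ny - 1e-9)
  x0 <- pmin(floor(tx), nx - 1); y0 <- pmin(floor(ty), ny - 1)
  fx <- tx - x0; fy <- ty - y0
  m <- dm$map
  v00 <- m[cbind(x0, y0)]; v10 <- m[cbind(x0 + 1, y0)]
  v01 <- m[cbind(x0, y0 + 1)]; v11 <- m[cbind(x0 + 1, y0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# central-difference gradient of the map at points
.dm_grad <- function(dm, pts) {
  h <- dm$pixel
  gx <- (.dm_value(dm, cbind(pts[, 1] + h, pts[, 2])) -
         .dm_value(dm, cbind(pts[, 1] - h, pts[, 2]))) / (2 * h)
  gy <- (.dm_value(dm, cbind(pts[, 1], pts[, 2] + h)) -
         .dm_value(dm, cbind(pts[, 1], pts[, 2] - h))) / (2 * h)
  cbind(gx, gy)
}

#' Default B-spline registration parameters
#'
#' @param grid_spacing_mm control-point spacing (mm).
#' @param iterations gradient-descent iterations.
#' @param pixel_mm distance-map raster resolution.
#' @param seed RNG seed for the stochastic point sampling.
#' @param sample_size points drawn per iteration.
#' @param step0_mm initial step length (max control-point move on step 1).
#' @return parameter list for [register_contours_bspline()].
#' @export
bspline_params <- function(grid_spacing_mm = 5, iterations = 500, pixel_mm = 0.1,
                           seed = 1L, sample_size = 120, step0_mm = 0.15) {
  list(grid_spacing_mm = grid_spacing_mm, iterations = iterations,
       pixel_mm = pixel_mm, seed = seed, sample_size = sample_size,
       step0_mm = step0_mm)
}

# Register the moving contours of one slice onto the fixed ones. Returns a
# bspline_transform (moving -> fixed domain) with attr "trace" (accepted
# metric values, non-increasing) and attrs "metric_before"/"metric_after".
.register_slice_bspline <- function(fixed_contours, moving_contours, params) {
  all_pts <- do.call(rbind, c(fixed_contours, moving_contours))
  lo <- apply(all_pts, 2, min) - 3; hi <- apply(all_pts, 2, max) + 3
  if (length(fixed_contours) && length(moving_contours)) {
    fb <- do.call(rbind, fixed_contours); mb <- do.call(rbind, moving_contours)
    overlap <- all(apply(mb, 2, min) <= apply(fb, 2, max) + 1e-9) &&
      all(apply(fb, 2, min) <= apply(mb, 2, max) + 1e-9)
    if (!overlap)
      stop("contour bounding boxes do not overlap; apply rigid pre-registration first")
  }
  dm <- .distance_map(fixed_contours, lo, hi, params$pixel_mm)
  samples <- do.call(rbind, lapply(moving_contours, resample_contour,
                                   spacing_mm = 0.2))
  grid <- bspline_grid_for_bbox(lo, hi, params$grid_spacing_mm)
  shp <- grid$shape
  cx <- matrix(0, shp[1], shp[2]); cy <- matrix(0, shp[1], shp[2])
  mk_tf <- function(cx, cy) bspline_transform(grid$origin_mm, grid$spacing_mm,
                                              shp, cx, cy)
  metric <- function(cx, cy)
    mean(.dm_value(dm, apply_transform(mk_tf(cx, cy), samples))^2)
  # basis weights per sample are fixed (the transform is parameterized over
  # the moving/fixed shared in-plane frame)
  tx <- (samples[, 1] - grid$origin_mm[1]) / grid$spacing_mm[1]
  ty <- (samples[, 2] - grid$origin_mm[2]) / grid$spacing_mm[2]
  lx <- floor(tx); ly <- floor(ty)
  wx <- .bspline_w(tx - lx); wy <- .bspline_w(ty - ly)
  m0 <- metric(cx, cy)
  best <- list(cx = cx, cy = cy, m = m0)
  trace <- m0
  n <- nrow(samples)
  rng <- .mk_rng(params$seed)
  a0 <- NULL
  for (k in seq_len(params$iterations)) {
    idx <- if (n > params$sample_size) rng$sample_int(n, params$sample_size) else seq_len(n)
    p <- apply_transform(mk_tf(cx, cy), samples[idx, , drop = FALSE])
    r <- .dm_value(dm, p)              # residuals (distance to fixed contours)
    g <- .dm_grad(dm, p)
    gx_acc <- matrix(0, shp[1], shp[2]); gy_acc <- matrix(0, shp[1], shp[2])
    for (a in 0:3) for (b in 0:3) {
      w <- wx[idx, a + 1] * wy[idx, b + 1] * 2 * r / length(idx)
      lin <- (ly[idx] + b - 1) * shp[1] + lx[idx] + a  # 1-based linear index
      upd <- rowsum(cbind(w * g[, 1], w * g[, 2]), group = lin)
      at <- as.integer(rownames(upd))
      gx_acc[at] <- gx_acc[at] + upd[, 1]
      gy_acc[at] <- gy_acc[at] + upd[, 2]
    }
    gmax <- max(abs(c(gx_acc, gy_acc)), 1e-12)
    if (is.null(a0)) a0 <- params$step0_mm / gmax
    step <- a0 / (1 + k / 50)^0.602
    cx <- cx - step * gx_acc
    cy <- cy - step * gy_acc
    m <- metric(cx, cy)
    if (m < best$m) { best <- list(cx = cx, cy = cy, m = m); trace <- c(trace, m) }
  }
  tf <- mk_tf(best$cx, best$cy)
  attr(tf, "trace") <- trace
  attr(tf, "metric_before") <- m0
  attr(tf, "metric_after") <- best$m
  tf
}

# deterministic sampler independent of the global RNG state
.mk_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  list(sample_int = function(n, size) {
    # linear congruential draw; adequate for subsampling optimisation points
    out <- integer(size)
    s <- env$state
    for (i in seq_len(size)) {
      s <- (1103515245 * (s %% 65536) + 12345) %% 2147483647
      out[i] <- (s %% n) + 1L
    }
    env$state <- s
    out
  })
}

#' Contour-driven non-rigid B-spline registration
#'
#' For every slice present in both stacks, fits a 2D cubic B-spline free-form
#' deformation (moving -> fixed domain) by minimizing the mean-squares metric
#' on the fixed stack's rasterized contour distance map, evaluated at the
#' transformed moving contour points, with stochastic gradient descent and
#' best-iterate selection (so the reported metric trace is non-increasing over
#' accepted iterations). The moving stack should already be rigidly
#' pre-registered to the fixed stack.
#'
#' @param fixed,moving [contour_stack()]s with matching structures on matching
#'   slices.
#' @param params see [bspline_params()].
#' @return named list (by slice index) of `bspline_transform`s, each carrying
#'   attributes `trace`, `metric_before`, `metric_after`.
#' @export
register_contours_bspline <- function(fixed, moving, params = bspline_params()) {
  slices <- intersect(stack_slices(fixed), stack_slices(moving))
  if (!length(slices)) stop("no common slices between fixed and moving stacks")
  out <- list()
  for (s in slices) {
    structs <- intersect(
      vapply(Filter(function(e) e$slice_index == s, fixed$entries), `[[`, character(1), "structure"),
      vapply(Filter(function(e) e$slice_index == s, moving$entries), `[[`, character(1), "structure"))
    if (!length(structs)) stop("slice ", s, ": no common structures to register")
    fc <- lapply(structs, function(st) stack_get(fixed, s, st))
    mc <- lapply(structs, function(st) stack_get(moving, s, st))
    out[[as.character(s)]] <- .register_slice_bspline(fc, mc, params)
  }
  out
}

#' Resample a volume through a spatial transform
#'
#' The transform maps target-grid world coordinates into the source volume's
#' domain; intensities are linearly interpolated and out-of-domain voxels take
#' the fill value.
#'
#' @param volume source [volume_image()].
#' @param transform either a `wss_transform` applied in-plane (x, y; z passes
#'   through), a function mapping n x 3 world points to n x 3 source points,
#'   or `NULL` for identity.
#' @param target_grid list with `dims` (length 3), `spacing_mm`, `origin_mm`;
#'   defaults to the source grid.
#' @param fill out-of-domain value (default 0).
#' @return resampled [volume_image()] on the target grid.
#' @export
resample_volume <- function(volume, transform = NULL, target_grid = NULL, fill = 0) {
  if (is.null(target_grid))
    target_grid <- list(dims = dim(volume$voxels), spacing_mm = volume$spacing_mm,
                        origin_mm = volume$origin_mm)
  d <- as.integer(target_grid$dims)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  world <- sweep(sweep(idx, 2, target_grid$spacing_mm, `*`), 2,
                 target_grid$origin_mm, `+`)
  src <- if (is.null(transform)) world
  else if (is.function(transform)) transform(world)
  else cbind(apply_transform(transform, world[, 1:2, drop = FALSE]), world[, 3])
  cont <- sweep(sweep(src, 2, volume$origin_mm, `-`), 2, volume$spacing_mm, `/`)
  sd <- dim(volume$voxels)
  i0 <- floor(cont)
  f <- cont - i0
  vals <- rep(fill, nrow(cont))
  vox <- volume$voxels
  acc <- numeric(nrow(cont))
  ok <- i0[, 1] >= -1 & i0[, 1] <= sd[1] - 1 & i0[, 2] >= -1 & i0[, 2] <= sd[2] - 1 &
    i0[, 3] >= -1 & i0[, 3] <= sd[3] - 1
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) * (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    inb <- ii >= 0 & ii < sd[1] & jj >= 0 & jj < sd[2] & kk >= 0 & kk < sd[3]
    v <- numeric(nrow(cont))
    v[inb] <- vox[cbind(ii[inb] + 1, jj[inb] + 1, kk[inb] + 1)]
    v[!inb] <- fill
    acc <- acc + w * v
  }
  vals[ok] <- acc[ok]
  volume_image(array(vals, d), target_grid$spacing_mm, target_grid$origin_mm)
}
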