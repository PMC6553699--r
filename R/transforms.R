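# In-plane spatial transforms and their composition. All transforms map 2D
# points (n x 2 matrices, mm) and carry optional source/target domain labels
# so chains can be checked for consistency.

#' Similarity transform (rotation + isotropic scale + translation)
#'
#' Maps a point `x` to `scale * R(rotation_deg) %*% x + translation_mm`.
#'
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param scale strictly positive isotropic scale factor.
#' @param translation_mm length-2 numeric, mm.
#' @param source,target optional domain labels for chain validation.
#' @return object of class `c("similarity_transform", "wss_transform")`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1,
                                 translation_mm = c(0, 0),
                                 source = NULL, target = NULL) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  structure(list(rotation_deg = as.numeric(rotation_deg), scale = as.numeric(scale),
                 translation_mm = as.numeric(translation_mm),
                 source = source, target = target),
            class = c("similarity_transform", "wss_transform"))
}

.rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Cubic B-spline free-form deformation of the plane
#'
#' Displacement at `p` is the tensor-product cubic B-spline interpolation of
#' per-control-point displacement coefficients; the transform maps `p` to
#' `p + u(p)`. The control grid must cover the working domain plus the one-
#' spacing support margin; [bspline_grid_for_bbox()] builds a conforming grid.
#'
#' @param origin_mm length-2 position of control point (0, 0).
#' @param spacing_mm length-2 positive grid spacing.
#' @param shape length-2 integer control-grid size (>= 4 per dimension).
#' @param coef_x,coef_y `shape[1] x shape[2]` matrices of displacement
#'   coefficients, mm.
#' @inheritParams similarity_transform
#' @return object of class `c("bspline_transform", "wss_transform")`.
#' @export
bspline_transform <- function(origin_mm, spacing_mm, shape, coef_x, coef_y,
                              source = NULL, target = NULL) {
  shape <- as.integer(shape)
  if (any(shape < 4)) stop("control grid needs at least 4 points per dimension")
  if (any(spacing_mm <= 0)) stop("grid spacing must be positive")
  coef_x <- as.matrix(coef_x); coef_y <- as.matrix(coef_y)
  if (!all(dim(coef_x) == shape) || !all(dim(coef_y) == shape))
    stop("coefficient matrices must match control grid shape")
  structure(list(origin_mm = as.numeric(origin_mm), spacing_mm = as.numeric(spacing_mm),
                 shape = shape, coef_x = coef_x, coef_y = coef_y,
                 source = source, target = target),
            class = c("bspline_transform", "wss_transform"))
}

#' Control grid covering a bounding box (plus B-spline support margin)
#' @param lo,hi length-2 numeric corners of the working domain, mm.
#' @param spacing_mm scalar or length-2 grid spacing, mm.
#' @return list with `origin_mm`, `spacing_mm`, `shape`.
#' @export
bspline_grid_for_bbox <- function(lo, hi, spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2)
  origin <- lo - 1.5 * spacing_mm
  shape <- as.integer(ceiling((hi - lo) / spacing_mm)) + 4L
  list(origin_mm = origin, spacing_mm = spacing_mm, shape = shape)
}

# Cubic B-spline basis weights for fractional offsets f in [0, 1): columns are
# the weights of control points l-1, l, l+1, l+2 where l = floor(t).
.bspline_w <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  cbind((1 - 3 * f + 3 * f2 - f3) / 6,
        (4 - 6 * f2 + 3 * f3) / 6,
        (1 + 3 * f + 3 * f2 - 3 * f3) / 6,
        f3 / 6)
}

# Displacement field of a bspline_transform at points (n x 2).
bspline_displacement <- function(tf, pts) {
  tx <- (pts[, 1] - tf$origin_mm[1]) / tf$spacing_mm[1]
  ty <- (pts[, 2] - tf$origin_mm[2]) / tf$spacing_mm[2]
  lx <- floor(tx); ly <- floor(ty)
  if (any(lx < 1) || any(lx > tf$shape[1] - 3) || any(ly < 1) || any(ly > tf$shape[2] - 3))
    stop("point outside B-spline control grid support; enlarge the grid")
  wx <- .bspline_w(tx - lx); wy <- .bspline_w(ty - ly)
  ux <- numeric(nrow(pts)); uy <- numeric(nrow(pts))
  for (a in 0:3) {
    ia <- lx + a  # R index of 0-based control point (lx - 1 + a)
    for (b in 0:3) {
      ib <- ly + b
      w <- wx[, a + 1] * wy[, b + 1]
      idx <- cbind(ia, ib)
      ux <- ux + w * tf$coef_x[idx]
      uy <- uy + w * tf$coef_y[idx]
    }
  }
  cbind(ux, uy, deparse.level = 0)
}

#' Apply a transform to 2D points
#' @param tf a `wss_transform` (similarity, B-spline, chain or inverse).
#' @param pts n x 2 matrix of points, mm.
#' @return n x 2 matrix of transformed points.
#' @export
apply_transform <- function(tf, pts) UseMethod("apply_transform")

#' @export
apply_transform.similarity_transform <- function(tf, pts) {
  pts <- as.matrix(pts)
  sweep(tf$scale * pts %*% t(.rot2(tf$rotation_deg)), 2, tf$translation_mm, `+`)
}

#' @export
apply_transform.bspline_transform <- function(tf, pts) {
  pts <- as.matrix(pts)
  pts + bspline_displacement(tf, pts)
}

#' @export
apply_transform.inverse_bspline <- function(tf, pts) {
  # fixed-point inversion x <- y - u(x); converges for sub-unit-Jacobian warps
  pts <- as.matrix(pts)
  x <- pts
  for (k in 1:60) {
    x_new <- pts - bspline_displacement(tf$forward, x)
    if (max(abs(x_new - x)) < 1e-12) { x <- x_new; break }
    x <- x_new
  }
  x
}

#' @export
apply_transform.transform_chain <- function(tf, pts) {
  for (t1 in tf$transforms) pts <- apply_transform(t1, pts)
  pts
}

#' @export
apply_transform.identity_transform <- function(tf, pts) as.matrix(pts)

#' The identity transform
#' @inheritParams similarity_transform
#' @export
identity_transform <- function(source = NULL, target = NULL)
  structure(list(source = source, target = target),
            class = c("identity_transform", "wss_transform"))

#' Invert a transform
#'
#' Similarity inverses are closed-form; B-spline inverses are evaluated by
#' fixed-point iteration at application time; chains invert element-wise in
#' reverse order.
#' @param tf a `wss_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(tf) UseMethod("invert_transform")

#' @export
invert_transform.similarity_transform <- function(tf) {
  Rinv <- .rot2(-tf$rotation_deg)
  t_inv <- -as.numeric(Rinv %*% tf$translation_mm) / tf$scale
  similarity_transform(-tf$rotation_deg, 1 / tf$scale, t_inv,
                       source = tf$target, target = tf$source)
}

#' @export
invert_transform.bspline_transform <- function(tf)
  structure(list(forward = tf, source = tf$target, target = tf$source),
            class = c("inverse_bspline", "wss_transform"))

#' @export
invert_transform.inverse_bspline <- function(tf) tf$forward

#' @export
invert_transform.identity_transform <- function(tf)
  identity_transform(source = tf$target, target = tf$source)

#' @export
invert_transform.transform_chain <- function(tf)
  transform_chain(rev(lapply(tf$transforms, invert_transform)))

#' Ordered composition of transforms
#'
#' `transform_chain(list(a, b))` applies `a` first, then `b`. Adjacent domain
#' labels, where present, must match (`target` of step i equals `source` of
#' step i + 1).
#' @param transforms list of `wss_transform` objects (chains are flattened).
#' @return object of class `c("transform_chain", "wss_transform")`.
#' @export
transform_chain <- function(transforms) {
  flat <- list()
  for (t1 in transforms) {
    if (inherits(t1, "transform_chain")) flat <- c(flat, t1$transforms)
    else flat <- c(flat, list(t1))
  }
  if (length(flat) > 1) {
    for (i in seq_len(length(flat) - 1)) {
      tg <- flat[[i]]$target; sr <- flat[[i + 1]]$source
      if (!is.null(tg) && !is.null(sr) && !identical(tg, sr))
        stop("domain mismatch in chain: step ", i, " targets '", tg,
             "' but step ", i + 1, " expects '", sr, "'")
    }
  }
  src <- if (length(flat)) flat[[1]]$source else NULL
  tgt <- if (length(flat)) flat[[length(flat)]]$target else NULL
  structure(list(transforms = flat, source = src, target = tgt),
            class = c("transform_chain", "wss_transform"))
}

#' Compose a chain into a single point-mapping function
#'
#' @param chain a `transform_chain` (or any single transform).
#' @return function mapping an n x 2 matrix to an n x 2 matrix, equal to
#'   sequential application of the chain's steps.
#' @export
compose <- function(chain) {
  force(chain)
  function(pts) apply_transform(chain, pts)
}

#' Apply an in-plane transform to every contour of a stack
#'
#' @param stack a `contour_stack`.
#' @param tf either one `wss_transform` applied to all slices, or a list of
#'   transforms named by slice index (each slice must be present).
#' @return transformed `contour_stack` (z locations unchanged).
#' @export
transform_contours <- function(stack, tf) {
  entries <- lapply(stack$entries, function(e) {
    t1 <- if (inherits(tf, "wss_transform")) tf else {
      key <- as.character(e$slice_index)
      if (is.null(tf[[key]])) stop("no transform for slice ", e$slice_index)
      tf[[key]]
    }
    e$points <- apply_transform(t1, e$points)
    e
  })
  contour_stack(entries, check_simple = FALSE)
}

#' Apply an in-plane transform to surface-mesh vertices
#'
#' Vertex (x, y) coordinates are mapped; z is untouched. With a per-slice
#' transform list, each vertex uses the transform of the nearest section z.
#'
#' @param field a `surface_field`.
#' @param tf a `wss_transform`, or a list of transforms named by slice index
#'   with `section_z` giving each slice's z location.
#' @param section_z numeric vector of section z locations named by slice
#'   index; required when `tf` is a per-slice list.
#' @return transformed `surface_field`.
#' @export
transform_surface <- function(field, tf, section_z = NULL) {
  v <- field$vertices
  if (inherits(tf, "wss_transform")) {
    v[, 1:2] <- apply_transform(tf, v[, 1:2, drop = FALSE])
  } else {
    if (is.null(section_z)) stop("section_z required for per-slice transforms")
    keys <- names(tf)
    zs <- section_z[keys]
    nearest <- keys[max.col(-abs(outer(v[, 3], zs, `-`)), ties.method = "first")]
    for (key in keys) {
      sel <- nearest == key
      if (any(sel)) v[sel, 1:2] <- apply_transform(tf[[key]], v[sel, 1:2, drop = FALSE])
    }
  }
  surface_field(v, field$faces, field$wss_pa)
}
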