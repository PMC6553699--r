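# Core containers. Conventions: all world coordinates in mm; z is the axial
# (caudal -> cranial) direction; slice planes are orthogonal to z; in-plane
# axes (x, y) form a right-handed frame with z; contours are counter-clockwise
# when viewed from +z (enforced on construction/read by reorientation).

#' Regular 3D scalar grid (MRI surrogate)
#'
#' World coordinate of voxel `(i, j, k)` (0-based) is
#' `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param voxels 3D numeric array.
#' @param spacing_mm positive length-3 numeric, mm.
#' @param origin_mm length-3 numeric, mm.
#' @return object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm); origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values")
  if (length(origin_mm) != 3) stop("origin_mm must have length 3")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' En-face photograph of one transverse section
#'
#' @param pixels 2D numeric matrix (grayscale, values in `[0, 1]`).
#' @param pixel_size_mm positive scalar.
#' @param z_mm axial location of the photographed (proximal) face.
#' @param landmarks data.frame with columns `label`, `x_mm`, `y_mm` giving
#'   landmark positions in this photo's own frame; labels must be unique.
#' @return object of class `planar_image`.
#' @export
planar_image <- function(pixels, pixel_size_mm, z_mm,
                         landmarks = data.frame(label = character(),
                                                x_mm = numeric(), y_mm = numeric())) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0) stop("pixel_size_mm must be > 0")
  if (anyDuplicated(landmarks$label)) stop("landmark labels must be unique within an image")
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm, z_mm = z_mm,
                 landmarks = landmarks),
            class = "planar_image")
}

#' Stack of closed planar contours at known z-locations
#'
#' The geometry currency of registration and binning. Entries hold one closed
#' polyline per (slice, structure).
#'
#' @param entries list of lists with fields `slice_index` (integer),
#'   `z_mm` (numeric), `structure` (one of `"lumen"`, `"outer_wall"`,
#'   `"intima"`, `"media"`), `points` (n x 2 matrix, mm).
#' @param check_simple validate against self-intersection (O(n^2); can be
#'   disabled for very dense programmatic contours).
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(entries, check_simple = TRUE) {
  structures <- c("lumen", "outer_wall", "intima", "media")
  for (e in entries) {
    if (!all(c("slice_index", "z_mm", "structure", "points") %in% names(e)))
      stop("each entry needs slice_index, z_mm, structure, points")
    if (!e$structure %in% structures)
      stop("unknown structure '", e$structure, "'")
  }
  entries <- lapply(entries, function(e) {
    e$points <- validate_contour(
      e$points, sprintf("slice %d %s", e$slice_index, e$structure),
      check_simple = check_simple)
    e$slice_index <- as.integer(e$slice_index)
    e
  })
  # z must be strictly increasing with slice_index
  si <- vapply(entries, `[[`, integer(1), "slice_index")
  zz <- vapply(entries, `[[`, numeric(1), "z_mm")
  o <- order(si, zz)
  entries <- entries[o]; si <- si[o]; zz <- zz[o]
  u <- !duplicated(si)
  if (any(diff(si[u]) <= 0) || any(diff(zz[u]) <= 0))
    stop("z_mm must be strictly increasing with slice_index")
  for (s in unique(si)) {
    zs <- zz[si == s]
    if (max(zs) - min(zs) > 1e-9) stop("inconsistent z_mm within slice ", s)
  }
  structure(list(entries = entries), class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat("<contour_stack> ", length(x$entries), " contours on ",
      length(unique(vapply(x$entries, `[[`, integer(1), "slice_index"))),
      " slices\n", sep = "")
  invisible(x)
}

#' Slice indices present in a contour stack
#' @param stack a `contour_stack`.
#' @return sorted integer vector.
#' @export
stack_slices <- function(stack) {
  sort(unique(vapply(stack$entries, `[[`, integer(1), "slice_index")))
}

#' Extract one contour from a stack
#' @param stack a `contour_stack`.
#' @param slice_index slice to look up.
#' @param structure structure name.
#' @return n x 2 matrix, or NULL if absent.
#' @export
stack_get <- function(stack, slice_index, structure) {
  for (e in stack$entries)
    if (e$slice_index == slice_index && e$structure == structure) return(e$points)
  NULL
}

#' z location of a slice in a stack
#' @inheritParams stack_get
#' @return numeric z in mm (NA if the slice is absent).
#' @export
stack_z <- function(stack, slice_index) {
  for (e in stack$entries) if (e$slice_index == slice_index) return(e$z_mm)
  NA_real_
}

#' Triangulated lumen surface carrying a WSS scalar
#'
#' @param vertices n x 3 matrix of points, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param wss_pa numeric vector, one non-negative value (Pa) per vertex.
#' @return object of class `surface_field`.
#' @export
surface_field <- function(vertices, faces, wss_pa) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (ncol(faces) != 3) stop("faces must be m x 3")
  if (length(wss_pa) != nrow(vertices)) stop("need exactly one wss_pa value per vertex")
  if (any(wss_pa < 0)) stop("wss_pa must be non-negative")
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = matrix(as.integer(faces), ncol = 3),
                 wss_pa = as.numeric(wss_pa)),
            class = "surface_field")
}

#' @export
print.surface_field <- function(x, ...) {
  cat("<surface_field> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, wss ", signif(min(x$wss_pa), 3), "-", signif(max(x$wss_pa), 3),
      " Pa\n", sep = "")
  invisible(x)
}

# Column layout of the per-bin table; one row per (specimen, section, bin).
.bin_table_cols <- c("specimen_id", "slice_index", "z_mm", "bin_index",
                     "mean_wss_pa", "min_wss_pa", "max_wss_pa",
                     "plaque_thickness_mm", "error_flags", "included")

#' Construct/validate a per-bin results table
#'
#' @param df data.frame with columns `specimen_id`, `slice_index`, `z_mm`,
#'   `bin_index`, `mean_wss_pa`, `min_wss_pa`, `max_wss_pa`,
#'   `plaque_thickness_mm`, `error_flags` (comma-joined subset of
#'   `type1,type2,type3`, `""` for none), `included` (logical).
#' @return the validated data.frame with class `bin_table`.
#' @export
bin_table <- function(df) {
  missing_cols <- setdiff(.bin_table_cols, names(df))
  if (length(missing_cols)) stop("bin table missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  df <- df[, .bin_table_cols]
  key <- paste(df$specimen_id, df$slice_index, df$bin_index)
  if (anyDuplicated(key))
    stop("duplicate (specimen, slice_index, bin_index) keys: ",
         key[anyDuplicated(key)])
  ok <- is.na(df$mean_wss_pa) |
    (df$min_wss_pa <= df$mean_wss_pa + 1e-12 & df$mean_wss_pa <= df$max_wss_pa + 1e-12)
  if (!all(ok)) stop("per-bin min <= mean <= max violated")
  if (any(!is.na(df$plaque_thickness_mm) & df$plaque_thickness_mm < -1e-12))
    stop("plaque thickness must be non-negative")
  flagged <- df$error_flags != ""
  if (!all(df$included == !flagged))
    stop("included must be TRUE exactly when error_flags is empty")
  class(df) <- c("bin_table", "data.frame")
  df
}
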