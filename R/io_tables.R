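# CSV/JSON/PNG artifact I/O: contour and landmark tables, bin tables, error
# flags, serialized transforms, en-face photographs.

.write_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a contour stack to CSV
#'
#' Columns: `slice_index`, `structure`, `point_index`, `x_mm`, `y_mm`, `z_mm`.
#' Vertices are written open (the closing edge is implicit).
#' @param stack a [contour_stack()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_contours <- function(stack, path) {
  rows <- lapply(stack$entries, function(e) {
    data.frame(slice_index = e$slice_index, structure = e$structure,
               point_index = seq_len(nrow(e$points)) - 1L,
               x_mm = e$points[, 1], y_mm = e$points[, 2], z_mm = e$z_mm)
  })
  .write_csv(do.call(rbind, rows), path)
}

#' Read a contour stack from CSV
#'
#' Validates every contour on read (closedness is implicit in the format;
#' self-intersecting or degenerate contours are rejected naming the slice and
#' structure; duplicate `(slice_index, structure, point_index)` rows are an
#' error). Contours are reoriented counter-clockwise.
#' @param path CSV written by [write_contours()] (or by hand with the same
#'   columns).
#' @return a [contour_stack()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("contour file does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("slice_index", "structure", "point_index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("contour CSV missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  key <- paste(df$slice_index, df$structure, df$point_index)
  if (anyDuplicated(key))
    stop("duplicate (slice_index, structure, point_index) in ", path, ": ",
         key[anyDuplicated(key)])
  groups <- split(df, paste(df$slice_index, df$structure, sep = "\r"))
  entries <- lapply(groups, function(g) {
    g <- g[order(g$point_index), ]
    list(slice_index = g$slice_index[1], z_mm = g$z_mm[1],
         structure = as.character(g$structure[1]),
         points = cbind(g$x_mm, g$y_mm))
  })
  contour_stack(unname(entries))
}

#' Write / read landmark tables
#'
#' Columns: `slice_index`, `label`, `x_mm`, `y_mm`.
#' @param landmarks data.frame with those columns.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_landmarks <- function(landmarks, path) .write_csv(landmarks, path)

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("slice_index", "label", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("landmark CSV missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$label <- as.character(df$label)
  df
}

#' Write / read a per-bin results table
#' @param table a [bin_table()].
#' @param path CSV path.
#' @return `path` (write) or a validated [bin_table()] (read).
#' @export
write_bin_table <- function(table, path) {
  df <- as.data.frame(table)
  .write_csv(df, path)
}

#' @rdname write_bin_table
#' @export
read_bin_table <- function(path) {
  if (!file.exists(path)) stop("bin table file does not exist: ", path)
  df <- utils::read.csv(path, colClasses = c(error_flags = "character"))
  df$error_flags[is.na(df$error_flags)] <- ""
  df$included <- as.logical(df$included)
  for (col in c("z_mm", "mean_wss_pa", "min_wss_pa", "max_wss_pa", "plaque_thickness_mm"))
    df[[col]] <- as.numeric(df[[col]])
  bin_table(df)
}

#' Read per-bin error flags
#'
#' Columns: `specimen_id`, `slice_index`, `bin_index`, `error_type`
#' (`type1`/`type2`/`type3`); one row per flag, bins may repeat.
#' @param path CSV path.
#' @return data.frame of flags.
#' @export
read_error_flags <- function(path) {
  if (!file.exists(path)) stop("error-flag file does not exist: ", path)
  df <- utils::read.csv(path)
  need <- c("specimen_id", "slice_index", "bin_index", "error_type")
  if (!all(need %in% names(df)))
    stop("flag CSV missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$error_type), c("type1", "type2", "type3"))
  if (length(bad)) stop("unknown error_type: ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_error_flags
#' @param flags data.frame of flags.
#' @export
write_error_flags <- function(flags, path) .write_csv(flags, path)

# --- transform serialization -------------------------------------------------

.transform_to_list <- function(tf) {
  if (inherits(tf, "similarity_transform"))
    list(type = "similarity", rotation_deg = tf$rotation_deg, scale = tf$scale,
         translation_mm = tf$translation_mm, source = tf$source, target = tf$target)
  else if (inherits(tf, "bspline_transform"))
    list(type = "bspline", origin_mm = tf$origin_mm, spacing_mm = tf$spacing_mm,
         shape = tf$shape, coef_x = as.numeric(tf$coef_x),
         coef_y = as.numeric(tf$coef_y), source = tf$source, target = tf$target)
  else if (inherits(tf, "inverse_bspline"))
    list(type = "inverse_bspline", forward = .transform_to_list(tf$forward))
  else if (inherits(tf, "identity_transform"))
    list(type = "identity", source = tf$source, target = tf$target)
  else if (inherits(tf, "transform_chain"))
    list(type = "chain", transforms = lapply(tf$transforms, .transform_to_list))
  else if (is.list(tf) && !inherits(tf, "wss_transform"))
    list(type = "slicewise", transforms = lapply(tf, .transform_to_list))
  else stop("cannot serialize transform of class ", paste(class(tf), collapse = "/"))
}

.transform_from_list <- function(x) {
  switch(x$type,
         similarity = similarity_transform(x$rotation_deg, x$scale,
                                           unlist(x$translation_mm),
                                           source = x$source, target = x$target),
         bspline = bspline_transform(unlist(x$origin_mm), unlist(x$spacing_mm),
                                     unlist(x$shape),
                                     matrix(unlist(x$coef_x), unlist(x$shape)[1]),
                                     matrix(unlist(x$coef_y), unlist(x$shape)[1]),
                                     source = x$source, target = x$target),
         inverse_bspline = invert_transform(.transform_from_list(x$forward)),
         identity = identity_transform(source = x$source, target = x$target),
         chain = transform_chain(lapply(x$transforms, .transform_from_list)),
         slicewise = lapply(x$transforms, .transform_from_list),
         stop("unknown transform type tag '", x$type, "'"))
}

#' Serialize transforms to JSON
#'
#' Handles single transforms, chains, and (nested, possibly slicewise) lists
#' of transforms; each object carries a `type` tag.
#' @param tf transform, chain, or named list thereof.
#' @param path JSON path.
#' @return `path` (write) or the reconstructed object (read).
#' @export
write_transforms <- function(tf, path) {
  jsonlite::write_json(.transform_to_list(tf), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  if (!file.exists(path)) stop("transform file does not exist: ", path)
  .transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

# --- en-face photographs -----------------------------------------------------

#' Write / read an en-face photo as grayscale PNG
#'
#' Pixel `(row r, col c)` has its center at `x = (c - 0.5) * pixel_size_mm`,
#' `y = (r - 0.5) * pixel_size_mm` in the photo frame. PNG stores only pixels;
#' `pixel_size_mm`, `z_mm` and landmarks travel in the specimen's landmark CSV
#' and metadata JSON (see [write_phantom_dir()]).
#' @param img a [planar_image()].
#' @param path PNG path.
#' @return `path` (write); for reads, a [planar_image()] with the supplied
#'   metadata attached.
#' @export
write_photo <- function(img, path) {
  px <- pmin(pmax(img$pixels, 0), 1)
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname write_photo
#' @param pixel_size_mm,z_mm,landmarks metadata to attach on read.
#' @export
read_photo <- function(path, pixel_size_mm, z_mm,
                       landmarks = data.frame(label = character(),
                                              x_mm = numeric(), y_mm = numeric())) {
  if (!file.exists(path)) stop("photo does not exist: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  planar_image(px, pixel_size_mm, z_mm, landmarks)
}
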