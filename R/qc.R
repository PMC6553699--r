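# Registration quality control: Dice similarity coefficient between lumen
# masks, symmetric Hausdorff distance between lumen contours, the three-
# error-type exclusion bookkeeping, and Table-1-style summaries.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`. Both masks empty is defined as 1 (identical
#' segmentations); exactly one empty mask is an error.
#' @param mask_a,mask_b logical/0-1 matrices of identical shape (same pixel
#'   size assumed).
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  a <- sum(mask_a != 0); b <- sum(mask_b != 0)
  if (a + b == 0) return(1)
  if (a == 0 || b == 0)
    stop("one mask is empty while the other is not; Dice undefined by convention")
  2 * sum(mask_a != 0 & mask_b != 0) / (a + b)
}

#' Rasterize a contour to a binary mask
#'
#' Pixel centers inside the polygon become TRUE.
#' @param contour closed contour, mm.
#' @param pixel_mm raster resolution (default 0.05 mm).
#' @param bbox optional list with `lo`, `hi` (length-2 each) fixing the grid;
#'   required when two masks must share a grid (see [dice_from_contours()]).
#' @return logical matrix (x index by y index).
#' @export
rasterize_contour_mask <- function(contour, pixel_mm = 0.05, bbox = NULL) {
  contour <- drop_closing_vertex(as.matrix(contour))
  if (is.null(bbox)) {
    lo <- apply(contour, 2, min) - 2 * pixel_mm
    hi <- apply(contour, 2, max) + 2 * pixel_mm
  } else { lo <- bbox$lo; hi <- bbox$hi }
  gx <- seq(lo[1] + pixel_mm / 2, hi[1], by = pixel_mm)
  gy <- seq(lo[2] + pixel_mm / 2, hi[2], by = pixel_mm)
  inside <- point_in_polygon(rep(gx, times = length(gy)), rep(gy, each = length(gx)),
                             contour)
  matrix(inside, length(gx), length(gy))
}

#' Dice coefficient between two contours
#'
#' Rasterizes both contours on one shared grid and applies
#' [dice_coefficient()].
#' @param contour_a,contour_b closed contours, mm.
#' @param pixel_mm raster resolution (default 0.05 mm).
#' @return scalar in `[0, 1]`.
#' @export
dice_from_contours <- function(contour_a, contour_b, pixel_mm = 0.05) {
  pts <- rbind(drop_closing_vertex(as.matrix(contour_a)),
               drop_closing_vertex(as.matrix(contour_b)))
  bbox <- list(lo = apply(pts, 2, min) - 2 * pixel_mm,
               hi = apply(pts, 2, max) + 2 * pixel_mm)
  dice_coefficient(rasterize_contour_mask(contour_a, pixel_mm, bbox),
                   rasterize_contour_mask(contour_b, pixel_mm, bbox))
}

#' Symmetric Hausdorff distance between two closed contours
#'
#' Continuous-curve Hausdorff distance: both contours are densely resampled
#' and each sampled point's exact distance to the other contour's segments is
#' taken; the result is the larger of the two directed maxima.
#' @param contour_a,contour_b closed contours, mm.
#' @param sample_spacing_mm resampling arc spacing (default 0.02 mm).
#' @return distance in mm.
#' @export
hausdorff_distance <- function(contour_a, contour_b, sample_spacing_mm = 0.02) {
  a <- drop_closing_vertex(as.matrix(contour_a))
  b <- drop_closing_vertex(as.matrix(contour_b))
  if (!nrow(a) || !nrow(b)) stop("empty contour")
  pa <- resample_contour(a, sample_spacing_mm)
  pb <- resample_contour(b, sample_spacing_mm)
  d_ab <- max(dist_to_polygon(pa[, 1], pa[, 2], b))
  d_ba <- max(dist_to_polygon(pb[, 1], pb[, 2], a))
  max(d_ab, d_ba)
}

#' Apply error-type exclusion flags to a bin table
#'
#' A bin is excluded (`included = FALSE`) exactly when it carries at least one
#' flag; bins with multiple flag types are excluded once but appear in every
#' per-type tally.
#' @param table a [bin_table()].
#' @param flags data.frame with `specimen_id`, `slice_index`, `bin_index`,
#'   `error_type` (`type1`/`type2`/`type3`); one row per flag.
#' @return the updated [bin_table()].
#' @export
apply_exclusions <- function(table, flags) {
  df <- as.data.frame(table)
  key <- paste(df$specimen_id, df$slice_index, df$bin_index)
  df$error_flags <- ""
  if (nrow(flags)) {
    fkey <- paste(flags$specimen_id, flags$slice_index, flags$bin_index)
    unknown <- setdiff(fkey, key)
    if (length(unknown))
      stop("flags reference unknown bins: ", paste(unique(unknown), collapse = "; "))
    agg <- tapply(as.character(flags$error_type), fkey,
                  function(x) paste(sort(unique(x)), collapse = ","))
    hit <- match(key, names(agg))
    df$error_flags[!is.na(hit)] <- as.character(agg[hit[!is.na(hit)]])
  }
  df$included <- df$error_flags == ""
  bin_table(df)
}

#' Exclusion tallies per specimen (Table-1-style bookkeeping)
#'
#' @param table a flagged [bin_table()] (after [apply_exclusions()]).
#' @return data.frame per specimen: total bins, per-type flag counts (a
#'   multi-flag bin counts in each of its types), excluded bins (set union,
#'   counted once), remaining bins and remaining fraction.
#' @export
exclusion_tally <- function(table) {
  df <- as.data.frame(table)
  out <- lapply(split(df, df$specimen_id), function(g) {
    has <- function(t) sum(grepl(t, g$error_flags, fixed = TRUE))
    excluded <- sum(!g$included)
    data.frame(specimen_id = g$specimen_id[1], n_bins = nrow(g),
               type1 = has("type1"), type2 = has("type2"), type3 = has("type3"),
               excluded = excluded, remaining = nrow(g) - excluded,
               remaining_fraction = (nrow(g) - excluded) / nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-specimen and cross-specimen DSC/HD summary (Table-1 layout)
#'
#' For each specimen and error type (2 and 3), averages per-section DSC and HD
#' before exclusion (all sections) and after exclusion (sections with no bin
#' flagged with that type). Cross-specimen averages are reported to two
#' decimals.
#'
#' @param section_metrics data.frame with `specimen_id`, `slice_index`,
#'   `dsc_type2`, `hd_type2_mm`, `dsc_type3`, `hd_type3_mm` (per-section
#'   metrics).
#' @param table a flagged [bin_table()] aligned with `section_metrics`.
#' @return list with `per_specimen` (one row per specimen x error type) and
#'   `cross_specimen` (averages over specimens, rounded to 2 decimals).
#' @export
qc_summary <- function(section_metrics, table) {
  df <- as.data.frame(table)
  rows <- list()
  for (sp in unique(section_metrics$specimen_id)) {
    m <- section_metrics[section_metrics$specimen_id == sp, ]
    g <- df[df$specimen_id == sp, ]
    for (type in c("type2", "type3")) {
      dsc_col <- paste0("dsc_", type); hd_col <- paste0("hd_", type, "_mm")
      bad_slices <- unique(g$slice_index[grepl(type, g$error_flags, fixed = TRUE)])
      keep <- !(m$slice_index %in% bad_slices)
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = sp, error_type = type,
        n_flagged_bins = sum(grepl(type, g$error_flags, fixed = TRUE)),
        dsc_before = mean(m[[dsc_col]]), dsc_after = mean(m[[dsc_col]][keep]),
        hd_before_mm = mean(m[[hd_col]]), hd_after_mm = mean(m[[hd_col]][keep]))
    }
  }
  per_specimen <- do.call(rbind, rows)
  cross <- do.call(rbind, lapply(split(per_specimen, per_specimen$error_type),
                                 function(g) data.frame(
    error_type = g$error_type[1],
    dsc_before = round(mean(g$dsc_before), 2),
    dsc_after = round(mean(g$dsc_after), 2),
    hd_before_mm = round(mean(g$hd_before_mm), 2),
    hd_after_mm = round(mean(g$hd_after_mm), 2))))
  rownames(cross) <- NULL
  list(per_specimen = per_specimen, cross_specimen = cross)
}

#' Cross-specimen average of per-specimen QC values
#'
#' Utility for Table-1-style arithmetic: the mean over specimens, reported to
#' two decimals.
#' @param values numeric per-specimen values (e.g. post-exclusion DSC).
#' @return rounded mean.
#' @export
qc_cross_specimen_average <- function(values) round(mean(values), 2)
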