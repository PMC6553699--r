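# Volume I/O: NIfTI-1 (.nii / .nii.gz) and MetaImage (.mhd + .raw).
# No NIfTI or MetaImage reader ships with the available R stack, so both
# formats are implemented here against their published layouts (NIfTI-1:
# fixed 348-byte header, data at vox_offset; MetaImage: text header plus a
# separate raw block). Scope: scalar 3D images, little-endian, the datatypes
# MRI tooling commonly emits. Orientation handling is deliberately minimal:
# spacing comes from pixdim/ElementSpacing and the origin from the sform row
# offsets (or Offset); rotation matrices in sforms are not applied.

.vol_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return("nii.gz")
  if (grepl("\\.nii$", p)) return("nii")
  if (grepl("\\.mhd$", p)) return("mhd")
  stop("unknown volume format for '", path, "' (expected .nii, .nii.gz or .mhd)")
}

#' Read a 3D volume
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mhd` with local raw
#' data).
#' @param path file to read.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  switch(.vol_ext(path),
         "nii" = , "nii.gz" = .read_nifti(path),
         "mhd" = .read_mhd(path))
}

#' Write a 3D volume
#'
#' Round-trips voxels, spacing and origin losslessly (float64 payload).
#' @param volume a [volume_image()].
#' @param path destination (`.nii`, `.nii.gz` or `.mhd`; MetaImage also
#'   writes the sibling `.raw`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  switch(.vol_ext(path),
         "nii" = .write_nifti(volume, path, gz = FALSE),
         "nii.gz" = .write_nifti(volume, path, gz = TRUE),
         "mhd" = .write_mhd(volume, path))
  invisible(path)
}

.read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", 348)
  if (length(raw_hdr) < 348) stop("corrupt NIfTI header in ", path, " (short read)")
  rd <- function(what, n, off, size) {
    readBin(raw_hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  sizeof_hdr <- rd("integer", 1, 0, 4)
  endian <- "little"
  if (sizeof_hdr != 348) {
    sizeof_hdr_be <- readBin(raw_hdr[1:4], "integer", 1, 4, endian = "big")
    if (sizeof_hdr_be == 348) {
      endian <- "big"
      rd <- function(what, n, off, size)
        readBin(raw_hdr[(off + 1):(off + n * size)], what, n = n, size = size,
                endian = "big")
    } else stop("corrupt NIfTI header in ", path, " (sizeof_hdr != 348)")
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("corrupt NIfTI header in ", path,
                                        " (bad magic '", magic, "')")
  dim8 <- rd("integer", 8, 40, 2)
  ndim <- dim8[1]
  if (ndim < 3) dim8[(ndim + 2):8] <- 1L
  dims <- pmax(dim8[2:4], 1L)
  if (any(dim8[5:8] > 1, na.rm = TRUE))
    stop("only scalar 3D NIfTI volumes are supported: ", path)
  datatype <- rd("integer", 1, 70, 2)
  pixdim <- rd("numeric", 8, 76, 4)
  vox_offset <- rd("numeric", 1, 108, 4)
  scl_slope <- rd("numeric", 1, 112, 4)
  scl_inter <- rd("numeric", 1, 116, 4)
  sform_code <- rd("integer", 1, 254, 2)
  srow <- rbind(rd("numeric", 4, 280, 4), rd("numeric", 4, 296, 4),
                rd("numeric", 4, 312, 4))
  qoffset <- rd("numeric", 3, 268, 4)
  spec <- switch(as.character(datatype),
                 "2" = list("integer", 1, FALSE), "4" = list("integer", 2, TRUE),
                 "8" = list("integer", 4, TRUE), "16" = list("numeric", 4, NA),
                 "64" = list("numeric", 8, NA), "512" = list("integer", 2, FALSE),
                 stop("unsupported NIfTI datatype ", datatype, " in ", path))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vox <- if (identical(spec[[1]], "integer"))
    readBin(con, "integer", n = n, size = spec[[2]], signed = isTRUE(spec[[3]]),
            endian = endian)
  else readBin(con, "numeric", n = n, size = spec[[2]], endian = endian)
  if (length(vox) < n) stop("corrupt NIfTI data in ", path, " (short read)")
  vox <- as.numeric(vox)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  origin <- if (sform_code > 0) srow[, 4] else qoffset
  volume_image(array(vox, dims), spacing, origin)
}

.write_nifti <- function(volume, path, gz = FALSE) {
  dims <- dim(volume$voxels)
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)
  w(348L, 4); pad(36)                                   # sizeof_hdr .. dim_info
  w(as.integer(c(3, dims, 1, 1, 1, 1)), 2)              # dim[8]
  w(c(0, 0, 0), 4); w(0L, 2)                            # intent_p*, intent_code
  w(64L, 2); w(64L, 2); w(0L, 2)                        # datatype, bitpix, slice_start
  w(c(1, volume$spacing_mm, 0, 0, 0, 0), 4)             # pixdim[8]
  w(352, 4); w(1, 4); w(0, 4)                           # vox_offset, scl_slope, scl_inter
  w(0L, 2); pad(1); writeBin(as.raw(2L), con)           # slice_end, slice_code, xyzt=mm
  w(c(0, 0, 0, 0), 4); w(0L, 4); w(0L, 4)               # cal/slice_duration/toffset/glmax/glmin
  pad(80 + 24)                                          # descrip, aux_file
  w(0L, 2); w(1L, 2)                                    # qform_code, sform_code
  w(c(0, 0, 0), 4); w(volume$origin_mm, 4)              # quatern, qoffset
  w(c(volume$spacing_mm[1], 0, 0, volume$origin_mm[1]), 4)
  w(c(0, volume$spacing_mm[2], 0, volume$origin_mm[2]), 4)
  w(c(0, 0, volume$spacing_mm[3], volume$origin_mm[3]), 4)
  pad(16)                                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)         # magic
  pad(4)                                                # extension flag
  w(as.numeric(volume$voxels), 8)
  invisible(path)
}

.read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(kv)))
    stop("corrupt MetaImage header in ", path, ": missing ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  if (as.integer(kv$NDims) != 3) stop("only 3D MetaImage volumes supported: ", path)
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  spec <- switch(kv$ElementType,
                 "MET_UCHAR" = list("integer", 1, FALSE),
                 "MET_SHORT" = list("integer", 2, TRUE),
                 "MET_USHORT" = list("integer", 2, FALSE),
                 "MET_INT" = list("integer", 4, TRUE),
                 "MET_FLOAT" = list("numeric", 4, NA),
                 "MET_DOUBLE" = list("numeric", 8, NA),
                 stop("unsupported MetaImage ElementType ", kv$ElementType))
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path)) stop("MetaImage data file missing: ", raw_path)
  con <- file(raw_path, "rb"); on.exit(close(con))
  n <- prod(dims)
  vox <- if (identical(spec[[1]], "integer"))
    readBin(con, "integer", n = n, size = spec[[2]], signed = isTRUE(spec[[3]]),
            endian = "little")
  else readBin(con, "numeric", n = n, size = spec[[2]], endian = "little")
  if (length(vox) < n) stop("corrupt MetaImage data in ", raw_path, " (short read)")
  volume_image(array(as.numeric(vox), dims), spacing, origin)
}

.write_mhd <- function(volume, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  dims <- dim(volume$voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(format(volume$spacing_mm, digits = 17),
                                           collapse = " ")),
           paste("Offset =", paste(format(volume$origin_mm, digits = 17),
                                   collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb"); on.exit(close(con))
  writeBin(as.numeric(volume$voxels), con, size = 8, endian = "little")
  invisible(path)
}
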