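# Surface mesh I/O: VTK PolyData XML (.vtp, ascii) and PLY (ascii). The WSS
# scalar travels as a per-vertex array named "wss_pa"; reads without it fail.

.surf_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.vtp$", p)) return("vtp")
  if (grepl("\\.ply$", p)) return("ply")
  stop("unknown surface format for '", path, "' (expected .vtp or .ply)")
}

#' Read a lumen surface with WSS scalars
#' @param path `.vtp` (VTK PolyData XML, ascii) or `.ply` (ascii) file.
#' @return a [surface_field()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("surface file does not exist: ", path)
  switch(.surf_ext(path), vtp = .read_vtp(path), ply = .read_ply(path))
}

#' Write a lumen surface with WSS scalars
#' @param field a [surface_field()].
#' @param path destination `.vtp` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(field, path) {
  stopifnot(inherits(field, "surface_field"))
  switch(.surf_ext(path), vtp = .write_vtp(field, path), .write_ply(field, path))
  invisible(path)
}

.num_line <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                               collapse = " ")

.write_vtp <- function(field, path) {
  n <- nrow(field$vertices); m <- nrow(field$faces)
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl('<?xml version="1.0"?>')
  wl('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  wl('  <PolyData>')
  wl(sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">', n, m))
  wl('      <PointData Scalars="wss_pa">')
  wl('        <DataArray type="Float64" Name="wss_pa" format="ascii">')
  wl("          ", .num_line(field$wss_pa))
  wl('        </DataArray>')
  wl('      </PointData>')
  wl('      <Points>')
  wl('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  wl("          ", .num_line(t(field$vertices)))
  wl('        </DataArray>')
  wl('      </Points>')
  wl('      <Polys>')
  wl('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  wl("          ", paste(t(field$faces) - 1L, collapse = " "))
  wl('        </DataArray>')
  wl('        <DataArray type="Int64" Name="offsets" format="ascii">')
  wl("          ", paste(seq_len(m) * 3L, collapse = " "))
  wl('        </DataArray>')
  wl('      </Polys>')
  wl('    </Piece>')
  wl('  </PolyData>')
  wl('</VTKFile>')
}

.read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("corrupt .vtp (no Piece): ", path)
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  if (inherits(pts_node, "xml_missing")) stop("corrupt .vtp (no Points): ", path)
  verts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  wss_node <- xml2::xml_find_first(piece, './PointData/DataArray[@Name="wss_pa"]')
  if (inherits(wss_node, "xml_missing"))
    stop("surface in ", path, " lacks the required 'wss_pa' vertex scalar array")
  wss <- num(wss_node)
  conn_node <- xml2::xml_find_first(piece, './Polys/DataArray[@Name="connectivity"]')
  faces <- if (inherits(conn_node, "xml_missing") ||
               !nzchar(trimws(xml2::xml_text(conn_node)))) {
    matrix(integer(), ncol = 3)
  } else matrix(as.integer(num(conn_node)) + 1L, ncol = 3, byrow = TRUE)
  surface_field(verts, faces, wss)
}

.write_ply <- function(field, path) {
  n <- nrow(field$vertices); m <- nrow(field$faces)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property double x", "property double y", "property double z",
               "property double wss_pa",
               paste("element face", m),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(cbind(field$vertices, field$wss_pa), 1, .num_line), con)
  if (m) writeLines(paste(3L, field$faces[, 1] - 1L, field$faces[, 2] - 1L,
                          field$faces[, 3] - 1L), con)
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_idx <- match("end_header", trimws(lines))
  if (is.na(end_idx)) stop("corrupt .ply (no end_header): ", path)
  hdr <- trimws(lines[seq_len(end_idx)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (!length(nf)) nf <- 0L
  vprops <- sub("^property \\S+ ", "", grep("^property (double|float) ", hdr, value = TRUE))
  wss_col <- match("wss_pa", vprops)
  if (is.na(wss_col))
    stop("surface in ", path, " lacks the required 'wss_pa' vertex scalar array")
  body <- lines[-seq_len(end_idx)]
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  faces <- if (nf > 0) {
    fdat <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                  as.integer))
    fdat[, 2:4, drop = FALSE] + 1L
  } else matrix(integer(), ncol = 3)
  xyz <- match(c("x", "y", "z"), vprops)
  surface_field(vdat[, xyz, drop = FALSE], faces, vdat[, wss_col])
}
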