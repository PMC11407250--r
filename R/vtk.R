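# Minimal VTK XML unstructured-grid (.vtu) writer: ASCII, tetrahedra only.
# Enough for ParaView/pyvista inspection of meshes, labels and nodal fields.

#' Write a mesh (with optional fields) as a VTK .vtu file
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path (conventionally `.vtu`).
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element vectors; the tissue label is
#'   always written as an integer array `tissue` (index into
#'   [tissue_labels()]).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  cell_data$tissue <- match(mesh$labels, tissue_labels())
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x, per_line = 6L) {
    x <- format(x, digits = 9, trim = TRUE, scientific = TRUE)
    lines <- split(x, ceiling(seq_along(x) / per_line))
    writeLines(vapply(lines, paste, "", collapse = " "), con)
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  num(as.vector(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
                   mesh$elements[, 3] - 1L, mesh$elements[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  num(4L * seq_len(m), per_line = 12L)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  num(rep(10L, m), per_line = 24L)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      num(as.numeric(point_data[[nm]]))
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <CellData>')
  for (nm in names(cell_data)) {
    w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
    num(as.numeric(cell_data[[nm]]))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a probe layout as JSON
#'
#' @param layout a [build_probe_layout()] result.
#' @param path output path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(list(grid_shape = layout$grid_shape,
                            extent = layout$extent,
                            optodes = layout$optodes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
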