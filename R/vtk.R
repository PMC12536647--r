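#' Export a mesh and fields as a legacy ASCII VTK unstructured grid
#'
#' Writes triangles or tetrahedra with optional named point and cell arrays,
#' readable by ParaView and meshio.
#'
#' @param mesh `mp_mesh`.
#' @param path output file path (`.vtk`).
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elem); nl <- ncol(mesh$elem)
  pts <- mesh$nodes
  if (ncol(pts) == 2) pts <- cbind(pts, 0)
  writeLines(c("# vtk DataFile Version 3.0",
               "magnetopiezo field snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(format(pts, digits = 10, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", m, m * (nl + 1L)), con)
  utils::write.table(cbind(nl, mesh$elem - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(if (nl == 3) 5L else 10L, m)), con)
  wr_arrays <- function(data, hdr, count) {
    writeLines(paste(hdr, count), con)
    for (nm in names(data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      v <- data[[nm]]
      v[is.na(v)] <- 0
      writeLines(format(v, digits = 9, scientific = TRUE), con)
    }
  }
  if (!is.null(point_data)) wr_arrays(point_data, "POINT_DATA", n)
  if (!is.null(cell_data)) {
    writeLines(c(paste("CELL_DATA", m),
                 "SCALARS subdomain int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(as.integer(factor(mesh$subdomain))), con)
    for (nm in names(cell_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      v <- cell_data[[nm]]
      v[is.na(v)] <- 0
      writeLines(format(v, digits = 9, scientific = TRUE), con)
    }
  }
  invisible(path)
}
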