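# Minimal ASCII XML VTK writers (UnstructuredGrid .vtu for meshes + fields,
# PolyData .vtp for wire polylines) and a matching reader for round-trips.

.fmt_nums <- function(x, per_line = 6L) {
  s <- format(x, digits = 17, scientific = TRUE, trim = TRUE)
  paste(s, collapse = " ")
}

#' Write a mesh and fields to an XML VTU file
#'
#' @param mesh a `tet_mesh`
#' @param path output file
#' @param point_data named list of nodal fields (vector length n_nodes or
#'   matrix n_nodes x 3 for vectors)
#' @param cell_data named list of per-element fields
#' @return `path`, invisibly
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  da <- function(name, x, ncomp) {
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp))
    w("          ", .fmt_nums(if (ncomp > 1) as.vector(t(x)) else x))
    w("        </DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne))
  w('      <Points>')
  da("Points", mesh$nodes, 3L)
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", paste(as.vector(t(mesh$tets)) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", paste(seq_len(ne) * 4L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(rep(10L, ne), collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      da(nm, x, if (is.null(dim(x))) 1L else ncol(x))
    }
    w('      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      da(nm, x, if (is.null(dim(x))) 1L else ncol(x))
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read back a VTU file written by [write_vtu]
#'
#' @param path a .vtu file
#' @return list with `nodes`, `tets`, `point_data`, `cell_data`
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getarr <- function(node) {
    vals <- scan(text = xml2::xml_text(node), what = double(), quiet = TRUE)
    nc <- xml2::xml_attr(node, "NumberOfComponents")
    nc <- if (is.na(nc)) 1L else as.integer(nc)
    if (nc > 1) matrix(vals, ncol = nc, byrow = TRUE) else vals
  }
  pts <- getarr(xml2::xml_find_first(piece, ".//Points/DataArray"))
  conn <- scan(text = xml2::xml_text(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']")), what = integer(),
    quiet = TRUE)
  tets <- matrix(conn + 1L, ncol = 4L, byrow = TRUE)
  rd <- function(where) {
    sect <- xml2::xml_find_first(piece, paste0(".//", where))
    out <- list()
    if (!inherits(sect, "xml_missing")) {
      for (node in xml2::xml_find_all(sect, "DataArray")) {
        out[[xml2::xml_attr(node, "Name")]] <- getarr(node)
      }
    }
    out
  }
  list(nodes = pts, tets = tets, point_data = rd("PointData"),
       cell_data = rd("CellData"))
}

#' Write wire polylines to an XML VTP file
#'
#' @param ws a `wire_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vtp <- function(ws, path) {
  pts <- do.call(rbind, ws$wires)
  counts <- vapply(ws$wires, nrow, 1L)
  offsets <- cumsum(counts)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfLines="%d">',
            nrow(pts), length(counts)))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", .fmt_nums(as.vector(t(pts))))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Lines>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", paste(seq_len(nrow(pts)) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", paste(offsets, collapse = " "))
  w('        </DataArray>')
  w('      </Lines>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
  invisible(path)
}
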