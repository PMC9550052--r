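# Plain-text interchange: VTK XML unstructured-grid (.vtu, ASCII) export
# and import of labeled meshes, and cohort manifests. Written by hand since
# no VTK binding is available in R; the ASCII subset used here is
# deliberately small (tetrahedra, one integer and one 3-vector cell array).

#' Write a labeled mesh as ASCII VTK XML (.vtu)
#'
#' Cell data arrays: `tissue_class` (Int32: 0 healthy, 1 BZ, 2 scar) and
#' `fiber` (3-component Float64). Coordinates in cm.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  num <- function(x) paste(formatC(x, digits = 10, format = "g"),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", paste(t(mesh$elems) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", paste(seq_len(m) * 4L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(rep(10L, m), collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData Scalars="tissue_class">')
  w('        <DataArray type="Int32" Name="tissue_class" format="ascii">')
  w("          ", paste(mesh$tissue, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Float64" Name="fiber" NumberOfComponents="3" format="ascii">')
  w("          ", num(t(mesh$fiber)))
  w('        </DataArray>')
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a labeled mesh from an ASCII .vtu file
#'
#' Reads files written by [write_vtu()] (tetrahedral cells, `tissue_class`
#' and `fiber` cell arrays).
#'
#' @param path file path.
#' @param patient_id,resolution_tag,extent metadata not stored in the file.
#' @return a [labeled_mesh()].
#' @export
read_vtu <- function(path, patient_id = "patient", resolution_tag = NA,
                     extent = NULL) {
  doc <- xml2::read_xml(path)
  arr <- function(xpath) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing")) stop("missing array: ", xpath)
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- arr(".//Points/DataArray")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  types <- arr(".//Cells/DataArray[@Name='types']")
  if (!all(types == 10)) stop("only tetrahedral (.vtu type 10) cells supported")
  conn <- arr(".//Cells/DataArray[@Name='connectivity']")
  elems <- matrix(as.integer(conn) + 1L, ncol = 4, byrow = TRUE)
  tissue <- as.integer(arr(".//CellData/DataArray[@Name='tissue_class']"))
  fib <- matrix(arr(".//CellData/DataArray[@Name='fiber']"), ncol = 3,
                byrow = TRUE)
  labeled_mesh(nodes, elems, tissue, fib, patient_id = patient_id,
               resolution_tag = resolution_tag, extent = extent)
}

#' Write a cohort to disk (.vtu meshes + JSON manifest)
#'
#' One mesh file per patient per resolution plus `cohort_manifest.json`
#' recording specs, seeds and file paths.
#'
#' @param specs list of [patient_spec()].
#' @param edge_lengths one or more target edge lengths, cm.
#' @param dir output directory (created if needed).
#' @return manifest list, invisibly.
#' @export
write_cohort <- function(specs, edge_lengths, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(specs, function(sp) {
    files <- vapply(edge_lengths, function(h) {
      mesh <- generate_patient(sp, h)
      f <- file.path(dir, sprintf("%s_h%s.vtu", sp$patient_id,
                                  formatC(h, format = "g")))
      write_vtu(mesh, f)
      f
    }, character(1))
    c(unclass(sp), list(files = files))
  })
  manifest <- list(n_patients = length(specs), edge_lengths = edge_lengths,
                   patients = entries)
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
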