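#' Write a field snapshot to disk
#'
#' Exports a simulation snapshot (an element of
#' `simulate_eye_disc(...)$snapshots`) either as a flat CSV of nodes and
#' nodal fields, or as a legacy ASCII VTK unstructured-grid file with
#' the concentration and indicator fields attached as point data, for
#' inspection in standard mesh viewers.
#'
#' @param snapshot list with `nodes`, `tri`, `fields` and optionally
#'   `ind` (as produced by the simulator).
#' @param file output path.
#' @param format `"csv"` or `"vtk"`.
#' @return `file`, invisibly.
#' @export
write_snapshot <- function(snapshot, file, format = c("csv", "vtk")) {
  format <- match.arg(format)
  nodes <- snapshot$nodes
  fields <- c(snapshot$fields, snapshot$ind)
  if (format == "csv") {
    df <- data.frame(node = seq_len(nrow(nodes)),
                     x = nodes[, 1], y = nodes[, 2])
    for (nm in names(fields)) df[[nm]] <- fields[[nm]]
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(file))
  }
  tri <- snapshot$tri
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "eyedisc snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(nodes))), con)
  writeLines(sprintf("%.6g %.6g 0", nodes[, 1], nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tri), 4 * nrow(tri)), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tri)), con)
  writeLines(rep("5", nrow(tri)), con)        # VTK_TRIANGLE
  writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6g", fields[[nm]]), con)
  }
  invisible(file)
}
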