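# Gmsh MSH v2.2 ASCII I/O (tetrahedral elements with physical-group
# labels) and legacy-VTK export for 3-D viewing.  Node and element ids
# are 1-based in the files, matching the dialect.

#' Write a mesh as Gmsh MSH v2.2 ASCII
#'
#' Tets are written as element type 4 with their physical-group id; label
#' names go into `$PhysicalNames`.  Per-electrode distal node sets are
#' generator metadata and are not representable in plain MSH; re-derive
#' them by placing electrodes after reading if needed.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @export
write_msh <- function(mesh, path) {
  labs <- sort(unique(mesh$labels))
  lab_id <- seq_along(labs)
  names(lab_id) <- labs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(labs)), con)
  writeLines(sprintf("3 %d \"%s\"", lab_id, labs), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  writeLines(as.character(nrow(mesh$tets)), con)
  ids <- lab_id[mesh$labels]
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(mesh$tets)),
                     ids, ids, mesh$tets[, 1], mesh$tets[, 2],
                     mesh$tets[, 3], mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2.2 ASCII mesh
#'
#' Only tetrahedral elements (type 4) are imported; labels come from
#' `$PhysicalNames` when present, else the physical tag number.  The
#' reader validates the mesh (positive volumes after orientation fixing,
#' no orphan nodes) and rejects invalid files.
#'
#' @param path MSH file path.
#' @return a `tet_mesh` (nodes in the file's units, expected mm).
#' @export
read_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(tag) {
    i <- match(paste0("$", tag), ln)
    j <- match(paste0("$End", tag), ln)
    if (is.na(i) || is.na(j)) return(NULL)
    ln[(i + 1):(j - 1)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "2.2")) {
    abort("unsupported MSH version (need 2.2 ASCII)")
  }
  names_sec <- sec("PhysicalNames")
  phys <- NULL
  if (!is.null(names_sec)) {
    nn <- as.integer(names_sec[1])
    if (nn > 0) {
      parts <- strsplit(names_sec[1 + seq_len(nn)], " ")
      phys <- vapply(parts, function(p) gsub('"', "", paste(p[-(1:2)], collapse = " ")), "")
      names(phys) <- vapply(parts, `[[`, "", 2)
    }
  }
  nodes_sec <- sec("Nodes")
  n <- as.integer(nodes_sec[1])
  nm <- matrix(scan(text = nodes_sec[1 + seq_len(n)], quiet = TRUE), ncol = 4, byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el_sec <- sec("Elements")
  m <- as.integer(el_sec[1])
  rows <- strsplit(el_sec[1 + seq_len(m)], " +")
  keep <- vapply(rows, function(r) r[2] == "4", TRUE)
  if (!any(keep)) abort("no tetrahedral elements in %s", path)
  tets <- t(vapply(rows[keep], function(r) {
    ntags <- as.integer(r[3])
    as.integer(r[(3 + ntags + 1):(3 + ntags + 4)])
  }, integer(4)))
  tag <- vapply(rows[keep], function(r) r[4], "")
  labels <- if (!is.null(phys)) unname(phys[tag]) else tag
  labels[is.na(labels)] <- tag[is.na(labels)]
  tets <- orient_tets(nodes, tets)
  mesh <- new_tet_mesh(nodes, tets, labels, meta = list(kind = "external", source = path))
  validate_mesh(mesh)
}

#' Write a mesh (or a per-element scalar map) as legacy VTK
#'
#' ASCII `UNSTRUCTURED_GRID`, optionally with one `CELL_DATA` scalar
#' array (e.g. a field amplitude or phase map on the cortical surface).
#'
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @param cell_scalars optional numeric vector, one value per tet.
#' @param scalar_name name of the scalar array.
#' @export
write_vtk <- function(mesh, path, cell_scalars = NULL, scalar_name = "label") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(mesh$nodes)), con)
  writeLines(sprintf("%.8g %.8g %.8g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, m * 5), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  if (is.null(cell_scalars)) {
    cell_scalars <- as.integer(factor(mesh$labels))
  }
  writeLines(sprintf("SCALARS %s double 1", scalar_name), con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(sprintf("%.8g", cell_scalars), con)
  invisible(path)
}
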