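# Tetrahedral mesh container and the layered-sphere phantom generator.
#
# The phantom is a structured mesh: an icosphere triangulation replicated on
# concentric node shells, with every tissue interface placed exactly at its
# nominal radius.  Triangular prisms between consecutive shells are split
# into three tetrahedra with globally consistent diagonals (smallest-vertex
# rule), so the mesh is conforming by construction.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  # enforce outward (counter-clockwise seen from outside) orientation
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    if (sum(crossprod3(b - a, c3 - a) * (a + b + c3)) < 0) {
      f[i, 2:3] <- f[i, 3:2]
    }
  }
  list(vertices = v, faces = f)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# vectorized cross product of row-matrices
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

subdivide_sphere <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- e[, 1] * (nrow(v) + 1) + e[, 2]
  first <- !duplicated(key)
  ue <- e[first, , drop = FALSE]
  mid_id <- match(key, key[first]) + nrow(v)
  mid <- normalize_rows((v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2)
  n <- nrow(f)
  m12 <- mid_id[seq_len(n)]
  m23 <- mid_id[n + seq_len(n)]
  m31 <- mid_id[2 * n + seq_len(n)]
  list(
    vertices = rbind(v, mid),
    faces = rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  )
}

icosphere <- function(level) {
  s <- icosahedron()
  for (i in seq_len(level)) s <- subdivide_sphere(s$vertices, s$faces)
  s
}

# Split the prisms over triangles `f` between node layers offset lo (bottom)
# and hi (top) into 3 tets each, diagonals chosen through the smallest
# vertex id of each quad face so adjacent prisms always agree.
prisms_to_tets <- function(f, lo, hi) {
  # rotate each triangle so its smallest vertex id comes first
  rot1 <- f[, 2] < f[, 1] & f[, 2] <= f[, 3]
  rot2 <- f[, 3] < f[, 1] & f[, 3] < f[, 2]
  g <- f
  g[rot1, ] <- f[rot1, c(2, 3, 1), drop = FALSE]
  g[rot2, ] <- f[rot2, c(3, 1, 2), drop = FALSE]
  v1 <- g[, 1] + lo; v2 <- g[, 2] + lo; v3 <- g[, 3] + lo
  v4 <- g[, 1] + hi; v5 <- g[, 2] + hi; v6 <- g[, 3] + hi
  case1 <- g[, 2] < g[, 3]
  t1 <- cbind(v1, v2, v3, ifelse(case1, v6, v5))
  t2 <- cbind(v1, ifelse(case1, v2, v5), ifelse(case1, v6, v3), ifelse(case1, v5, v6))
  t3 <- cbind(v1, v5, v6, v4)
  rbind(t1, t2, t3)
}

#' Signed tetrahedron volumes
#'
#' @param nodes numeric matrix of node coordinates (rows).
#' @param tets integer matrix of 4 node indices per row.
#' @return numeric vector of signed volumes (positive for the package's
#'   orientation convention), in the cube of the node coordinate unit.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c3 <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  rowSums(rowcross(b, c3) * d) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3), drop = FALSE]
  tets
}

new_tet_mesh <- function(nodes, tets, labels, meta = list()) {
  structure(
    list(nodes = nodes, tets = tets, labels = labels,
         electrodes = list(), meta = meta),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("Tetrahedral mesh: %d nodes, %d tets\n",
              nrow(x$nodes), nrow(x$tets)))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (length(x$electrodes)) {
    cat(sprintf("  electrodes: %d (%s...)\n", length(x$electrodes),
                paste(utils::head(names(x$electrodes), 5), collapse = ", ")))
  }
  invisible(x)
}

#' Validate a tetrahedral mesh
#'
#' Checks strictly positive tet volumes, absence of orphan nodes and that
#' every label is known to the supplied tissue table (if given).
#'
#' @param mesh a `tet_mesh`.
#' @param tissue optional [tissue_table()] whose labels must cover the mesh.
#' @return the mesh, invisibly; errors describe the first violation found.
#' @export
validate_mesh <- function(mesh, tissue = NULL) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) {
    abort("mesh has %d non-positive-volume tets (first: tet %d)",
          sum(v <= 0), which(v <= 0)[1])
  }
  used <- unique(as.vector(mesh$tets))
  if (length(used) < nrow(mesh$nodes)) {
    abort("mesh has %d orphan nodes", nrow(mesh$nodes) - length(used))
  }
  if (!is.null(tissue)) {
    unknown <- setdiff(unique(mesh$labels), names(tissue))
    if (length(unknown)) {
      abort("labels without a conductivity: %s", paste(unknown, collapse = ", "))
    }
  }
  invisible(mesh)
}

#' Build a layered-sphere head phantom
#'
#' Generates a conforming labeled tetrahedral mesh of nested concentric
#' spheres, a parametric stand-in for an MRI-derived head model.  Every
#' tissue interface is meshed exactly at its nominal radius; the innermost
#' label fills the remaining ball down to the centre.  The default
#' four-layer configuration (92/88/83/80 mm, scalp/skull/CSF/brain)
#' approximates adult head proportions.
#'
#' @param layer_radii numeric vector of interface radii in mm, strictly
#'   decreasing outer to inner.  Layer `i` occupies the shell between
#'   `layer_radii[i]` and `layer_radii[i+1]`; the last layer is solid.
#' @param labels character vector of tissue labels, one per layer.
#'   Defaults to `c("scalp","skull","csf","brain")` for four layers and to
#'   `layer1..layerN` otherwise.
#' @param target_edge_length target element edge length in mm; controls the
#'   angular subdivision of the sphere and the radial spacing inside thick
#'   layers.  Thin layers are always resolved by at least one radial
#'   element because interfaces carry their own node shells.
#' @param seed integer kept for interface stability; the construction is
#'   fully deterministic, so any seed yields the identical mesh.
#' @return a `tet_mesh` with nodes in mm, 0-based-free (1-based) tet
#'   indices, per-tet labels and generator metadata.
#' @examples
#' m <- build_layered_sphere(c(46, 44, 41.5, 40), target_edge_length = 12)
#' m
#' @export
build_layered_sphere <- function(layer_radii,
                                 labels = NULL,
                                 target_edge_length = 8,
                                 seed = 1L) {
  r <- as.numeric(layer_radii)
  if (length(r) < 1 || any(!is.finite(r)) || any(r <= 0)) {
    abort("layer_radii must be positive and finite")
  }
  if (length(r) > 1 && any(diff(r) >= 0)) {
    abort("layer_radii must be strictly decreasing (outer to inner)")
  }
  h <- target_edge_length
  if (!is.finite(h) || h <= 0 || h >= r[1] / 2) {
    abort("target_edge_length %.3g mm cannot resolve a sphere of radius %.3g mm",
          h, r[1])
  }
  if (is.null(labels)) {
    labels <- if (length(r) == 4) c("scalp", "skull", "csf", "brain")
              else paste0("layer", seq_along(r))
  }
  if (length(labels) != length(r)) abort("need one label per layer")
  if (anyDuplicated(labels)) abort("layer labels must be unique")

  level <- max(2L, as.integer(ceiling(log2(1.0515 * r[1] / h))))
  sph <- icosphere(level)
  nv <- nrow(sph$vertices)

  # radial node shells: every interface exactly, thick spans subdivided,
  # then graded shells inside the innermost ball down to a small core
  shells <- r[1]
  shell_label <- character(0)
  for (i in seq_along(r)) {
    r_out <- r[i]
    r_in <- if (i < length(r)) r[i + 1] else NA
    if (!is.na(r_in)) {
      k <- max(1L, round((r_out - r_in) / h))
      shells <- c(shells, r_out - (r_out - r_in) * seq_len(k) / k)
      shell_label <- c(shell_label, rep(labels[i], k))
    } else {
      # solid core: uniform spacing h until the shells get small
      rr <- r_out
      repeat {
        nxt <- rr - h
        if (nxt <= 1.35 * h) break
        shells <- c(shells, nxt)
        shell_label <- c(shell_label, labels[i])
        rr <- nxt
      }
      shell_label <- c(shell_label, labels[i]) # core slab to the centre
    }
  }
  nl <- length(shells)

  nodes <- matrix(0, nl * nv + 1L, 3)
  for (k in seq_len(nl)) {
    nodes[(k - 1L) * nv + seq_len(nv), ] <- sph$vertices * shells[k]
  }
  centre <- nl * nv + 1L # last node is the centre (coordinates 0,0,0)

  tet_list <- vector("list", nl)
  lab_list <- vector("list", nl)
  for (k in seq_len(nl - 1L)) {
    tt <- prisms_to_tets(sph$faces, lo = (k - 1L) * nv, hi = k * nv)
    tet_list[[k]] <- tt
    lab_list[[k]] <- rep(shell_label[k], nrow(tt))
  }
  core <- cbind(centre, sph$faces[, 1] + (nl - 1L) * nv,
                sph$faces[, 2] + (nl - 1L) * nv,
                sph$faces[, 3] + (nl - 1L) * nv)
  tet_list[[nl]] <- core
  lab_list[[nl]] <- rep(shell_label[nl], nrow(core))

  tets <- do.call(rbind, tet_list)
  storage.mode(tets) <- "integer"
  tets <- orient_tets(nodes, tets)
  mesh <- new_tet_mesh(
    nodes, tets, unlist(lab_list),
    meta = list(
      kind = "layered_sphere", radii = r, layer_labels = labels,
      level = level, edge = h, n_surface_vertices = nv,
      shells = shells
    )
  )
  validate_mesh(mesh)
}

#' Boundary triangles of a mesh
#'
#' Faces that belong to exactly one tetrahedron, oriented outward.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `faces` (node triples), `owner` (tet index),
#'   `normals`, `areas` (mm^2) and `centroids` (mm).
#' @export
boundary_faces <- function(mesh) {
  fc <- all_faces(mesh$tets)
  once <- !(duplicated(fc$key) | duplicated(fc$key, fromLast = TRUE))
  orient_interface(mesh, fc$faces[once, , drop = FALSE], fc$tet[once])
}

# all 4 faces of every tet with a sortable numeric key
all_faces <- function(tets) {
  m <- nrow(tets)
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  tet <- rep(seq_len(m), 4)
  srt <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
               f[, 1] + f[, 2] + f[, 3] -
                 pmin(f[, 1], f[, 2], f[, 3]) - pmax(f[, 1], f[, 2], f[, 3]),
               pmax(f[, 1], f[, 2], f[, 3]))
  n <- max(tets) + 1
  key <- (srt[, 1] * n + srt[, 2]) * n + srt[, 3]
  list(faces = f, tet = tet, key = key, sorted = srt)
}

# orient triangle faces so their normal points away from the owning tet
orient_interface <- function(mesh, faces, owner) {
  a <- mesh$nodes[faces[, 1], , drop = FALSE]
  b <- mesh$nodes[faces[, 2], , drop = FALSE]
  c3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  nrm <- rowcross(b - a, c3 - a)
  cent <- (a + b + c3) / 3
  tc <- (mesh$nodes[mesh$tets[owner, 1], , drop = FALSE] +
         mesh$nodes[mesh$tets[owner, 2], , drop = FALSE] +
         mesh$nodes[mesh$tets[owner, 3], , drop = FALSE] +
         mesh$nodes[mesh$tets[owner, 4], , drop = FALSE]) / 4
  flip <- rowSums(nrm * (cent - tc)) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2), drop = FALSE]
  nrm[flip, ] <- -nrm[flip, ]
  area2 <- sqrt(rowSums(nrm^2))
  list(
    faces = faces, owner = owner,
    normals = nrm / area2, areas = area2 / 2, centroids = cent
  )
}
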