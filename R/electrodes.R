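# Electrode placement: sponge electrodes are meshed as outward extrusions
# of a patch of scalp boundary triangles whose total area approximates the
# disc footprint.  The distal (outermost) copy of the footprint nodes is
# recorded per electrode; Dirichlet boundary conditions are applied there.

#' Attach electrodes to a mesh
#'
#' For every row of `layout`, selects the patch of outer boundary triangles
#' around the electrode direction whose summed area best matches the disc
#' area `pi * radius_mm^2`, then extrudes it outward along the local
#' surface normal by `height_mm` (in radial sub-layers), labelling the new
#' tets `"electrode"`.  A zero radius selects the single nearest boundary
#' node instead (point electrode, no volume) — useful for comparisons with
#' analytic point-source solutions.  Footprints follow the curved scalp
#' (curved-cap convention, recorded in metadata).
#'
#' @param mesh a `tet_mesh` without previously placed electrodes of the
#'   same names.
#' @param layout an `electrode_layout` (see [layout_1010_61()]); an empty
#'   layout returns the mesh unchanged.
#' @return the augmented `tet_mesh`; `mesh$electrodes` maps each name to
#'   its distal-face node set, footprint triangles and footprint area.
#' @examples
#' m <- build_layered_sphere(c(46, 44, 41.5, 40), target_edge_length = 12)
#' m <- place_electrodes(m, layout_parietal8(height_mm = 12))
#' names(m$electrodes)
#' @export
place_electrodes <- function(mesh, layout) {
  if (nrow(layout) == 0) return(mesh)
  clash <- intersect(layout$name, names(mesh$electrodes))
  if (length(clash)) abort("electrodes already placed: %s", paste(clash, collapse = ", "))
  bnd <- boundary_faces(mesh)
  cent_dir <- normalize_rows(bnd$centroids)
  # per-node outward normal, averaged over adjacent boundary faces
  bnodes <- unique(as.vector(bnd$faces))
  node_nrm <- matrix(0, nrow(mesh$nodes), 3)
  for (k in 1:3) {
    for (cc in 1:3) {
      node_nrm[, cc] <- node_nrm[, cc] +
        tabulate2(bnd$faces[, k], bnd$normals[, cc], nrow(mesh$nodes))
    }
  }
  nn <- sqrt(rowSums(node_nrm^2))
  node_nrm[bnodes, ] <- node_nrm[bnodes, ] / nn[bnodes]

  claimed <- rep(NA_character_, nrow(bnd$faces))
  edge_est <- sqrt(mean(bnd$areas) * 4 / sqrt(3))

  nodes <- mesh$nodes
  add_tets <- list(); add_lab <- list()
  electrodes <- list()
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]
    d <- normalize_rows(matrix(as.numeric(layout[i, c("x", "y", "z")]), 1))[1, ]
    r_e <- layout$radius_mm[i]
    h_e <- layout$height_mm[i]

    if (r_e == 0) {
      # point electrode: nearest boundary node, no volume
      nd <- normalize_rows(mesh$nodes[bnodes, , drop = FALSE])
      j <- bnodes[which.max(nd %*% d)]
      electrodes[[nm]] <- list(
        distal_nodes = j, footprint_faces = integer(0),
        footprint_area = 0, direction = d, height_mm = 0, contact = "point"
      )
      next
    }

    cosang <- as.vector(cent_dir %*% d)
    ord <- order(cosang, decreasing = TRUE)
    disc <- pi * r_e^2
    cum <- cumsum(bnd$areas[ord])
    k <- which(cum >= disc)[1]
    if (is.na(k)) k <- length(ord)
    if (k > 1 && abs(cum[k - 1] - disc) < abs(cum[k] - disc)) k <- k - 1
    sel <- ord[seq_len(k)]
    hit <- !is.na(claimed[sel])
    if (any(hit)) {
      abort("electrode %s footprint overlaps %s", nm, claimed[sel][hit][1])
    }
    claimed[sel] <- nm
    foot_faces <- bnd$faces[sel, , drop = FALSE]
    foot_nodes <- unique(as.vector(foot_faces))

    if (h_e == 0) {
      electrodes[[nm]] <- list(
        distal_nodes = foot_nodes, footprint_faces = sel,
        footprint_area = sum(bnd$areas[sel]), direction = d,
        height_mm = 0, contact = "surface-cap"
      )
      next
    }

    n_h <- max(2L, min(4L, round(h_e / edge_est)))
    base_id <- nrow(nodes)
    # extruded node columns: layer l = 1..n_h above each footprint node
    new_nodes <- do.call(rbind, lapply(seq_len(n_h), function(l) {
      mesh$nodes[foot_nodes, , drop = FALSE] +
        node_nrm[foot_nodes, , drop = FALSE] * (h_e * l / n_h)
    }))
    nodes <- rbind(nodes, new_nodes)
    # local ids: layer 0 = scalp nodes themselves
    loc <- function(l) {
      if (l == 0) foot_nodes else base_id + (l - 1L) * length(foot_nodes) + seq_along(foot_nodes)
    }
    fl <- matrix(match(foot_faces, foot_nodes), ncol = 3)
    for (l in seq_len(n_h)) {
      lo_ids <- loc(l - 1L); hi_ids <- loc(l)
      # per-layer maps share the footprint-node ordering, so the
      # smallest-vertex diagonal rule stays consistent inside the patch
      tt_loc <- prisms_to_tets(fl, lo = 0L, hi = length(foot_nodes))
      tt <- matrix(c(lo_ids, hi_ids)[tt_loc], ncol = 4)
      add_tets[[length(add_tets) + 1L]] <- tt
      add_lab[[length(add_lab) + 1L]] <- rep("electrode", nrow(tt))
    }
    electrodes[[nm]] <- list(
      distal_nodes = loc(n_h), footprint_faces = sel,
      footprint_area = sum(bnd$areas[sel]), direction = d,
      height_mm = h_e, contact = "curved-cap"
    )
  }

  if (length(add_tets)) {
    tets <- rbind(mesh$tets, do.call(rbind, add_tets))
    storage.mode(tets) <- "integer"
    tets <- orient_tets(nodes, tets)
    labels <- c(mesh$labels, unlist(add_lab))
  } else {
    tets <- mesh$tets; labels <- mesh$labels
  }
  out <- new_tet_mesh(nodes, tets, labels, meta = mesh$meta)
  out$electrodes <- c(mesh$electrodes, electrodes)
  # distal node sets must be pairwise disjoint
  all_d <- unlist(lapply(out$electrodes, `[[`, "distal_nodes"))
  if (anyDuplicated(all_d)) abort("electrode distal node sets overlap")
  validate_mesh(out)
}

# sum `val` into bins `idx` (sparse tabulate with weights)
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
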