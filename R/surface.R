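# Cortical surface extraction and geodesic-cap ROI patches.

#' Extract the cortical surface from a labeled mesh
#'
#' Collects the triangular faces separating tets carrying `cortical_label`
#' from tets of any other label (or from the mesh exterior), oriented with
#' the outward normal pointing away from the cortical compartment (grey
#' matter toward CSF).  Each triangle keeps a pointer to its owning
#' cortical tet; the forward solver evaluates the normal field component
#' there.
#'
#' @param mesh a `tet_mesh`.
#' @param cortical_label tissue label of the cortical compartment
#'   (default `"brain"`, the phantom's single brain compartment).
#' @return a `cortical_surface`: list with `faces`, `owner` (tet index),
#'   `normals` (unit, outward), `areas` (mm^2), `centroids` (mm) and the
#'   source mesh dimensions for later consistency checks.
#' @export
extract_cortical_surface <- function(mesh, cortical_label = "brain") {
  if (!cortical_label %in% mesh$labels) {
    abort("label '%s' not present in mesh", cortical_label)
  }
  fc <- all_faces(mesh$tets)
  is_cort <- mesh$labels[fc$tet] == cortical_label
  ord <- order(fc$key)
  key_s <- fc$key[ord]
  n <- length(key_s)
  same_next <- c(key_s[-1] == key_s[-n], FALSE)
  same_prev <- c(FALSE, same_next[-n])
  # twin[i]: face instance sharing the same node triple (NA on the boundary)
  mate <- rep(NA_integer_, n)
  mate[same_next] <- ord[which(same_next) + 1L]
  mate[same_prev] <- ord[which(same_prev) - 1L]
  twin <- rep(NA_integer_, n)
  twin[ord] <- mate
  other_cort <- rep(FALSE, n)
  has <- !is.na(twin)
  other_cort[has] <- is_cort[twin[has]]
  keep <- is_cort & !other_cort
  faces <- fc$faces[keep, , drop = FALSE]
  owner <- fc$tet[keep]
  surf <- orient_interface(mesh, faces, owner)
  structure(
    list(faces = surf$faces, owner = owner, normals = surf$normals,
         areas = surf$areas, centroids = surf$centroids,
         label = cortical_label,
         mesh_nodes = nrow(mesh$nodes), mesh_tets = nrow(mesh$tets)),
    class = "cortical_surface"
  )
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("Cortical surface ('%s'): %d triangles, total area %.1f mm^2\n",
              x$label, nrow(x$faces), sum(x$areas)))
  invisible(x)
}

#' Define a geodesic-cap ROI patch on the cortical surface
#'
#' Selects the cortical triangles whose centroid direction (from the head
#' centre) lies within `angular_radius_deg` of `center_direction` — a
#' spherical-cap stand-in for manual ROI segmentation.
#'
#' @param surface a `cortical_surface`.
#' @param center_direction length-3 vector; only its direction is used.
#' @param angular_radius_deg cap radius in degrees, in (0, 90].
#' @param name ROI name.
#' @return an `roi_patch`: list with `name`, `elements` (triangle indices
#'   into the surface), `area` (mm^2) and definition metadata.
#' @export
define_roi_patch <- function(surface, center_direction, angular_radius_deg, name) {
  if (!is.finite(angular_radius_deg) ||
      angular_radius_deg <= 0 || angular_radius_deg > 90) {
    abort("angular_radius_deg must be in (0, 90]")
  }
  d <- center_direction / sqrt(sum(center_direction^2))
  cd <- normalize_rows(surface$centroids)
  sel <- which(as.vector(cd %*% d) >= cos(deg2rad(angular_radius_deg)))
  if (!length(sel)) abort("ROI '%s' selects no cortical elements", name)
  roi_patch(name, sel, surface,
            meta = list(center = d, angular_radius_deg = angular_radius_deg))
}

#' Construct an ROI patch from explicit element indices
#'
#' @param name ROI name.
#' @param elements integer triangle indices into `surface`.
#' @param surface the `cortical_surface` the indices refer to.
#' @param meta optional definition metadata.
#' @return an `roi_patch`.
#' @export
roi_patch <- function(name, elements, surface, meta = list()) {
  elements <- as.integer(elements)
  if (!length(elements)) abort("ROI '%s' is empty", name)
  if (any(elements < 1 | elements > nrow(surface$faces))) {
    abort("ROI '%s' has element indices outside the surface", name)
  }
  structure(
    list(name = name, elements = unique(elements),
         area = sum(surface$areas[unique(elements)]), meta = meta),
    class = "roi_patch"
  )
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("ROI '%s': %d elements, area %.1f mm^2\n",
              x$name, length(x$elements), x$area))
  invisible(x)
}

#' Read ROI definitions from JSON
#'
#' Accepts a JSON array of objects with `name` plus either `center`
#' (length-3 direction) and `angular_radius_deg`, or an explicit
#' `elements` index list.
#'
#' @param path JSON file.
#' @param surface the `cortical_surface` the ROIs live on.
#' @return named list of `roi_patch` objects.
#' @export
read_roi_json <- function(path, surface) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(spec, function(s) {
    if (!is.null(s$elements)) {
      roi_patch(s$name, unlist(s$elements), surface)
    } else {
      define_roi_patch(surface, unlist(s$center), s$angular_radius_deg, s$name)
    }
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
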