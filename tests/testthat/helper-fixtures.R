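# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small four-layer phantom for unit tests (half-scale head, coarse)
small_phantom <- function() fixture("small_phantom", function() {
  m <- build_layered_sphere(c(46, 44, 41.5, 40), target_edge_length = 6)
  place_electrodes(m, layout_parietal8(height_mm = 12))
})

small_surface <- function() fixture("small_surface", function() {
  extract_cortical_surface(small_phantom(), "brain")
})

small_system <- function() fixture("small_system", function() {
  assemble_system(small_phantom(), tissue_table())
})

small_leadfield <- function() fixture("small_leadfield", function() {
  build_leadfield(small_phantom(), tissue_table(),
                  surface = small_surface(), active = "Pz")
})

# full-scale study phantom: 92/88/83/80 mm, edge 8 mm, 61 electrodes
study_mesh <- function() fixture("study_mesh", function() {
  m <- build_layered_sphere(c(92, 88, 83, 80), target_edge_length = 8)
  place_electrodes(m, layout_1010_61())
})

study_surface <- function() fixture("study_surface", function() {
  extract_cortical_surface(study_mesh(), "brain")
})

study_leadfield <- function() fixture("study_leadfield", function() {
  build_leadfield(study_mesh(), tissue_table(), surface = study_surface())
})

# bilateral parietal 15-degree caps (the bilateral-IPS study geometry)
parietal_rois <- function() fixture("parietal_rois", function() {
  s <- study_surface()
  list(
    lIPS = define_roi_patch(s, c(-0.5, -0.5, 0.72), 15, "lIPS"),
    rIPS = define_roi_patch(s, c(0.5, -0.5, 0.72), 15, "rIPS")
  )
})

# homogeneous brain-conductivity sphere with antipodal cap electrodes,
# for comparison against the analytic series solution
oracle_sphere <- function(edge = 10) {
  fixture(paste0("oracle_sphere_", edge), function() {
    m <- build_layered_sphere(80, labels = "brain", target_edge_length = edge)
    lay <- structure(
      data.frame(name = c("top", "bottom"),
                 x = c(0, 0), y = c(0, 0), z = c(1, -1),
                 radius_mm = 4, height_mm = 0),
      class = c("electrode_layout", "data.frame")
    )
    place_electrodes(m, lay)
  })
}

# FEM-vs-analytic relative L2 discrepancy of the surface potential,
# evaluated away from the electrode caps
oracle_discrepancy <- function(edge = 10, exclude_deg = 30) {
  mesh <- oracle_sphere(edge)
  sys <- assemble_system(mesh, tissue_table())
  ps <- solve_pair(sys, "top", "bottom")
  r <- sqrt(rowSums(mesh$nodes^2))
  on_surf <- which(abs(r - 80) < 1e-6)
  ang <- rad2deg_(acos(pmin(1, abs(mesh$nodes[on_surf, 3]) / 80)))
  keep <- on_surf[ang > exclude_deg]
  va <- sphere_pair_potential(mesh$nodes[keep, , drop = FALSE], 80,
                              tissue_table()[["brain"]],
                              c(0, 0, 1), c(0, 0, -1))
  vf <- ps$V[keep]
  vf <- vf - mean(vf)
  va <- va - mean(va)
  sqrt(sum((vf - va)^2) / sum(va^2))
}

rad2deg_ <- function(x) x * 180 / pi
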