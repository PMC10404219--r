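test_that("layered-sphere phantom reproduces analytic shell volumes and nesting", {
  m <- study_mesh()
  v <- tet_volumes(m$nodes, m$tets)
  expect_true(all(v > 0))
  shell <- function(r1, r2) 4 / 3 * pi * (r1^3 - r2^3)
  analytic <- c(scalp = shell(92, 88), skull = shell(88, 83),
                csf = shell(83, 80), brain = 4 / 3 * pi * 80^3)
  got <- tapply(v, m$labels, sum)[names(analytic)]
  expect_true(all(abs(got / analytic - 1) < 0.10))
  # label nesting: every skull tet centroid sits between the CSF and scalp radii
  sk <- m$labels == "skull"
  cent <- (m$nodes[m$tets[sk, 1], ] + m$nodes[m$tets[sk, 2], ] +
             m$nodes[m$tets[sk, 3], ] + m$nodes[m$tets[sk, 4], ]) / 4
  rc <- sqrt(rowSums(cent^2))
  expect_true(all(rc > 83 & rc < 88))
  # no orphan nodes
  expect_identical(length(unique(as.vector(m$tets))), nrow(m$nodes))
})

test_that("single-layer phantom carries one label and the build is deterministic", {
  m1 <- build_layered_sphere(30, labels = "brain", target_edge_length = 8, seed = 5)
  expect_identical(unique(m1$labels), "brain")
  m2 <- build_layered_sphere(30, labels = "brain", target_edge_length = 8, seed = 5)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
})

test_that("generator rejects bad radii and hopeless edge lengths", {
  expect_error(build_layered_sphere(c(80, 85)), "decreasing")
  expect_error(build_layered_sphere(c(92, 88), target_edge_length = 60),
               "resolve")
})

test_that("electrode placement yields disjoint distal sets and disc-sized footprints", {
  m <- study_mesh()
  expect_length(m$electrodes, 61)
  all_distal <- unlist(lapply(m$electrodes, `[[`, "distal_nodes"))
  expect_identical(anyDuplicated(all_distal), 0L)
  areas <- vapply(m$electrodes, `[[`, 0, "footprint_area")
  expect_true(all(abs(areas / (pi * 5^2) - 1) < 0.20))
  # empty layout leaves the mesh unchanged
  m0 <- build_layered_sphere(30, labels = "brain", target_edge_length = 8)
  lay0 <- layout_1010_61()[0, ]
  expect_identical(place_electrodes(m0, lay0), m0)
})

test_that("overlapping electrode footprints are rejected", {
  m0 <- build_layered_sphere(30, labels = "brain", target_edge_length = 8)
  lay <- layout_parietal8(height_mm = 10)[1:2, ]
  lay[2, c("x", "y", "z")] <- lay[1, c("x", "y", "z")] # same direction
  lay$name <- c("E1", "E2")
  expect_error(place_electrodes(m0, lay), "overlaps")
})

test_that("cortical surface is the closed grey/CSF interface with outward normals", {
  s <- study_surface()
  expect_lt(abs(sum(s$areas) / (4 * pi * 80^2) - 1), 0.05)
  radial <- rowSums(s$normals * s$centroids / sqrt(rowSums(s$centroids^2)))
  expect_true(all(radial > 0))
  expect_true(all(abs(sqrt(rowSums(s$normals^2)) - 1) < 1e-9))
  # two-layer phantom: triangle count equals the icosphere face count
  m2 <- build_layered_sphere(c(30, 25), labels = c("scalp", "brain"),
                             target_edge_length = 7)
  s2 <- extract_cortical_surface(m2, "brain")
  expect_equal(nrow(s2$faces), 20 * 4^m2$meta$level)
  expect_error(extract_cortical_surface(m2, "liver"), "not present")
})

test_that("geodesic cap ROIs match spherical-cap areas and stay disjoint", {
  s <- study_surface()
  roi <- define_roi_patch(s, c(1, 0, 0), 15, "cap")
  cap_area <- 2 * pi * 80^2 * (1 - cos(15 * pi / 180))
  expect_lt(abs(roi$area / cap_area - 1), 0.15)
  roi2 <- define_roi_patch(s, c(-1, 0, 0), 15, "anticap")
  expect_length(intersect(roi$elements, roi2$elements), 0)
  expect_error(define_roi_patch(s, c(1, 0, 0), 0, "null"), "angular_radius")
})

test_that("MSH v2.2 round trip preserves node count and per-tet labels", {
  m <- build_layered_sphere(c(30, 25), labels = c("scalp", "brain"),
                            target_edge_length = 8)
  path <- tempfile(fileext = ".msh")
  write_msh(m, path)
  m2 <- read_msh(path)
  expect_identical(nrow(m2$nodes), nrow(m$nodes))
  expect_identical(m2$labels, m$labels)
  expect_equal(tet_volumes(m2$nodes, m2$tets), abs(tet_volumes(m$nodes, m$tets)),
               tolerance = 1e-6)
  unlink(path)
})

test_that("VTK export writes a well-formed unstructured grid", {
  m <- build_layered_sphere(25, labels = "brain", target_edge_length = 9)
  path <- tempfile(fileext = ".vtk")
  write_vtk(m, path)
  ln <- readLines(path)
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", ln)))
  expect_true(any(grepl(sprintf("^CELLS %d", nrow(m$tets)), ln)))
  unlink(path)
})

test_that("10-10 layout has 61 uniquely named upper-hemisphere channels", {
  lay <- layout_1010_61()
  expect_identical(nrow(lay), 61L)
  expect_identical(anyDuplicated(lay$name), 0L)
  expect_true(all(lay$z > 0.2))
  expect_true(all(abs(sqrt(lay$x^2 + lay$y^2 + lay$z^2) - 1) < 1e-9))
  expect_true(all(c("P3", "Pz", "P4", "PO3", "PO4", "PO7", "Oz", "PO8") %in%
                    layout_parietal8()$name))
  # left/right mirror symmetry of the generated positions
  c3 <- lay[lay$name == "C3", ]; c4 <- lay[lay$name == "C4", ]
  expect_equal(c3$x, -c4$x, tolerance = 1e-9)
  expect_equal(c3$z, c4$z, tolerance = 1e-9)
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_layout_csv(lay, path)
  lay2 <- read_layout_csv(path)
  expect_equal(lay2$x, lay$x, tolerance = 1e-12)
  expect_identical(lay2$name, lay$name)
  unlink(path)
})
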