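test_that("stiffness matrix keeps constants in its null space and is linear in sigma", {
  sys <- small_system()
  rs <- Matrix::rowSums(sys$K)
  expect_lt(max(abs(rs)) / max(abs(sys$K)), 1e-10)
  expect_true(Matrix::isSymmetric(sys$K, tol = 1e-12))
  # doubling all conductivities doubles the matrix
  tt <- tissue_table()
  tt2 <- tissue_table(
    scalp = 2 * tt[["scalp"]], skull = 2 * tt[["skull"]],
    csf = 2 * tt[["csf"]], brain = 2 * tt[["brain"]],
    electrode = 2 * tt[["electrode"]]
  )
  m <- build_layered_sphere(c(30, 25), labels = c("scalp", "brain"),
                            target_edge_length = 9)
  K1 <- assemble_system(m, tissue_table())$K
  K2 <- assemble_system(m, tt2)$K
  expect_lt(max(abs(K2 - 2 * K1)), 1e-12 * max(abs(K1)))
})

test_that("single reference tet reproduces the hand-computed P1 element stiffness", {
  # unit right tet, unit conductivity: gradients are (-1,-1,-1), e1, e2, e3
  # and K = V * G G^T with V = 1/6
  nodes <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0), c(0, 0, 1000)) # mm -> 1 m edges
  mesh <- phasortacs:::new_tet_mesh(nodes, matrix(1:4, 1), "brain")
  sys <- assemble_system(mesh, tissue_table(brain = 1))
  expected <- rbind(
    c(3, -1, -1, -1),
    c(-1, 1, 0, 0),
    c(-1, 0, 1, 0),
    c(-1, 0, 0, 1)
  ) / 6
  expect_equal(as.matrix(sys$K), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("missing conductivities and degenerate tets are rejected", {
  m <- build_layered_sphere(25, labels = "mystery", target_edge_length = 9)
  expect_error(assemble_system(m, tissue_table()), "mystery")
  flat <- phasortacs:::new_tet_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0)),
    matrix(1:4, 1), "brain"
  )
  expect_error(assemble_system(flat, tissue_table()), "volume|degenerate")
})

test_that("antipodal pair on a homogeneous sphere is antisymmetric and conserves current", {
  mesh <- oracle_sphere(10)
  sys <- assemble_system(mesh, tissue_table())
  ps <- solve_pair(sys, "top", "bottom")
  expect_lt(ps$conservation, 1e-3)
  vmax <- max(ps$V)
  eq <- which(abs(mesh$nodes[, 3]) < 1 & sqrt(rowSums(mesh$nodes^2)) > 70)
  expect_lt(max(abs(ps$V[eq] / vmax - 0.5)), 0.02)
  # discrete maximum principle (small slack for sliver elements)
  expect_gt(min(ps$V) / vmax, -0.02)
  expect_lt(max(ps$V) / vmax, 1.02)
  # flux integration over sponge-electrode distal faces agrees with the
  # reaction-force current to P1 quadrature accuracy, and the in/out
  # fluxes balance much more tightly
  sys2 <- small_system()
  ps2 <- solve_pair(sys2, "Pz", "Oz")
  f_in <- electrode_flux_current(sys2, ps2, "Pz")
  f_out <- electrode_flux_current(sys2, ps2, "Oz")
  expect_lt(abs(abs(f_in) - 1), 0.10)
  expect_lt(abs(f_in + f_out), 0.01)
})

test_that("FEM surface potential matches the analytic sphere series", {
  expect_lt(oracle_discrepancy(edge = 10), 0.05)
})

test_that("refining the mesh shrinks the discrepancy against the analytic oracle", {
  errs <- vapply(c(18, 12, 8), oracle_discrepancy, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("lead field has one column per return and is a superposition basis", {
  lf <- small_leadfield()
  m <- small_phantom()
  expect_identical(ncol(lf$A), length(m$electrodes) - 1L)
  expect_identical(lf$returns, setdiff(names(m$electrodes), "Pz"))
  expect_true(all(is.finite(lf$A)))
  expect_lt(max(lf$conservation), 1e-3)
  # montage {return r: +1 mA} reproduces column r exactly
  r <- lf$returns[3]
  mon <- complete_montage(replace(complex(length.out = ncol(lf$A)),
                                  3, 1 + 0i), lf)
  fld <- synthesize_field(lf, mon)
  expect_equal(Re(fld$values), lf$A[, 3], tolerance = 1e-12)
  expect_equal(Im(fld$values), rep(0, nrow(lf$A)), tolerance = 1e-12)
  # {r1: 1, r2: -1} equals column(r1) - column(r2) to machine precision
  x <- complex(length.out = ncol(lf$A)); x[1] <- 1; x[2] <- -1
  fld2 <- synthesize_field(lf, complete_montage(x, lf))
  expect_equal(Re(fld2$values), lf$A[, 1] - lf$A[, 2], tolerance = 1e-12)
})

test_that("lead-field superposition matches a direct multi-electrode solve", {
  lf <- small_leadfield()
  sys <- small_system()
  surf <- small_surface()
  set.seed(7)
  for (k in 1:3) {
    idx <- sample(seq_along(lf$returns), 3)
    cur <- stats::rnorm(3)
    montage_cur <- c(-sum(cur), cur)
    names(montage_cur) <- c("Pz", lf$returns[idx])
    direct <- solve_montage_direct(sys, surf, montage_cur)
    sup <- as.vector(lf$A %*% replace(numeric(ncol(lf$A)), idx, cur))
    expect_lt(sqrt(sum((sup - direct)^2) / sum(direct^2)), 0.01)
  }
})

test_that("cortical normal field is linear and vanishes for tangential fields", {
  lf <- small_leadfield()
  surf <- small_surface()
  sys <- small_system()
  ps <- solve_pair(sys, "Pz", "Oz")
  en <- cortical_normal_field(ps, surf)
  expect_equal(cortical_normal_field(ps$E * 3.5, surf), 3.5 * en,
               tolerance = 1e-12)
  # synthetic purely tangential field: rotate each outward normal 90 deg
  tang <- cbind(-surf$normals[, 2], surf$normals[, 1], 0)
  Efake <- matrix(0, nrow(sys$mesh$tets), 3)
  Efake[surf$owner, ] <- tang
  expect_equal(max(abs(cortical_normal_field(Efake, surf))), 0)
  # radial montage flips sign between the hemispheres under the electrodes
  mesh <- oracle_sphere(10)
  s2 <- extract_cortical_surface(mesh, "brain")
  ps2 <- solve_pair(assemble_system(mesh, tissue_table()), "top", "bottom")
  en2 <- cortical_normal_field(ps2, s2)
  top_third <- s2$centroids[, 3] > 40
  bot_third <- s2$centroids[, 3] < -40
  expect_true(mean(en2[top_third]) * mean(en2[bot_third]) < 0)
})

test_that("pair solves reject unknown or identical electrodes", {
  sys <- small_system()
  expect_error(solve_pair(sys, "Pz", "Pz"), "distinct")
  expect_error(solve_pair(sys, "Pz", "Nowhere"), "not placed")
  expect_error(build_leadfield(small_phantom(), active = "Nowhere"),
               "not placed")
})
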