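# Electrostatic forward problem: P1 (linear tetrahedral) finite elements
# for div(sigma grad V) = 0, Dirichlet pair solves normalized to 1 mA, and
# the lead-field matrix (normal-component cortical field per unit-current
# electrode pair).
#
# Node coordinates are mm in the mesh and converted to metres here, so the
# stiffness matrix is in siemens, potentials in volts, fields in V/m and
# reaction currents in amperes.

#' Assemble the P1 stiffness system
#'
#' Builds the sparse symmetric stiffness matrix `K[i,j] = sum_e sigma_e
#' V_e grad(phi_i) . grad(phi_j)` over all tets.  Before boundary
#' conditions the matrix is positive semidefinite with the constants in
#' its null space (every row sums to zero).
#'
#' @param mesh a `tet_mesh` (with electrodes placed if pair solves are
#'   intended).
#' @param tissue a [tissue_table()] covering every mesh label.
#' @return a `fem_system`: list with `K` (dgCMatrix, siemens), per-tet
#'   barycentric gradients (1/m), volumes (m^3), conductivities and the
#'   mesh.
#' @export
assemble_system <- function(mesh, tissue = tissue_table()) {
  validate_mesh(mesh, tissue)
  sigma <- unname(unclass(tissue)[mesh$labels])
  nodes <- mesh$nodes / 1000 # mm -> m
  tets <- mesh$tets
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  # det and adjugate of B = [e1 e2 e3] (columns), vectorized
  c23 <- rowcross(e2, e3); c31 <- rowcross(e3, e1); c12 <- rowcross(e1, e2)
  detB <- rowSums(e1 * c23)
  bad <- which(abs(detB) < 1e-18)
  if (length(bad)) abort("degenerate element geometry at tet %d", bad[1])
  vol <- detB / 6
  # gradients of barycentric coords 2..4 are the rows of B^{ -1 }
  g2 <- c23 / detB; g3 <- c31 / detB; g4 <- c12 / detB
  g1 <- -(g2 + g3 + g4)
  gx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
  gy <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
  gz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  w <- sigma * vol
  n <- nrow(nodes)
  ii <- jj <- xx <- vector("list", 16)
  idx <- 1L
  for (a in 1:4) for (b in 1:4) {
    ii[[idx]] <- tets[, a]
    jj[[idx]] <- tets[, b]
    xx[[idx]] <- w * (gx[, a] * gx[, b] + gy[, a] * gy[, b] + gz[, a] * gz[, b])
    idx <- idx + 1L
  }
  K <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n)
  )
  structure(
    list(K = K, mesh = mesh, sigma = sigma, vol = vol,
         gx = gx, gy = gy, gz = gz),
    class = "fem_system"
  )
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("FEM system: %d dofs, %d tets, %d nonzeros\n",
              nrow(x$K), nrow(x$mesh$tets), Matrix::nnzero(x$K)))
  invisible(x)
}

electrode_nodes <- function(mesh, name) {
  el <- mesh$electrodes[[name]]
  if (is.null(el)) abort("electrode '%s' not placed on this mesh", name)
  el$distal_nodes
}

# piecewise-constant E = -grad V per tet (V/m); optionally only some tets
tet_field <- function(system, V, which_tets = NULL) {
  tets <- system$mesh$tets
  if (!is.null(which_tets)) {
    tets <- tets[which_tets, , drop = FALSE]
    gx <- system$gx[which_tets, , drop = FALSE]
    gy <- system$gy[which_tets, , drop = FALSE]
    gz <- system$gz[which_tets, , drop = FALSE]
  } else {
    gx <- system$gx; gy <- system$gy; gz <- system$gz
  }
  Vm <- matrix(V[tets], ncol = 4)
  -cbind(rowSums(Vm * gx), rowSums(Vm * gy), rowSums(Vm * gz))
}

#' Solve one electrode pair and normalize to 1 mA
#'
#' Applies Dirichlet conditions V = 1 V on the distal face of the active
#' electrode and V = 0 on the return, solves the reduced system by sparse
#' Cholesky factorization, computes the delivered current from the
#' stiffness reaction forces at the constrained nodes, and rescales the
#' whole solution so the delivered current is exactly 1 mA.
#'
#' @param system a `fem_system` from [assemble_system()].
#' @param active,return_electrode electrode names (must be distinct and
#'   placed on the mesh).
#' @return a `pair_solution`: list with nodal `V` (volts), per-tet field
#'   `E` (V/m) and current density `J` (A/m^2), `current_mA` (delivered,
#'   1 after normalization), `conservation` (relative active/return
#'   current imbalance) and the electrode names.
#' @export
solve_pair <- function(system, active, return_electrode) {
  if (identical(active, return_electrode)) abort("electrodes must be distinct")
  mesh <- system$mesh
  na_ <- electrode_nodes(mesh, active)
  nr_ <- electrode_nodes(mesh, return_electrode)
  n <- nrow(system$K)
  fixed <- c(na_, nr_)
  vfix <- c(rep(1, length(na_)), rep(0, length(nr_)))
  free <- setdiff(seq_len(n), fixed)
  rhs <- -system$K[free, fixed, drop = FALSE] %*% vfix
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(system$K[free, free]), LDL = FALSE)
  V <- numeric(n)
  V[fixed] <- vfix
  V[free] <- as.vector(Matrix::solve(ch, rhs))
  r <- as.vector(system$K %*% V)
  i_act <- sum(r[na_])
  i_ret <- sum(r[nr_])
  if (abs(i_act) < 1e-15) abort("zero delivered current; check electrode geometry")
  scale <- 1e-3 / i_act
  V <- V * scale
  E <- tet_field(system, V)
  structure(
    list(V = V, E = E, J = E * system$sigma,
         current_mA = 1, raw_current_A = i_act,
         conservation = abs(i_act + i_ret) / abs(i_act),
         active = active, return_electrode = return_electrode),
    class = "pair_solution"
  )
}

#' Normal-component cortical field of a solution
#'
#' Signed E . n-hat (outward normal, V/m) per cortical surface triangle,
#' taken from the owning tet's piecewise-constant field.
#'
#' @param solution a `pair_solution`, or a per-tet field matrix (n_tets x 3).
#' @param surface a `cortical_surface` extracted from the same mesh.
#' @return numeric vector, one value per surface triangle.
#' @export
cortical_normal_field <- function(solution, surface) {
  E <- if (inherits(solution, "pair_solution")) solution$E else solution
  if (max(surface$owner) > nrow(E)) {
    abort("surface does not match the solved mesh (tet count mismatch)")
  }
  rowSums(E[surface$owner, , drop = FALSE] * surface$normals)
}

#' Build the lead-field matrix
#'
#' One pair solve per return electrode against the fixed active electrode
#' (default the frontal-midline channel Fpz), each normalized to 1 mA
#' delivered through the pair; columns are signed so that column `r` is
#' the cortical normal field when return `r` injects +1 mA and the active
#' electrode returns it — the orientation under which superposition with
#' return currents `x` and active current `-sum(x)` reproduces the
#' columns exactly.  All solves share a
#' single Cholesky factorization of the active-grounded stiffness matrix;
#' each return's Dirichlet condition is imposed through a small Lagrange
#' (Schur-complement) correction, which is algebraically identical to the
#' per-pair reduced solve.
#'
#' @param mesh a `tet_mesh` with electrodes placed.
#' @param tissue a [tissue_table()].
#' @param surface optional pre-extracted `cortical_surface`; extracted
#'   from `cortical_label` when missing.
#' @param active name of the fixed active electrode.
#' @param cortical_label label used if `surface` is missing.
#' @return a `leadfield`: list with `A` (n_elements x n_returns, V/m per
#'   mA), `active`, `returns` (ordered as placed), `surface`, per-column
#'   `conservation`, and solver metadata.
#' @export
build_leadfield <- function(mesh, tissue = tissue_table(),
                            surface = NULL, active = "Fpz",
                            cortical_label = "brain") {
  if (length(mesh$electrodes) < 2) abort("need at least 2 electrodes")
  if (!active %in% names(mesh$electrodes)) {
    abort("active electrode '%s' not placed", active)
  }
  if (is.null(surface)) surface <- extract_cortical_surface(mesh, cortical_label)
  system <- assemble_system(mesh, tissue)
  returns <- setdiff(names(mesh$electrodes), active)
  n <- nrow(system$K)
  na_ <- electrode_nodes(mesh, active)
  free <- setdiff(seq_len(n), na_)
  Kff <- Matrix::forceSymmetric(system$K[free, free])
  ch <- Matrix::Cholesky(Kff, LDL = FALSE)
  rhs0 <- -Matrix::rowSums(system$K[free, na_, drop = FALSE])
  u0 <- as.vector(Matrix::solve(ch, rhs0))
  pos_in_free <- integer(n)
  pos_in_free[free] <- seq_along(free)

  A <- matrix(0, nrow(surface$faces), length(returns))
  conservation <- numeric(length(returns))
  owners <- surface$owner
  for (j in seq_along(returns)) {
    dr <- pos_in_free[electrode_nodes(mesh, returns[j])]
    sel <- Matrix::sparseMatrix(i = dr, j = seq_along(dr),
                                x = 1, dims = c(length(free), length(dr)))
    W <- as.matrix(Matrix::solve(ch, sel))
    lam <- solve(W[dr, , drop = FALSE], u0[dr])
    V <- numeric(n)
    V[na_] <- 1
    V[free] <- u0 - as.vector(W %*% lam)
    r <- as.vector(system$K %*% V)
    i_act <- sum(r[na_])
    i_ret <- sum(r[electrode_nodes(mesh, returns[j])])
    conservation[j] <- abs(i_act + i_ret) / abs(i_act)
    # normalize to +1 mA injected at the RETURN electrode (the active
    # carries -1 mA), so that superposition with return currents x and
    # active current -sum(x) reproduces the columns exactly
    V <- V * (-1e-3 / i_act)
    E <- tet_field(system, V, which_tets = owners)
    A[, j] <- rowSums(E * surface$normals)
  }
  structure(
    list(A = A, active = active, returns = returns, surface = surface,
         conservation = conservation,
         meta = list(units = "V/m per mA", solver = "sparse Cholesky",
                     n_nodes = n, n_tets = nrow(mesh$tets),
                     mesh_kind = mesh$meta$kind %||% "external")),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Lead field: %d cortical elements x %d return electrodes (active %s)\n",
              nrow(x$A), ncol(x$A), x$active))
  cat(sprintf("  worst current conservation: %.2e\n", max(x$conservation)))
  invisible(x)
}

#' Direct multi-electrode solve with Neumann current sources
#'
#' Cross-check for lead-field superposition: injects the given real
#' currents (mA, summing to zero) lumped on each electrode's distal nodes,
#' solves the Neumann problem with a one-node gauge, and returns the
#' normal-component cortical field.
#'
#' @param system a `fem_system`.
#' @param surface a `cortical_surface` from the same mesh.
#' @param currents_mA named numeric vector (electrode name -> mA); must
#'   sum to zero within 1e-9.
#' @return numeric vector of normal-component E (V/m) per surface triangle.
#' @export
solve_montage_direct <- function(system, surface, currents_mA) {
  if (abs(sum(currents_mA)) > 1e-9) abort("currents must sum to zero")
  mesh <- system$mesh
  n <- nrow(system$K)
  b <- numeric(n)
  for (nm in names(currents_mA)) {
    dn <- electrode_nodes(mesh, nm)
    b[dn] <- b[dn] + currents_mA[[nm]] * 1e-3 / length(dn)
  }
  gauge <- 1L
  free <- setdiff(seq_len(n), gauge)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(system$K[free, free]), LDL = FALSE)
  V <- numeric(n)
  V[free] <- as.vector(Matrix::solve(ch, b[free]))
  E <- tet_field(system, V, which_tets = surface$owner)
  rowSums(E * surface$normals)
}

#' Current through an electrode's distal face by flux integration
#'
#' Independent cross-check of the reaction-force current: integrates
#' J . n over the boundary faces sitting on the electrode's distal nodes.
#' Less accurate than the reaction forces for P1 elements but useful as a
#' sanity check.
#'
#' @param system a `fem_system`.
#' @param solution a `pair_solution`.
#' @param electrode electrode name.
#' @return current in mA flowing out of the mesh through the distal face.
#' @export
electrode_flux_current <- function(system, solution, electrode) {
  mesh <- system$mesh
  dn <- electrode_nodes(mesh, electrode)
  bnd <- boundary_faces(mesh)
  on_el <- rowSums(matrix(bnd$faces %in% dn, ncol = 3)) == 3
  if (!any(on_el)) abort("no boundary faces on electrode '%s'", electrode)
  Jn <- rowSums(solution$J[bnd$owner[on_el], , drop = FALSE] *
                  bnd$normals[on_el, , drop = FALSE])
  sum(Jn * bnd$areas[on_el] * 1e-6) * 1e3 # mm^2 -> m^2, A -> mA
}
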