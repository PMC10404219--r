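# A fake lead field is enough for the algebraic operations: a real matrix
# plus named returns and a minimal surface carrier.
fake_leadfield <- function(A, returns = paste0("R", seq_len(ncol(A))),
                           active = "ACT") {
  structure(
    list(A = A, active = active, returns = returns,
         surface = list(areas = rep(1, nrow(A)), faces = matrix(0, nrow(A), 3)),
         conservation = rep(0, ncol(A)), meta = list()),
    class = "leadfield"
  )
}

fake_roi <- function(name, elements) {
  structure(list(name = name, elements = as.integer(elements), area = 1,
                 meta = list()),
            class = "roi_patch")
}

test_that("target vector carries A*exp(j*phi) on ROI elements and zero elsewhere", {
  lf <- fake_leadfield(matrix(rnorm(40), 10, 4))
  t2 <- phasor_target(list(fake_roi("ref", 1:3), fake_roi("other", 6:8)),
                      amplitude = 0.3, phase_deg = c(0, 120))
  b <- build_target_vector(lf, t2)
  expect_equal(b[1:3], rep(complex(real = 0.3), 3))
  expect_equal(b[6:8], rep(complex(real = -0.15, imaginary = 0.3 * sqrt(3) / 2), 3),
               tolerance = 1e-12)
  expect_equal(b[c(4, 5, 9, 10)], complex(length.out = 4))
})

test_that("phasor targets validate phases, amplitudes and ROI disjointness", {
  r1 <- fake_roi("a", 1:3); r2 <- fake_roi("b", 3:5)
  expect_error(phasor_target(list(r1, r2), phase_deg = c(0, 90)), "overlap")
  expect_error(phasor_target(list(r1), amplitude = -1), "> 0")
  expect_error(phasor_target(list(r1), phase_deg = 200), "180")
  expect_error(phasor_target(list(fake_roi("a", 1:2), fake_roi("b", 3:4)),
                             phase_deg = c(10, 90)), "reference")
})

test_that("complex least squares matches exact and brute-force solutions", {
  # zero target -> zero currents
  A <- matrix(rnorm(24), 8, 3)
  expect_equal(solve_cls(A, complex(length.out = 8)), complex(length.out = 3))
  # square well-conditioned system: exact recovery
  set.seed(3)
  As <- diag(3) + 0.1 * matrix(rnorm(9), 3)
  x0 <- complex(real = rnorm(3), imaginary = rnorm(3))
  expect_equal(solve_cls(As, as.vector(As %*% x0)), x0, tolerance = 1e-8)
  # random rectangular systems vs an independent numerical minimizer
  set.seed(11)
  for (k in 1:5) {
    A <- matrix(rnorm(24), 8, 3)
    b <- complex(real = rnorm(8), imaginary = rnorm(8))
    x <- solve_cls(A, b)
    obj <- function(p) {
      xc <- complex(real = p[1:3], imaginary = p[4:6])
      sum(Mod(b - A %*% xc)^2)
    }
    fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    expect_lt(max(abs(c(Re(x), Im(x)) - fit$par)), 1e-5)
    # normal-equation optimality residual
    res <- b - A %*% x
    expect_lt(max(Mod(crossprod(A, res))), 1e-8 * max(Mod(crossprod(A, b))))
  }
})

test_that("ridge shrinks the solution and ill-conditioned systems are truncated", {
  set.seed(4)
  A <- matrix(rnorm(40), 10, 4)
  b <- complex(real = rnorm(10), imaginary = rnorm(10))
  x0 <- solve_cls(A, b)
  x1 <- solve_cls(A, b, ridge = 10)
  expect_lt(sum(Mod(x1)^2), sum(Mod(x0)^2))
  # a numerically rank-deficient column must not blow up
  A2 <- cbind(A, A[, 1] + 1e-14 * rnorm(10))
  x2 <- solve_cls(A2, b)
  expect_true(all(is.finite(Mod(x2))))
  expect_error(solve_cls(A * NA, b), "finite")
})

test_that("montage completion enforces Kirchhoff exactly", {
  lf <- fake_leadfield(matrix(rnorm(20), 10, 2), returns = c("r1", "r2"))
  mon <- complete_montage(c(1 + 0i, -0.5 + 0.5i), lf)
  expect_equal(mon$current_mA[mon$electrode == "ACT"], -0.5 - 0.5i)
  expect_identical(sum(mon$current_mA), 0 + 0i)
  mon0 <- complete_montage(c(0i, 0i), lf)
  expect_true(all(mon0$amplitude_mA == 0))
  monj <- complete_montage(c(0i, 2i), lf)
  expect_equal(mon$current_mA[1], -0.5 - 0.5i)
  expect_equal(monj$current_mA[monj$electrode == "ACT"], -2i)
  expect_error(complete_montage(c(1 + 0i), lf), "expected 2")
})

test_that("safety scaling is uniform, phase-preserving and idempotent when feasible", {
  lf <- fake_leadfield(matrix(rnorm(30), 10, 3))
  # max return 4 mA, active 3 mA -> s = 0.5 via the return limit
  x <- c(4 + 0i, -0.5 - 2i, -0.5 + 0i) # active = -3
  mon <- complete_montage(x, lf)
  sc <- apply_safety_scaling(mon)
  expect_equal(attr(sc, "safety_scale"), 0.5)
  expect_equal(sc$amplitude_mA, mon$amplitude_mA / 2)
  expect_equal(sc$phase_deg, mon$phase_deg)
  # already feasible montage is unchanged
  ok <- apply_safety_scaling(complete_montage(c(0.5 + 0i, 0.2i, 0i), lf))
  expect_equal(attr(ok, "safety_scale"), 1)
  # active-driven scaling: eight -1 mA returns -> active 8 mA -> s = 0.5
  lf8 <- fake_leadfield(matrix(rnorm(80), 10, 8))
  mon2 <- complete_montage(rep(-1 + 0i, 8), lf8)
  expect_equal(Mod(mon2$current_mA[mon2$electrode == "ACT"]), 8)
  sc2 <- apply_safety_scaling(mon2)
  expect_equal(attr(sc2, "safety_scale"), 0.5)
  expect_equal(max(Mod(sc2$current_mA)), 4)
})

test_that("rotating the target rotates currents and field phases, amplitudes fixed", {
  set.seed(9)
  A <- matrix(rnorm(60), 20, 3)
  lf <- fake_leadfield(A)
  b <- complex(real = rnorm(20), imaginary = rnorm(20))
  theta <- 37
  x1 <- solve_cls(lf, b)
  x2 <- solve_cls(lf, b * exp(1i * theta * pi / 180))
  expect_equal(x2, x1 * exp(1i * theta * pi / 180), tolerance = 1e-10)
  f1 <- synthesize_field(lf, complete_montage(x1, lf))
  f2 <- synthesize_field(lf, complete_montage(x2, lf))
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-10)
  dphi <- wrap_angle(f2$phase_deg - f1$phase_deg)
  expect_equal(dphi[f1$amplitude > 1e-9], rep(theta, sum(f1$amplitude > 1e-9)),
               tolerance = 1e-6)
})

test_that("montage JSON round trips through file", {
  lf <- fake_leadfield(matrix(rnorm(20), 10, 2), returns = c("r1", "r2"))
  mon <- apply_safety_scaling(complete_montage(c(1 + 2i, -3 + 0.5i), lf))
  path <- tempfile(fileext = ".json")
  write_montage_json(mon, path)
  mon2 <- read_montage_json(path, lf)
  expect_equal(mon2$current_mA, mon$current_mA, tolerance = 1e-9)
  expect_equal(attr(mon2, "safety_scale"), attr(mon, "safety_scale"))
  unlink(path)
})
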