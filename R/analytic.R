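# Closed-form potential of a homogeneous conducting sphere driven by two
# point current electrodes on its surface.  Serves as an independent
# validation oracle for the finite-element solver.

legendre_sum <- function(x, coef) {
  # sum_n coef[n] * P_n(x), n = 1..length(coef), by upward recurrence
  p_prev <- rep(1, length(x)) # P0
  p <- x                      # P1
  acc <- coef[1] * p
  for (n in seq_along(coef)[-1]) {
    p_next <- ((2 * n - 1) * x * p - (n - 1) * p_prev) / n
    p_prev <- p
    p <- p_next
    acc <- acc + coef[n] * p
  }
  acc
}

#' Analytic potential of a homogeneous sphere with two surface point electrodes
#'
#' For a sphere of radius `R` and conductivity `sigma` with current `I`
#' entering at surface point `active_dir` and leaving at `return_dir`, the
#' interior potential is the Legendre series
#' `V = I/(4 pi sigma R) * sum_n (2n+1)/n (r/R)^n [P_n(cos gA) - P_n(cos gB)]`
#' where `gA`, `gB` are the angles to the two electrodes.  On the surface
#' the series has the closed form
#' `f(g) = 1/sin(g/2) - 2 - log(sin(g/2) (1 + sin(g/2)))`, which is used
#' whenever a point lies within 1e-9 of the surface, so no truncation
#' error enters surface comparisons.
#'
#' @param points matrix of evaluation points (mm), same frame as the mesh.
#' @param radius_mm sphere radius (mm).
#' @param sigma conductivity (S/m).
#' @param active_dir,return_dir unit directions of the two electrodes.
#' @param current_mA injected current (default 1 mA).
#' @param n_terms series length for interior points.
#' @return potentials in volts, gauge: mean of the series (zero monopole).
#' @export
sphere_pair_potential <- function(points, radius_mm, sigma,
                                  active_dir, return_dir,
                                  current_mA = 1, n_terms = 200) {
  R <- radius_mm / 1000
  pts <- points / 1000
  r <- sqrt(rowSums(pts^2))
  a <- active_dir / sqrt(sum(active_dir^2))
  b <- return_dir / sqrt(sum(return_dir^2))
  dirs <- pts / pmax(r, 1e-300)
  ca <- pmin(1, pmax(-1, as.vector(dirs %*% a)))
  cb <- pmin(1, pmax(-1, as.vector(dirs %*% b)))
  I0 <- current_mA * 1e-3
  pref <- I0 / (4 * pi * sigma * R)
  out <- numeric(nrow(pts))
  on_surf <- abs(r - R) <= 1e-9 * R
  if (any(on_surf)) {
    f <- function(cg) {
      s <- sqrt(pmax((1 - cg) / 2, 1e-300)) # sin(g/2)
      1 / s - 2 - log(s * (1 + s))
    }
    out[on_surf] <- pref * (f(ca[on_surf]) - f(cb[on_surf]))
  }
  if (any(!on_surf)) {
    idx <- which(!on_surf)
    n <- seq_len(n_terms)
    coefs <- (2 * n + 1) / n
    rr <- (r[idx] / R)
    # accumulate sum_n coef (r/R)^n [Pn(ca) - Pn(cb)]
    pa_prev <- rep(1, length(idx)); pb_prev <- pa_prev
    pa <- ca[idx]; pb <- cb[idx]
    rp <- rr
    acc <- coefs[1] * rp * (pa - pb)
    for (k in n[-1]) {
      pa_next <- ((2 * k - 1) * ca[idx] * pa - (k - 1) * pa_prev) / k
      pb_next <- ((2 * k - 1) * cb[idx] * pb - (k - 1) * pb_prev) / k
      pa_prev <- pa; pa <- pa_next
      pb_prev <- pb; pb <- pb_next
      rp <- rp * rr
      acc <- acc + coefs[k] * rp * (pa - pb)
    }
    out[idx] <- pref * acc
  }
  out
}
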