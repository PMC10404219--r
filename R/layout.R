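# Electrode layouts.  Positions are stored as unit direction vectors from
# the head centre (x = right, y = anterior, z = up); the mesher intersects
# them with the scalp.  The 61-channel 10-10 set is generated geometrically
# on the sphere: a circumferential ring at 72 deg polar angle (10% above
# the nasion-inion reference plane), the midline arc in 18 deg steps, and
# the intermediate rows as equal arc fractions of the circle through the
# row's two ring members and its midline member.

dir_from_angles <- function(theta_deg, phi_deg) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  cbind(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

# equal-arc-fraction points on the circle through three points of a sphere
circle3_points <- function(pL, pM, pR, fracs) {
  n <- crossprod3(pM - pL, pR - pL)
  n <- n / sqrt(sum(n^2))
  c0 <- n * sum(n * pL)
  u <- pL - c0
  rho <- sqrt(sum(u^2))
  u <- u / rho
  w <- crossprod3(n, u)
  ang <- function(p) atan2(sum((p - c0) * w), sum((p - c0) * u))
  aM <- ang(pM) %% (2 * pi)
  aR <- ang(pR) %% (2 * pi)
  sweep <- if (aM <= aR) aR else aR - 2 * pi
  t(vapply(fracs, function(f) {
    a <- f * sweep
    c0 + rho * (cos(a) * u + sin(a) * w)
  }, numeric(3)))
}

new_layout <- function(name, dirs, radius_mm, height_mm) {
  dirs <- normalize_rows(dirs)
  out <- data.frame(
    name = name, x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
    radius_mm = radius_mm, height_mm = height_mm,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$name)) abort("electrode names must be unique")
  if (any(out$radius_mm < 0)) abort("electrode radius must be >= 0")
  class(out) <- c("electrode_layout", "data.frame")
  rownames(out) <- NULL
  out
}

#' 61-channel 10-10 electrode layout on a spherical head
#'
#' The standard 61-electrode subset of the international 10-10 system
#' (Fp/AF/F/FC/C/CP/P/PO/O rows plus the midline), mapped onto the sphere.
#' Exact MNI scalp coordinates are irrelevant on a phantom; the layout is
#' self-consistent spherical geometry.
#'
#' @param radius_mm disc electrode radius (default 5 mm).
#' @param height_mm sponge electrode height (default 25 mm).
#' @return an `electrode_layout` data frame with unit direction columns
#'   `x`, `y`, `z`.
#' @examples
#' lay <- layout_1010_61()
#' nrow(lay)
#' @export
layout_1010_61 <- function(radius_mm = 5, height_mm = 25) {
  ring_phi <- c(
    Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
    TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
    O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
    FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18
  )
  ring <- dir_from_angles(72, ring_phi)
  rownames(ring) <- names(ring_phi)

  mid_theta <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0,
                 CPz = -18, Pz = -36, POz = -54)
  midline <- dir_from_angles(abs(mid_theta), ifelse(mid_theta >= 0, 0, 180))
  midline[abs(mid_theta) == 0, ] <- c(0, 0, 1)
  rownames(midline) <- names(mid_theta)

  rows <- list(
    list(L = "AF7", M = "AFz", R = "AF8",
         names = c("AF7", "AF3", "AFz", "AF4", "AF8"), fr = (0:4) / 4),
    list(L = "F7", M = "Fz", R = "F8",
         names = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         fr = (0:8) / 8),
    list(L = "FT7", M = "FCz", R = "FT8",
         names = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         fr = (0:8) / 8),
    list(L = "T7", M = "Cz", R = "T8",
         names = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         fr = (0:8) / 8),
    list(L = "TP7", M = "CPz", R = "TP8",
         names = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
         fr = (0:8) / 8),
    list(L = "P7", M = "Pz", R = "P8",
         names = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         fr = (0:8) / 8),
    list(L = "PO7", M = "POz", R = "PO8",
         names = c("PO7", "PO3", "POz", "PO4", "PO8"), fr = (0:4) / 4)
  )

  pos <- rbind(ring, midline)
  for (rw in rows) {
    pts <- circle3_points(pos[rw$L, ], pos[rw$M, ], pos[rw$R, ], rw$fr)
    rownames(pts) <- rw$names
    new <- setdiff(rw$names, rownames(pos))
    pos <- rbind(pos, pts[new, , drop = FALSE])
  }

  order61 <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  new_layout(order61, pos[order61, , drop = FALSE], radius_mm, height_mm)
}

#' Parietal-occipital 8-electrode layout preset
#'
#' The eight-channel subset (P3, Pz, P4, PO3, PO4, PO7, Oz, PO8) used for
#' bilateral intraparietal stimulation with a multi-channel stimulator.
#'
#' @inheritParams layout_1010_61
#' @return an `electrode_layout` with 8 rows.
#' @export
layout_parietal8 <- function(radius_mm = 5, height_mm = 25) {
  lay <- layout_1010_61(radius_mm, height_mm)
  out <- lay[match(c("P3", "Pz", "P4", "PO3", "PO4", "PO7", "Oz", "PO8"),
                   lay$name), ]
  rownames(out) <- NULL
  out
}

#' Read / write electrode layout CSV
#'
#' Two header dialects are accepted: `name,x,y,z,radius_mm,height_mm`
#' (direction or position vector) or `name,theta_deg,phi_deg,radius_mm,
#' height_mm` (polar angle from the vertex and azimuth from the anterior
#' midline toward the right ear).
#'
#' @param path CSV file path.
#' @return an `electrode_layout`.
#' @export
read_layout_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("x", "y", "z") %in% names(d))) {
    dirs <- as.matrix(d[, c("x", "y", "z")])
  } else if (all(c("theta_deg", "phi_deg") %in% names(d))) {
    dirs <- dir_from_angles(d$theta_deg, d$phi_deg)
  } else {
    abort("layout CSV needs columns x,y,z or theta_deg,phi_deg")
  }
  new_layout(d$name, dirs,
             d$radius_mm %||% 5, d$height_mm %||% 25)
}

#' @rdname read_layout_csv
#' @param layout an `electrode_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}
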