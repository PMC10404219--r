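# Complex least-squares montage optimization.
#
# Desired fields and injection currents are phasors A*cos(wt+phi) +
# j*A*sin(wt+phi) = A<phi; the carrier frequency and time drop out of the
# optimization because the electrostatic forward map is linear and real.
# Consequently the complex problem min ||b - A x||_2 splits into two
# independent real least-squares problems (real and imaginary parts), an
# exact identity, not an approximation.

#' Build a phasor target
#'
#' Per-ROI desired field amplitude (V/m) and phase (degrees); zero outside
#' the ROIs.  The reference ROI carries phase 0 by convention; a positive
#' phase on another ROI means the reference leads it.
#'
#' @param rois list of `roi_patch` objects.
#' @param amplitude desired amplitudes, recycled; default 0.3 V/m.
#' @param phase_deg desired phases in (-180, 180], one per ROI; the
#'   reference ROI must have phase 0.
#' @param reference name of the reference ROI (default: the first).
#' @return a `phasor_target`.
#' @examples
#' # two caps, the second lagging the reference by 90 degrees
#' # phasor_target(list(roiL, roiR), phase_deg = c(0, 90))
#' @export
phasor_target <- function(rois, amplitude = 0.3, phase_deg = 0,
                          reference = NULL) {
  if (!length(rois)) abort("need at least one ROI")
  nm <- vapply(rois, `[[`, "", "name")
  if (anyDuplicated(nm)) abort("ROI names must be unique")
  amplitude <- rep_len(amplitude, length(rois))
  phase_deg <- rep_len(phase_deg, length(rois))
  if (any(amplitude <= 0)) abort("desired amplitudes must be > 0")
  if (any(phase_deg <= -180 | phase_deg > 180)) {
    abort("phases must lie in (-180, 180]")
  }
  reference <- reference %||% nm[1]
  ref_i <- match(reference, nm)
  if (is.na(ref_i)) abort("reference ROI '%s' not among the ROIs", reference)
  if (phase_deg[ref_i] != 0) abort("the reference ROI must have phase 0")
  # ROIs may not overlap within one target
  all_el <- unlist(lapply(rois, `[[`, "elements"))
  if (anyDuplicated(all_el)) abort("ROIs overlap; targets must be disjoint")
  structure(
    list(rois = rois, amplitude = amplitude, phase_deg = phase_deg,
         reference = reference),
    class = "phasor_target"
  )
}

#' @export
print.phasor_target <- function(x, ...) {
  cat("Phasor target (reference:", x$reference, ")\n")
  for (i in seq_along(x$rois)) {
    cat(sprintf("  %s: %.3g V/m at %+.1f deg (%d elements)\n",
                x$rois[[i]]$name, x$amplitude[i], x$phase_deg[i],
                length(x$rois[[i]]$elements)))
  }
  invisible(x)
}

#' Read / write a phasor target as JSON
#'
#' Format: `{"reference": "name", "rois": [{"name", "amplitude_Vpm",
#' "phase_deg", "center" | "elements", "angular_radius_deg"}]}`.
#'
#' @param path JSON file.
#' @param surface `cortical_surface` for resolving cap definitions.
#' @return a `phasor_target`.
#' @export
read_target_json <- function(path, surface) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rois <- lapply(spec$rois, function(s) {
    if (!is.null(s$elements)) roi_patch(s$name, unlist(s$elements), surface)
    else define_roi_patch(surface, unlist(s$center), s$angular_radius_deg, s$name)
  })
  phasor_target(
    rois,
    amplitude = vapply(spec$rois, function(s) s$amplitude_Vpm %||% 0.3, 0),
    phase_deg = vapply(spec$rois, function(s) s$phase_deg %||% 0, 0),
    reference = spec$reference
  )
}

#' Build the complex target vector
#'
#' `b[e] = A (cos phi + j sin phi)` for elements of each ROI and 0
#' elsewhere; length equals the cortical element count of the lead field.
#'
#' @param leadfield a `leadfield`.
#' @param target a `phasor_target`.
#' @return complex vector.
#' @export
build_target_vector <- function(leadfield, target) {
  n <- nrow(leadfield$A)
  b <- complex(length.out = n)
  for (i in seq_along(target$rois)) {
    el <- target$rois[[i]]$elements
    if (any(el > n)) abort("ROI indices exceed the lead field")
    ph <- deg2rad(target$phase_deg[i])
    b[el] <- complex(real = target$amplitude[i] * cos(ph),
                     imaginary = target$amplitude[i] * sin(ph))
  }
  b
}

#' Complex least-squares solve for the return currents
#'
#' Minimizes `||b - A x||_2` (plus `ridge * ||x||_2^2` when `ridge > 0`)
#' by singular value decomposition of the real lead-field matrix — a
#' rank-revealing factorization, never the explicit normal-equation
#' inverse.  Because `A` is real, the real and imaginary parts of `b`
#' are solved as two independent real problems sharing the SVD.  Singular
#' values below `1e-10` of the largest are truncated when `ridge = 0`.
#'
#' @param leadfield a `leadfield` (or a plain real matrix).
#' @param b complex target vector.
#' @param ridge nonnegative Tikhonov weight (default 0).
#' @return complex vector of return currents (mA), ordered as the
#'   lead-field columns.
#' @export
solve_cls <- function(leadfield, b, ridge = 0) {
  A <- if (inherits(leadfield, "leadfield")) leadfield$A else leadfield
  if (ncol(A) < 1) abort("lead field has no columns")
  if (any(!is.finite(A)) || any(!is.finite(Re(b))) || any(!is.finite(Im(b)))) {
    abort("non-finite entries in the least-squares system")
  }
  if (ridge < 0) abort("ridge must be >= 0")
  sv <- svd(A)
  uth_b <- crossprod(sv$u, b) # complex
  d <- sv$d
  if (ridge > 0) {
    w <- d / (d^2 + ridge)
  } else {
    keep <- d > max(d) * 1e-10
    w <- ifelse(keep, 1 / d, 0)
  }
  as.vector(sv$v %*% (w * uth_b))
}

#' Complete a montage with the active electrode current
#'
#' The active current is the negated sum of the return currents, so the
#' complex currents satisfy Kirchhoff's law exactly.
#'
#' @param return_currents complex vector (mA), ordered as the lead-field
#'   columns.
#' @param leadfield the `leadfield` the currents refer to.
#' @param frequency_hz carrier frequency (montage metadata only; it plays
#'   no role in the optimization).
#' @return a `montage`: data frame with `electrode`, complex `current_mA`,
#'   `amplitude_mA`, `phase_deg`; attributes `frequency_hz`, `active`,
#'   `safety_scale`.
#' @export
complete_montage <- function(return_currents, leadfield, frequency_hz = 80) {
  if (length(return_currents) != length(leadfield$returns)) {
    abort("expected %d return currents, got %d",
          length(leadfield$returns), length(return_currents))
  }
  cur <- c(-sum(return_currents), return_currents)
  out <- data.frame(
    electrode = c(leadfield$active, leadfield$returns),
    stringsAsFactors = FALSE
  )
  out$current_mA <- cur
  out$amplitude_mA <- Mod(cur)
  out$phase_deg <- ifelse(Mod(cur) == 0, 0, wrap_angle(rad2deg(Arg(cur))))
  attr(out, "frequency_hz") <- frequency_hz
  attr(out, "active") <- leadfield$active
  attr(out, "safety_scale") <- 1
  class(out) <- c("montage", "data.frame")
  out
}

#' Enforce per-electrode safety current limits
#'
#' Applies the uniform scale `s = min(1, return_limit / max return
#' amplitude, active_limit / active amplitude)` to every complex current.
#' Uniform scaling preserves all phases and the relative amplitude
#' distribution exactly, hence also the phase map of the synthesized
#' field; the applied factor is recorded in `attr(, "safety_scale")`.
#'
#' @param montage a `montage`.
#' @param return_limit maximum single return amplitude (default 2 mA).
#' @param active_limit maximum active amplitude (default 4 mA).
#' @return the scaled `montage`.
#' @export
apply_safety_scaling <- function(montage, return_limit = 2, active_limit = 4) {
  if (return_limit <= 0 || active_limit <= 0) abort("limits must be > 0")
  act <- attr(montage, "active")
  is_act <- montage$electrode == act
  max_ret <- max(montage$amplitude_mA[!is_act], 0)
  a_amp <- montage$amplitude_mA[is_act]
  s <- min(1,
           if (max_ret > 0) return_limit / max_ret else Inf,
           if (a_amp > 0) active_limit / a_amp else Inf)
  montage$current_mA <- montage$current_mA * s
  # keep the Kirchhoff identity bitwise exact after scaling
  montage$current_mA[is_act] <- -sum(montage$current_mA[!is_act])
  montage$amplitude_mA <- Mod(montage$current_mA)
  attr(montage, "safety_scale") <- attr(montage, "safety_scale") * s
  montage
}

#' One-call montage optimization
#'
#' [build_target_vector()] + [solve_cls()] + [complete_montage()] +
#' [apply_safety_scaling()].
#'
#' @inheritParams solve_cls
#' @inheritParams complete_montage
#' @inheritParams apply_safety_scaling
#' @param target a `phasor_target`.
#' @return a safety-scaled `montage`.
#' @export
optimize_montage <- function(leadfield, target, frequency_hz = 80,
                             ridge = 0, return_limit = 2, active_limit = 4) {
  b <- build_target_vector(leadfield, target)
  x <- solve_cls(leadfield, b, ridge = ridge)
  m <- complete_montage(x, leadfield, frequency_hz = frequency_hz)
  apply_safety_scaling(m, return_limit = return_limit,
                       active_limit = active_limit)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "Montage: %d electrodes at %g Hz (active %s, safety scale %.3g)\n",
    nrow(x), attr(x, "frequency_hz"), attr(x, "active"),
    attr(x, "safety_scale")))
  top <- x[order(-x$amplitude_mA), ][seq_len(min(8, nrow(x))), ]
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-4s %6.3f mA at %+7.2f deg\n",
                top$electrode[i], top$amplitude_mA[i], top$phase_deg[i]))
  }
  invisible(x)
}

#' Write / read a montage as JSON
#'
#' `{"frequency_hz", "active", "safety_scale", "channels":
#' [{"electrode", "amplitude_mA", "phase_deg"}]}`.
#'
#' @param montage a `montage`.
#' @param path output JSON path.
#' @export
write_montage_json <- function(montage, path) {
  jsonlite::write_json(
    list(
      frequency_hz = attr(montage, "frequency_hz"),
      active = attr(montage, "active"),
      safety_scale = attr(montage, "safety_scale"),
      channels = data.frame(
        electrode = montage$electrode,
        amplitude_mA = montage$amplitude_mA,
        phase_deg = montage$phase_deg
      )
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_montage_json
#' @param leadfield `leadfield` used to restore channel order.
#' @export
read_montage_json <- function(path, leadfield) {
  j <- jsonlite::fromJSON(path)
  ch <- j$channels
  ord <- match(c(j$active, setdiff(ch$electrode, j$active)), ch$electrode)
  ch <- ch[ord, ]
  cur <- ch$amplitude_mA * exp(1i * deg2rad(ch$phase_deg))
  ret <- cur[-1]
  names(ret) <- ch$electrode[-1]
  ret <- ret[leadfield$returns]
  m <- complete_montage(ret, leadfield, frequency_hz = j$frequency_hz)
  attr(m, "safety_scale") <- j$safety_scale
  m
}
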