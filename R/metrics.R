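# Evaluation of the achieved complex cortical field: amplitude/phase maps,
# per-ROI peaks and half-maximum areas, circular median phases, lead
# angles and percent errors.

#' Synthesize the achieved phasor field of a montage
#'
#' Superposition: `field = sum_k x_k column_k` with complex return
#' currents on the real lead-field columns.
#'
#' @param leadfield a `leadfield`.
#' @param montage a `montage` whose return channels match the lead-field
#'   columns (names and order are checked).
#' @return a `phasor_field`: list with complex `values` (V/m phasor of
#'   the normal component per cortical element), `amplitude`, `phase_deg`
#'   and the element `areas`.
#' @export
synthesize_field <- function(leadfield, montage) {
  act <- attr(montage, "active")
  ret <- montage[montage$electrode != act, ]
  if (!identical(ret$electrode, leadfield$returns)) {
    abort("montage return channels do not match the lead-field column order")
  }
  x <- ret$current_mA
  vals <- as.vector(leadfield$A %*% Re(x)) + 1i * as.vector(leadfield$A %*% Im(x))
  phasor_field(vals, leadfield$surface$areas)
}

phasor_field <- function(values, areas = NULL) {
  structure(
    list(values = values, amplitude = Mod(values),
         phase_deg = ifelse(Mod(values) == 0, 0,
                            wrap_angle(rad2deg(Arg(values)))),
         areas = areas),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("Phasor field: %d elements, |E| max %.3g V/m\n",
              length(x$values), max(x$amplitude)))
  invisible(x)
}

#' Circular median of angles
#'
#' The observed angle minimizing the sum of absolute circular deviations
#' (optionally weighted); ties are broken by the smallest wrapped angle.
#' Robust, exact, and equal to the ordinary median whenever the support
#' spans less than a half circle.
#'
#' @param theta_deg angles in degrees.
#' @param weights optional nonnegative weights (e.g. element areas).
#' @return the median angle in (-180, 180].
#' @export
circular_median <- function(theta_deg, weights = NULL) {
  th <- wrap_angle(theta_deg)
  n <- length(th)
  if (!n) abort("no angles supplied")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    abort("weights must be nonnegative and match the angles")
  }
  cost <- vapply(th, function(c0) sum(weights * abs(wrap_angle(th - c0))), 0)
  best <- which(cost <= min(cost) + 1e-12)
  min(th[best])
}

#' Per-ROI field report
#'
#' `E_max` is the peak amplitude within the ROI; the half-maximum set is
#' the ROI elements with amplitude at least half of `E_max`; the median
#' phase is the circular median over that set.  The half-maximum
#' threshold is applied within the ROI only, never cortex-wide.
#'
#' @param field a `phasor_field`.
#' @param roi an `roi_patch`.
#' @param area_weighted use element areas as weights in the circular
#'   median (default FALSE, unweighted).
#' @return an `roi_report`: list with `name`, `E_max` (V/m), `half_max_set`
#'   (element indices), `median_phase_deg` and `phase_defined`.
#' @export
roi_report <- function(field, roi, area_weighted = FALSE) {
  el <- roi$elements
  if (any(el > length(field$values))) abort("ROI indices exceed the field")
  amp <- field$amplitude[el]
  e_max <- max(amp)
  if (e_max == 0) {
    return(structure(
      list(name = roi$name, E_max = 0, half_max_set = integer(0),
           median_phase_deg = NA_real_, phase_defined = FALSE),
      class = "roi_report"
    ))
  }
  hm <- el[amp >= 0.5 * e_max]
  w <- if (area_weighted && !is.null(field$areas)) field$areas[hm] else NULL
  structure(
    list(name = roi$name, E_max = e_max, half_max_set = hm,
         median_phase_deg = circular_median(field$phase_deg[hm], w),
         phase_defined = TRUE),
    class = "roi_report"
  )
}

#' @export
print.roi_report <- function(x, ...) {
  cat(sprintf("ROI %s: E_max %.3g V/m, half-max set %d elements, median phase %s\n",
              x$name, x$E_max, length(x$half_max_set),
              if (x$phase_defined) sprintf("%+.2f deg", x$median_phase_deg)
              else "undefined"))
  invisible(x)
}

#' Lead angle between two regions
#'
#' `wrap(phi_other - phi_ref)` in (-180, 180]; a positive value means the
#' reference region leads the other.
#'
#' @param report_ref,report_other `roi_report`s (or bare phases in
#'   degrees).
#' @return lead angle in degrees.
#' @examples
#' lead_angle(2.92, 117.20) # 114.28
#' @export
lead_angle <- function(report_ref, report_other) {
  ph <- function(x) {
    if (inherits(x, "roi_report")) {
      if (!x$phase_defined) abort("undefined phase in ROI '%s'", x$name)
      x$median_phase_deg
    } else as.numeric(x)
  }
  wrap_angle(ph(report_other) - ph(report_ref))
}

#' Absolute and relative phase error
#'
#' `absolute = |wrap(achieved - desired)|` degrees; `relative =
#' absolute / |desired| * 100` percent when the desired delay is nonzero.
#' For a synchronization target (desired 0) the relative error is defined
#' as 0 when the absolute error is below `zero_tol` and flagged undefined
#' (NA) otherwise.
#'
#' @param achieved,desired phase delays in degrees.
#' @param zero_tol tolerance for the synchronized case (degrees).
#' @return list with `absolute_deg` and `relative_pct`.
#' @examples
#' phase_error(114.28, 120) # absolute 5.72 deg
#' @export
phase_error <- function(achieved, desired, zero_tol = 1e-6) {
  absolute <- abs(wrap_angle(achieved - desired))
  relative <- if (desired != 0) {
    absolute / abs(desired) * 100
  } else if (absolute < zero_tol) 0 else NA_real_
  list(absolute_deg = absolute, relative_pct = relative)
}

#' Delay report against a phasor target
#'
#' Evaluates a synthesized field against the desired per-ROI phases:
#' achieved lead angles relative to the reference ROI, absolute and
#' relative errors, and per-ROI peak amplitudes.
#'
#' @param field a `phasor_field`.
#' @param target the `phasor_target` it was optimized for.
#' @param area_weighted see [roi_report()].
#' @return a data frame with one row per non-reference ROI plus
#'   attribute `reports` (the per-ROI `roi_report`s).
#' @export
delay_report <- function(field, target, area_weighted = FALSE) {
  reports <- lapply(target$rois, roi_report, field = field,
                    area_weighted = area_weighted)
  names(reports) <- vapply(reports, `[[`, "", "name")
  ref <- reports[[target$reference]]
  other_i <- which(vapply(target$rois, `[[`, "", "name") != target$reference)
  rows <- lapply(other_i, function(i) {
    ach <- lead_angle(ref, reports[[i]])
    err <- phase_error(ach, target$phase_deg[i])
    data.frame(
      roi = reports[[i]]$name,
      E_max_Vpm = reports[[i]]$E_max,
      desired_lead_deg = target$phase_deg[i],
      achieved_lead_deg = ach,
      abs_error_deg = err$absolute_deg,
      rel_error_pct = err$relative_pct
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Export a field map as CSV
#'
#' Per-element `element,amp_Vpm,phase_deg` table.
#'
#' @param field a `phasor_field`.
#' @param path output path.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(
    data.frame(element = seq_along(field$values),
               amp_Vpm = field$amplitude, phase_deg = field$phase_deg),
    path, row.names = FALSE
  )
  invisible(path)
}
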