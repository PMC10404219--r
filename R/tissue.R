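#' Tissue conductivity table
#'
#' Construct the label-to-conductivity lookup used by the forward solver.
#' Default values (S/m) follow the standard isotropic literature set for
#' transcranial electrical stimulation modelling: scalp 0.25, skull 0.015,
#' CSF 1.79, grey matter 0.276, white matter 0.126 and sponge electrode
#' 5.21.  The single-compartment `brain` label of the sphere phantom
#' carries the grey-matter value, since the montage optimization only uses
#' the field on the cortical surface.
#'
#' @param ... named conductivities (S/m) that add to or override the
#'   defaults, e.g. `tissue_table(skull = 0.010)`.
#' @return a named numeric vector of class `tissue_table`.
#' @examples
#' tissue_table()
#' tissue_table(tumour = 0.5)
#' @export
tissue_table <- function(...) {
  sigma <- c(
    scalp = 0.25, skull = 0.015, csf = 1.79,
    grey = 0.276, white = 0.126, electrode = 5.21,
    brain = 0.276
  )
  extra <- c(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      abort("tissue_table(...) arguments must be named")
    }
    sigma[names(extra)] <- as.numeric(extra)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("all conductivities must be finite and > 0")
  }
  structure(sigma, class = "tissue_table")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("Tissue conductivities (S/m):\n")
  print(unclass(x))
  invisible(x)
}
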