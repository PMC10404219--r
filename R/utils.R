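#' Wrap angles into (-180, 180] degrees
#'
#' Phase arithmetic throughout the package uses degrees wrapped into the
#' half-open interval (-180, 180]; exactly -180 maps to +180 by convention.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 360, 540))
#' @export
wrap_angle <- function(x) {
  w <- ((x %% 360) + 360) %% 360
  w[w > 180] <- w[w > 180] - 360
  # x %% 360 of exactly 180 + 360k is 180, already mapped to +180
  w
}

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) abort("cannot normalize a zero vector")
  m / n
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
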