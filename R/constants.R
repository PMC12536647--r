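#' Physical constants and unit conversions
#'
#' Vacuum permittivity `eps0` (F/m), vacuum permeability `mu0` (H/m) and the
#' CGS oersted in SI units (1 Oe = 1e3/(4*pi) A/m).
#'
#' @format Named numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
eps0 <- 8.8541878128e-12

#' @rdname constants
#' @export
mu0 <- 4e-7 * pi

#' @rdname constants
#' @export
oersted_to_A_per_m <- 1e3 / (4 * pi)

#' Convert a magnetic flux density in tesla to a field strength in oersted
#'
#' Free-space conversion H = B/mu0, then A/m to Oe. 300 mT corresponds to
#' approximately 3000 Oe.
#'
#' @param B_tesla flux density, T.
#' @return field strength, Oe.
#' @export
tesla_to_oersted <- function(B_tesla) {
  (B_tesla / mu0) / oersted_to_A_per_m
}

# Internal: seeded evaluation that does not disturb the caller's RNG stream.
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  force(expr)
}
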