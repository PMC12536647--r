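#' Material property registry
#'
#' Linear constitutive records for the five media of the pipeline: the
#' magnetostrictive cobalt-ferrite core (CFO), the piezoelectric barium
#' titanate shell (BTO), the piezoelectric hydroxyapatite particle (HAP), the
#' alginate hydrogel matrix, and a homogenized human cell. Values are package
#' fixtures (YAML files under `extdata/materials/`, sources recorded in the
#' file comments) and are validated on load.
#'
#' A `material_props` record carries, in SI units:
#' \describe{
#'   \item{elasticity_cE}{6x6 symmetric positive-definite stiffness, Pa,
#'     Voigt order (11,22,33,23,13,12), engineering shear strains.}
#'   \item{piezo_e}{3x6 stress-charge coupling matrix, C/m^2 (zero for
#'     non-piezoelectric media).}
#'   \item{permittivity_rs}{3x3 diagonal clamped relative permittivity.}
#'   \item{conductivity}{scalar, S/m.}
#'   \item{mu_r, Ms, lambda_s}{relative permeability, saturation
#'     magnetization (A/m) and saturation magnetostriction (zero for
#'     non-magnetostrictive media).}
#'   \item{density}{kg/m^3.}
#'   \item{poling_axis}{unit vector of the poling / crystal c-axis.}
#' }
#'
#' @name materials
NULL

.materials_cache <- new.env(parent = emptyenv())

material_fixture_path <- function() {
  system.file("extdata", "materials", package = "magnetopiezo")
}

#' Build a material record from a parsed fixture list
#'
#' Exposed so users can register custom materials following the documented
#' YAML schema of the shipped fixtures.
#'
#' @param spec named list with the fixture fields (see [materials]).
#' @return validated `material_props` object.
#' @export
material_from_list <- function(spec) {
  el <- spec$elasticity
  cE <- if (identical(el$type, "isotropic")) {
    iso_elasticity(as.numeric(el$youngs_modulus), as.numeric(el$poisson))
  } else {
    1e9 * do.call(rbind, lapply(el$matrix_gpa, as.numeric))
  }
  e <- if (is.null(spec$piezo_e)) {
    matrix(0, 3, 6)
  } else {
    do.call(rbind, lapply(spec$piezo_e, as.numeric))
  }
  perm <- as.numeric(spec$permittivity_rs)
  if (length(perm) == 1) perm <- rep(perm, 3)
  m <- structure(list(
    name = spec$name,
    elasticity_cE = cE,
    piezo_e = e,
    permittivity_rs = diag(perm),
    conductivity = as.numeric(spec$conductivity),
    mu_r = as.numeric(spec$mu_r),
    Ms = as.numeric(spec$Ms),
    lambda_s = as.numeric(spec$lambda_s),
    density = as.numeric(spec$density),
    poling_axis = as.numeric(spec$poling_axis)
  ), class = "material_props")
  validate_material(m)
  m
}

#' Validate a material record
#'
#' Checks symmetry and positive definiteness of the stiffness, shape of the
#' coupling matrix, permittivity >= 1 and conductivity >= 0.
#'
#' @param m `material_props` object.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_material <- function(m) {
  cE <- m$elasticity_cE
  if (!is.matrix(cE) || any(dim(cE) != 6) ||
      max(abs(cE - t(cE))) > 1e-6 * max(abs(cE))) {
    stop("material '", m$name, "': elasticity_cE must be a symmetric 6x6 matrix")
  }
  ev <- eigen(cE, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("material '", m$name, "': elasticity_cE is not positive definite")
  }
  if (!all(dim(m$piezo_e) == c(3, 6))) {
    stop("material '", m$name, "': piezo_e must be 3x6")
  }
  if (any(diag(m$permittivity_rs) < 1)) {
    stop("material '", m$name, "': relative permittivity entries must be >= 1")
  }
  if (m$conductivity < 0) stop("material '", m$name, "': conductivity < 0")
  if (m$Ms < 0) stop("material '", m$name, "': Ms < 0")
  invisible(m)
}

#' Look up a registered material
#'
#' @param name one of `"CFO"`, `"BTO"`, `"HAP"`, `"alginate"`, `"cell"`
#'   (case-insensitive).
#' @return a validated [materials] record.
#' @examples
#' get_material("alginate")$piezo_e  # zero 3x6 matrix
#' @export
get_material <- function(name) {
  key <- tolower(name)
  valid <- c("cfo", "bto", "hap", "alginate", "cell")
  if (!key %in% valid) {
    stop("unknown material '", name, "'; valid names: ",
         paste(toupper(valid[1:3]), collapse = ", "), ", alginate, cell")
  }
  if (!exists(key, envir = .materials_cache)) {
    path <- file.path(material_fixture_path(), paste0(key, ".yaml"))
    spec <- yaml::read_yaml(path)
    assign(key, material_from_list(spec), envir = .materials_cache)
  }
  get(key, envir = .materials_cache)
}

#' @export
print.material_props <- function(x, ...) {
  cat("<material_props>", x$name, "\n")
  cat("  c11 =", format(x$elasticity_cE[1, 1], digits = 4), "Pa;",
      "e33 =", format(x$piezo_e[3, 3], digits = 4), "C/m^2;",
      "eps33 =", format(x$permittivity_rs[3, 3], digits = 4), "\n")
  cat("  sigma =", format(x$conductivity, digits = 3), "S/m;",
      "mu_r =", x$mu_r, "; Ms =", format(x$Ms, digits = 4), "A/m;",
      "lambda_s =", format(x$lambda_s, digits = 4), "\n")
  invisible(x)
}

#' Rotate a material record
#'
#' Transforms the stiffness, coupling and permittivity tensors by the standard
#' fourth/third/second-rank rotation rules, applied in Voigt notation through
#' the Bond matrix. Scalar fields are unchanged; the poling axis co-rotates.
#'
#' @param m `material_props` record.
#' @param rotation 3x3 orthonormal matrix (checked to 1e-10).
#' @return rotated `material_props` record.
#' @export
rotate_material <- function(m, rotation) {
  R <- rotation
  if (!is.matrix(R) || any(dim(R) != 3) ||
      max(abs(crossprod(R) - diag(3))) > 1e-10) {
    stop("rotate_material: rotation must be orthonormal (R'R = I within 1e-10)")
  }
  M <- bond_stress_matrix(R)
  m$elasticity_cE <- M %*% m$elasticity_cE %*% t(M)
  # guard numerical asymmetry from the double product
  m$elasticity_cE <- (m$elasticity_cE + t(m$elasticity_cE)) / 2
  m$piezo_e <- R %*% m$piezo_e %*% t(M)
  m$permittivity_rs <- R %*% m$permittivity_rs %*% t(R)
  m$poling_axis <- as.numeric(R %*% m$poling_axis)
  m
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("z", "x", "y"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  switch(axis,
    z = matrix(c(c2, -s2, 0, s2, c2, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, c2, -s2, 0, s2, c2), 3, 3, byrow = TRUE),
    y = matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, 3, byrow = TRUE)
  )
}
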