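#' @title Stage (ii): electric-field coverage of dipole arrays
#' @description
#' Conduction solve of a 10 um gel square loaded with an array of dipole
#' particles (surface potential `V0 cos(theta)`, grounded outer boundary) and
#' the threshold-coverage statistics of the resulting field magnitude over
#' the gel area, excluding the particle interiors.
#' @name stage_concentration
NULL

#' Area-weighted threshold exceedance fractions
#'
#' @param field_samples |E| samples, V/m.
#' @param weights positive areas associated with the samples, m^2.
#' @param thresholds thresholds, V/m (default `10^(1:5)`).
#' @return named numeric vector of fractions in `[0, 1]`, non-increasing in
#'   the threshold.
#' @export
coverage_fraction <- function(field_samples, weights,
                              thresholds = 10^(1:5)) {
  if (!length(field_samples)) stop("coverage_fraction: empty sample set")
  if (length(weights) != length(field_samples) || any(weights <= 0)) {
    stop("coverage_fraction: weights must be positive and match the samples")
  }
  tot <- sum(weights)
  out <- vapply(thresholds,
                function(t) sum(weights[field_samples > t]) / tot,
                numeric(1))
  names(out) <- paste0("E>", format(thresholds, scientific = FALSE, trim = TRUE))
  out
}

#' Estimated 3D particle volume fraction of a grid arrangement
#'
#' Extends the planar grid arrangement to a cube of the same side:
#' `floor(side/spacing)` particles per axis, volume fraction
#' `n^3 (4/3) pi r^3 / side^3` as a percentage.
#'
#' @param spacing inter-particle distance, m.
#' @param gel_cube_side cube side, m (default 10 um).
#' @param particle_radius particle radius, m (default 70 nm).
#' @return volume fraction, percent.
#' @export
volume_fraction_3d <- function(spacing, gel_cube_side = 10e-6,
                               particle_radius = 70e-9) {
  if (spacing <= 2 * particle_radius) stop("spacing must exceed the diameter")
  n <- floor(gel_cube_side / spacing + 1e-9)
  100 * n^3 * (4 / 3) * pi * particle_radius^3 / gel_cube_side^3
}

# Printed concentration labels for the six studied spacings (um -> %).
.conc_labels <- c("1.4" = 0.5, "1" = 1.0, "0.9" = 1.5,
                  "0.8" = 2.0, "0.7" = 2.5, "0.65" = 3.0)

#' Run the concentration stage
#'
#' Builds the dipole array, solves the conduction problem with the dipole
#' surface potentials and the grounded outer boundary, and accumulates the
#' coverage statistics over the gel elements (areas as quadrature weights).
#'
#' @param spacing inter-particle distance, m.
#' @param placement `"uniform"` or `"random"` (seeded jitter).
#' @param V0 dipole surface potential amplitude, V.
#' @param seed jitter seed.
#' @param gel_side gel square side, m.
#' @param radius particle radius, m.
#' @param thresholds coverage thresholds, V/m.
#' @param delta,h mesh sizes passed to [make_dipole_array_mesh()].
#' @param out_dir optional output directory (VTK + CSV row).
#' @return object of class `coverage_stats`: spacing (m), concentration label
#'   (%), recomputed area coverage (%), per-threshold area fractions, E
#'   extrema (V/m), 3D volume-fraction estimate (%), particle count, and the
#'   solution objects.
#' @export
run_concentration_stage <- function(spacing, placement = c("uniform", "random"),
                                    V0 = 1.36e-3, seed = 1L,
                                    gel_side = 10e-6, radius = 70e-9,
                                    thresholds = 10^(1:5),
                                    delta = NULL, h = NULL, out_dir = NULL) {
  placement <- match.arg(placement)
  dip <- make_dipole_grid(gel_side = gel_side, spacing = spacing,
                          radius = radius,
                          jitter = if (placement == "random") "random" else "none",
                          seed = seed, V0 = V0)
  mesh <- make_dipole_array_mesh(dip, delta = delta, h = h)
  np <- nrow(dip$centers)
  dirichlet <- list(outer_top = 0, outer_bottom = 0, outer_side = 0)
  for (i in seq_len(np)) {
    local({
      ci <- dip$centers[i, ]
      dirichlet[[paste0("particle_surface_", i)]] <<-
        function(nodes) dipole_surface_potential(nodes, ci, dip$axis, V0)
    })
  }
  sol <- solve_conduction(mesh, list(gel = get_material("alginate")), dirichlet)
  areas <- tri_areas(mesh)
  fr <- coverage_fraction(sol$E_mag, areas, thresholds)
  gel_area <- gel_side^2
  res <- structure(list(
    spacing = spacing,
    placement = placement,
    n_particles = np,
    concentration_label = unname(.conc_labels[as.character(spacing * 1e6)]),
    area_coverage_recomputed = 100 * np * pi * radius^2 / gel_area,
    thresholds = thresholds,
    area_fraction_above = fr,
    E_max = max(sol$E_mag), E_min = min(sol$E_mag),
    volume_fraction_3d = volume_fraction_3d(spacing, gel_side, radius),
    V0 = V0, dipoles = dip, mesh = mesh, solution = sol
  ), class = "coverage_stats")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(mesh, file.path(out_dir,
                              sprintf("concentration_%0.2fum_%s.vtk",
                                      spacing * 1e6, placement)),
              point_data = list(V = sol$V),
              cell_data = list(E_mag = sol$E_mag))
    utils::write.csv(coverage_row(res),
                     file.path(out_dir, sprintf("coverage_%0.2fum_%s.csv",
                                                spacing * 1e6, placement)),
                     row.names = FALSE)
  }
  res
}

coverage_row <- function(res) {
  row <- data.frame(
    spacing_um = res$spacing * 1e6,
    placement = res$placement,
    n_particles = res$n_particles,
    concentration_label_pct = ifelse(is.null(res$concentration_label), NA,
                                     res$concentration_label),
    area_coverage_recomputed_pct = res$area_coverage_recomputed,
    volume_fraction_3d_pct = res$volume_fraction_3d,
    E_max = res$E_max, E_min = res$E_min
  )
  for (k in seq_along(res$thresholds)) {
    row[[paste0("pct_above_1e", round(log10(res$thresholds[k])))]] <-
      100 * res$area_fraction_above[k]
  }
  row
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat("<coverage_stats>", x$n_particles, "particles, spacing",
      format(x$spacing * 1e6, digits = 3), "um (", x$placement, ")\n")
  cat("  coverage above thresholds (%):\n")
  print(round(100 * x$area_fraction_above, 2))
  cat("  E range:", format(x$E_min, digits = 3), "-",
      format(x$E_max, digits = 3), "V/m; 3D volume fraction",
      format(x$volume_fraction_3d, digits = 3), "%\n")
  invisible(x)
}
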