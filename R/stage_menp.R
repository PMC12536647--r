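#' @title Stage (i): single-particle magnetoelectric response
#' @description
#' Axisymmetric chain for one core-shell nanoparticle in a hydrogel cylinder
#' under a DC magnetic flux density along z: magnetostatic solve for the core
#' magnetization, magnetostrictive eigenstrain, monolithic piezoelectric
#' solve (core + shell + gel, all dielectric, shell piezoelectric), and the
#' two magnetoelectric coefficient estimators.
#' @name stage_menp
NULL

#' Magnetoelectric coefficient from the border field
#'
#' Ratio of the average electric field intensity at the particle outer border
#' to the applied magnetic field intensity, in the conventional mixed units
#' V cm^-1 Oe^-1.
#'
#' @param E_avg_border average |E| at the particle border, V/m.
#' @param B_applied applied flux density, T (> 0).
#' @return magnetoelectric coefficient, V cm^-1 Oe^-1.
#' @export
me_coefficient_field <- function(E_avg_border, B_applied) {
  if (B_applied <= 0) stop("B_applied must be positive")
  (E_avg_border / 100) / tesla_to_oersted(B_applied)
}

#' Magnetoelectric coefficient from the shell potential difference
#'
#' Ratio of the electric potential difference across the particle to the
#' applied magnetic field intensity times the particle diameter.
#'
#' @param delta_V potential difference pole-to-pole, V.
#' @param B_applied applied flux density, T (> 0).
#' @param diameter particle diameter, m (> 0).
#' @return magnetoelectric coefficient, V cm^-1 Oe^-1.
#' @export
me_coefficient_potential <- function(delta_V, B_applied, diameter) {
  if (B_applied <= 0) stop("B_applied must be positive")
  if (diameter <= 0) stop("diameter must be positive")
  delta_V / (tesla_to_oersted(B_applied) * diameter * 100)
}

# Area-weighted mean of an element quantity over the facets of a tag,
# sampled on the adjacent element lying in `side_subdomain` (if given).
surface_mean <- function(mesh, sol_values, tag, side_subdomain = NULL) {
  sel <- which(mesh$btags == tag)
  f <- mesh$bfacets[sel, , drop = FALSE]
  adj <- facet_adjacent_elements(mesh, f, side_subdomain)
  wts <- facet_measures(mesh, f)
  sum(sol_values[adj] * wts) / sum(wts)
}

# Facet measures: length (planar), 2*pi*r_mid*length (axisym), area (3d).
facet_measures <- function(mesh, f) {
  p <- mesh$nodes
  if (ncol(f) == 2) {
    len <- sqrt(rowSums((p[f[, 1], , drop = FALSE] - p[f[, 2], , drop = FALSE])^2))
    if (mesh$coord == "axisym") {
      rmid <- (p[f[, 1], 1] + p[f[, 2], 1]) / 2
      2 * pi * rmid * len
    } else len
  } else {
    a <- p[f[, 2], ] - p[f[, 1], ]; b <- p[f[, 3], ] - p[f[, 1], ]
    0.5 * sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                 (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                 (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)
  }
}

# For each facet, the adjacent element (preferring `side_subdomain`).
facet_adjacent_elements <- function(mesh, f, side_subdomain = NULL) {
  nl <- ncol(mesh$elem)
  n <- nrow(mesh$nodes)
  # map node -> elements via sparse incidence
  inc <- Matrix::sparseMatrix(i = as.vector(mesh$elem),
                              j = rep(seq_len(nrow(mesh$elem)), nl),
                              x = 1, dims = c(n, nrow(mesh$elem)))
  out <- integer(nrow(f))
  for (k in seq_len(nrow(f))) {
    hits <- inc[f[k, 1], ] > 0
    for (q in 2:ncol(f)) hits <- hits & inc[f[k, q], ] > 0
    cand <- which(hits)
    if (!is.null(side_subdomain)) {
      pref <- cand[mesh$subdomain[cand] %in% side_subdomain]
      if (length(pref)) cand <- pref
    }
    out[k] <- cand[1]
  }
  out
}

#' Locate points in a 2D mesh
#'
#' Barycentric containment test over all triangles; returns the index of an
#' element containing each point (NA outside the mesh).
#'
#' @param mesh `mp_mesh` (2D).
#' @param points matrix of coordinates.
#' @return integer vector of element indices.
#' @export
locate_elements <- function(mesh, points) {
  p <- mesh$nodes; e <- mesh$elem
  x1 <- p[e[, 1], 1]; y1 <- p[e[, 1], 2]
  x2 <- p[e[, 2], 1]; y2 <- p[e[, 2], 2]
  x3 <- p[e[, 3], 1]; y3 <- p[e[, 3], 2]
  den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  out <- rep(NA_integer_, nrow(points))
  for (k in seq_len(nrow(points))) {
    px <- points[k, 1]; py <- points[k, 2]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / den
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / den
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    inside <- which(l1 >= tol & l2 >= tol & l3 >= tol)
    if (length(inside)) out[k] <- inside[1]
  }
  out
}

#' Sample an element field at points
#'
#' @param mesh `mp_mesh` (2D).
#' @param values per-element values.
#' @param points matrix of coordinates.
#' @return numeric vector (NA for points outside the mesh).
#' @export
sample_field_at_points <- function(mesh, values, points) {
  idx <- locate_elements(mesh, points)
  out <- rep(NA_real_, nrow(points))
  out[!is.na(idx)] <- values[idx[!is.na(idx)]]
  out
}

#' Default configuration of the single-particle stage
#' @return named list of geometry, field and mesh parameters (SI units).
#' @export
menp_config <- function() {
  list(B = 0.3, core_radius = 45e-9, shell_thickness = 25e-9,
       gel_side = 1e-6, h = 5e-9, profile_max = 400e-9, profile_step = 10e-9)
}

#' Run the single-particle magnetoelectric stage
#'
#' Executes the full chain (magnetostatics, magnetostriction, coupled
#' piezoelectricity) and summarises the magnetoelectric response.
#'
#' @param config list as from [menp_config()]; entries may be overridden.
#' @param out_dir optional directory for VTK and CSV outputs.
#' @return object of class `me_result` with fields `max_core_M` (A/m),
#'   `max_vonMises` (Pa) and its subdomain, `surface_V_amplitude` (V),
#'   `E_profile` (data.frame: distance, ray, E_mag), `alpha_ME_field` and
#'   `alpha_ME_potential` (V cm^-1 Oe^-1), plus the mesh and field solutions.
#' @export
run_menp_stage <- function(config = menp_config(), out_dir = NULL) {
  cfg <- utils::modifyList(menp_config(), config)
  mesh <- make_menp_axisym_mesh(cfg$core_radius, cfg$shell_thickness,
                                cfg$gel_side, cfg$h)
  mats <- list(core = get_material("CFO"), shell = get_material("BTO"),
               gel = get_material("alginate"))
  mag <- solve_magnetostatics(mesh, mats, B_applied = cfg$B)
  core <- mesh$subdomain == "core"
  eig <- matrix(0, nrow(mesh$elem), 6)
  if (cfg$B > 0 && mats$core$lambda_s != 0) {
    eig[core, ] <- magnetostrictive_strain(mag$M[core, , drop = FALSE],
                                           mats$core$Ms, mats$core$lambda_s)
  }
  outer_tags <- grep("^outer", unique(mesh$btags), value = TRUE)
  ground <- stats::setNames(as.list(rep(0, length(outer_tags))), outer_tags)
  sol <- solve_piezo(mesh, mats, electric_subdomains = c("core", "shell", "gel"),
                     elec_dirichlet = ground,
                     mech_fixed = outer_tags,
                     eigenstrain = eig)
  Rp <- cfg$core_radius + cfg$shell_thickness
  surf_nodes <- boundary_nodes(mesh, "particle_surface_1")
  V_amp <- max(abs(sol$V[surf_nodes]))
  in_particle <- mesh$subdomain %in% c("core", "shell")
  vm_max_i <- which.max(sol$vonMises * in_particle)
  # pole potentials: surface nodes on the axis
  ax_surf <- surf_nodes[abs(mesh$nodes[surf_nodes, 1]) < 1e-18]
  v_np <- sol$V[ax_surf[which.max(mesh$nodes[ax_surf, 2])]]
  v_sp <- sol$V[ax_surf[which.min(mesh$nodes[ax_surf, 2])]]
  delta_V <- v_np - v_sp
  E_border <- surface_mean(mesh, sol$E_mag, "particle_surface_1", "gel")
  dist <- seq(cfg$profile_step, cfg$profile_max, by = cfg$profile_step)
  prof_eq <- sample_field_at_points(mesh, sol$E_mag, cbind(Rp + dist, 0))
  prof_po <- sample_field_at_points(mesh, sol$E_mag, cbind(0, Rp + dist))
  res <- structure(list(
    max_core_M = max(mag$M_mag[core]),
    max_vonMises = sol$vonMises[vm_max_i],
    max_vonMises_subdomain = mesh$subdomain[vm_max_i],
    surface_V_amplitude = V_amp,
    delta_V = delta_V,
    E_avg_border = E_border,
    E_profile = data.frame(
      distance = c(dist, dist),
      ray = rep(c("equatorial", "polar"), each = length(dist)),
      E_mag = c(prof_eq, prof_po)
    ),
    alpha_ME_field = if (cfg$B > 0) me_coefficient_field(E_border, cfg$B) else 0,
    alpha_ME_potential = if (cfg$B > 0) {
      me_coefficient_potential(abs(delta_V), cfg$B, 2 * Rp)
    } else 0,
    B = cfg$B, mesh = mesh, magnetics = mag, fields = sol
  ), class = "me_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(mesh, file.path(out_dir, "menp_fields.vtk"),
              point_data = list(V = sol$V),
              cell_data = list(vonMises = sol$vonMises, E_mag = sol$E_mag,
                               M_mag = mag$M_mag))
    utils::write.csv(me_summary_row(res),
                     file.path(out_dir, "menp_summary.csv"), row.names = FALSE)
  }
  res
}

me_summary_row <- function(res) {
  data.frame(
    max_core_M_A_per_m = res$max_core_M,
    max_vonMises_Pa = res$max_vonMises,
    vonMises_location = res$max_vonMises_subdomain,
    surface_V_amplitude_V = res$surface_V_amplitude,
    delta_V_V = res$delta_V,
    E_avg_border_V_per_m = res$E_avg_border,
    alpha_ME_field = res$alpha_ME_field,
    alpha_ME_potential = res$alpha_ME_potential
  )
}

#' @export
print.me_result <- function(x, ...) {
  cat("<me_result> B =", x$B, "T\n")
  cat("  max core |M|      :", format(x$max_core_M, digits = 4), "A/m\n")
  cat("  max von Mises     :", format(x$max_vonMises, digits = 4), "Pa in",
      x$max_vonMises_subdomain, "\n")
  cat("  shell surface |V| :", format(x$surface_V_amplitude * 1e3, digits = 4), "mV\n")
  cat("  alpha_ME (field)  :", format(x$alpha_ME_field, digits = 4), "V/cm/Oe\n")
  cat("  alpha_ME (potent.):", format(x$alpha_ME_potential, digits = 4), "V/cm/Oe\n")
  invisible(x)
}
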