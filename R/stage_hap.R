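#' @title Stage (iii): hydroxyapatite particle driven by two dipoles
#' @description
#' Planar (plane-strain) model of one hydroxyapatite particle between two
#' nanoparticle dipoles: the conduction solve in the gel (particle holes with
#' dipole surface potentials, insulating hydroxyapatite) provides the
#' potential trace on the particle boundary, which drives a one-way coupled
#' piezoelectric solve of the particle embedded in the elastic gel. The
#' particle's crystal c-axis lies along its long axis.
#' @name stage_hap
NULL

#' Representative strain from end-face displacements
#'
#' Projects the relative displacement of the two end faces on the particle
#' axis and divides by the original length (the displacement-length ratio).
#'
#' @param u_end1,u_end2 displacement vectors of the two ends, m.
#' @param axis unit vector of the particle long axis.
#' @param L original length, m (> 0).
#' @return dimensionless strain.
#' @export
strain_from_displacement <- function(u_end1, u_end2, axis, L) {
  if (L <= 0) stop("L must be positive")
  sum((u_end2 - u_end1) * axis) / L
}

#' Default configuration of the interaction stage
#' @return named list (SI units).
#' @export
hap_config <- function() {
  list(hap_width = 50e-9, menp_spacing = 0.65e-6, V0 = 1.36e-3,
       gel_side = 1e-6, h = 5e-9, menp_radius = 70e-9, delta_far = 50e-9,
       gel_exclusion = 5e-9)
}

#' Run the dipole-pair / hydroxyapatite interaction stage
#'
#' @param hap_length particle length, m (100, 200 or 400 nm in the sweep).
#' @param rotation_deg particle rotation about its centroid, degrees
#'   (0 = vertical / parallel to the dipole axis, 90 = horizontal,
#'   45 = rotated).
#' @param config list as [hap_config()]; entries may be overridden.
#' @param zero_piezo if TRUE the particle's coupling matrix is zeroed
#'   (null-response check).
#' @param out_dir optional output directory.
#' @return object of class `hap_response`: potential range on the particle
#'   (V), maximum displacement (m), representative strain, von Mises maxima
#'   and particle average (Pa), gel maximum outside an exclusion layer (Pa).
#' @export
run_hap_stage <- function(hap_length = 100e-9, rotation_deg = 0,
                          config = hap_config(), zero_piezo = FALSE,
                          out_dir = NULL) {
  cfg <- utils::modifyList(hap_config(), config)
  mesh <- make_hap_2d_mesh(hap_length = hap_length, hap_width = cfg$hap_width,
                           rotation_deg = rotation_deg,
                           menp_spacing = cfg$menp_spacing,
                           gel_side = cfg$gel_side, h = cfg$h,
                           menp_radius = cfg$menp_radius,
                           delta_far = cfg$delta_far)
  gel <- get_material("alginate")
  # crystal c-axis (poling, z in the fixture) mapped onto the rotated long axis
  R <- rotation_about("z", rotation_deg) %*% rotation_about("x", -90)
  hap <- rotate_material(get_material("HAP"), R)
  if (zero_piezo) hap$piezo_e[] <- 0
  # conduction in the gel: dipole surfaces driven, HAP hole insulating
  sm <- submesh(mesh, "gel")
  centers <- rbind(c(0, cfg$menp_spacing / 2), c(0, -cfg$menp_spacing / 2))
  dirichlet <- list(outer_top = 0, outer_bottom = 0, outer_side = 0)
  for (i in 1:2) {
    local({
      ci <- centers[i, ]
      dirichlet[[paste0("particle_surface_", i)]] <<-
        function(nodes) dipole_surface_potential(nodes, ci, c(0, 1), cfg$V0)
    })
  }
  cond <- solve_conduction(sm$mesh, list(gel = gel), dirichlet)
  # potential trace on the particle boundary drives the piezo solve
  hap_nodes <- boundary_nodes(mesh, "hap_surface")
  v_trace <- cond$V[sm$node_map[hap_nodes]]
  sol <- solve_piezo(mesh, list(gel = gel, hap = hap),
                     electric_subdomains = "hap",
                     elec_nodes = hap_nodes, elec_values = v_trace,
                     mech_fixed = c("outer_top", "outer_bottom", "outer_side"))
  hap_e <- mesh$subdomain == "hap"
  areas <- tri_areas(mesh)
  hn <- sort(unique(as.vector(mesh$elem[hap_e, ])))
  u_mag <- sqrt(rowSums(sol$u^2))
  # end faces in the body frame of the rectangle
  a <- rotation_deg * pi / 180
  axis <- c(-sin(a), cos(a))
  body_y <- mesh$nodes[hap_nodes, 1] * axis[1] + mesh$nodes[hap_nodes, 2] * axis[2]
  hl <- hap_length / 2
  top_f <- hap_nodes[body_y > hl * (1 - 1e-6)]
  bot_f <- hap_nodes[body_y < -hl * (1 - 1e-6)]
  u_top <- colMeans(sol$u[top_f, , drop = FALSE])
  u_bot <- colMeans(sol$u[bot_f, , drop = FALSE])
  # gel maximum outside the corner-singularity exclusion layer
  cent <- elem_centroids(mesh)
  bx <- cent[, 1] * cos(a) + cent[, 2] * sin(a)
  by <- -cent[, 1] * sin(a) + cent[, 2] * cos(a)
  dx <- pmax(abs(bx) - cfg$hap_width / 2, 0)
  dy <- pmax(abs(by) - hl, 0)
  dist_hap <- sqrt(dx^2 + dy^2)
  gel_far <- mesh$subdomain == "gel" & dist_hap > cfg$gel_exclusion
  res <- structure(list(
    hap_length = hap_length, rotation_deg = rotation_deg,
    V_hap = range(sol$V[hn]),
    u_max = max(u_mag[hn]),
    strain_repr = abs(strain_from_displacement(u_bot, u_top, axis, hap_length)),
    vm_hap_max = max(sol$vonMises[hap_e]),
    vm_hap_avg = sum(sol$vonMises[hap_e] * areas[hap_e]) / sum(areas[hap_e]),
    vm_gel_max = max(sol$vonMises[gel_far]),
    vm_gel_max_unmasked = max(sol$vonMises[mesh$subdomain == "gel"]),
    gel_exclusion = cfg$gel_exclusion,
    V0 = cfg$V0, mesh = mesh, conduction = cond, fields = sol
  ), class = "hap_response")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(mesh, file.path(out_dir,
                              sprintf("hap_%dnm_rot%d.vtk",
                                      round(hap_length * 1e9), round(rotation_deg))),
              point_data = list(V = ifelse(is.na(sol$V), 0, sol$V)),
              cell_data = list(vonMises = sol$vonMises, E_mag = sol$E_mag))
  }
  res
}

hap_row <- function(res) {
  data.frame(
    hap_length_nm = res$hap_length * 1e9,
    rotation_deg = res$rotation_deg,
    V_hap_min = res$V_hap[1], V_hap_max = res$V_hap[2],
    u_max_m = res$u_max,
    strain_repr = res$strain_repr,
    vm_hap_max_Pa = res$vm_hap_max,
    vm_hap_avg_Pa = res$vm_hap_avg,
    vm_gel_max_Pa = res$vm_gel_max
  )
}

#' Sweep particle size and orientation
#'
#' Runs the stage over the studied lengths and orientations and returns one
#' summary row per case.
#'
#' @param lengths particle lengths, m.
#' @param rotations orientations, degrees.
#' @param config stage configuration.
#' @param out_dir optional directory; writes `hap_sweep.csv`.
#' @return data.frame of [run_hap_stage()] summaries.
#' @export
run_hap_sweep <- function(lengths = c(100e-9, 200e-9, 400e-9),
                          rotations = 0, config = hap_config(),
                          out_dir = NULL) {
  rows <- list()
  for (L in lengths) for (rot in rotations) {
    rows[[length(rows) + 1L]] <-
      hap_row(run_hap_stage(L, rot, config, out_dir = out_dir))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "hap_sweep.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.hap_response <- function(x, ...) {
  cat("<hap_response> L =", x$hap_length * 1e9, "nm, rotation",
      x$rotation_deg, "deg\n")
  cat("  V on particle:", format(x$V_hap * 1e3, digits = 3), "mV;",
      "u_max:", format(x$u_max, digits = 3), "m\n")
  cat("  strain:", format(x$strain_repr, digits = 3),
      "; vm max/avg (particle):", format(x$vm_hap_max, digits = 3), "/",
      format(x$vm_hap_avg, digits = 3), "Pa; vm gel max:",
      format(x$vm_gel_max, digits = 3), "Pa\n")
  invisible(x)
}
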