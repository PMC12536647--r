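#' @title Stage (iv): 3D gel / cell / dipole-pair / hydroxyapatite model
#' @description
#' Conduction solve over the gel and cell slabs (dipole spheres as driven
#' surfaces, hydroxyapatite rod insulating), followed by a one-way coupled 3D
#' piezoelectric solve of the rod and its elastic neighbourhood. Reports the
#' electric field experienced by the rod (split by the surrounding medium in
#' the interface configuration) and the von Mises stress transmitted to the
#' cell and gel.
#' @name stage_3d
NULL

#' Summarise an element field over a subdomain
#'
#' Volume-weighted average and maximum of an element quantity over one
#' subdomain, optionally split by the side of the gel-cell interface plane
#' each element centroid lies on.
#'
#' @param sol `field_solution`.
#' @param subdomain subdomain label.
#' @param quantity `"E_mag"` or `"vonMises"` (any element field of `sol`).
#' @param split_by_neighbor if TRUE also return gel-side / cell-side maxima
#'   and averages (geometric partition at `z_interface`).
#' @param z_interface interface plane, m.
#' @return list with `max`, `avg` (and per-side entries when split).
#' @export
subdomain_field_summary <- function(sol, subdomain, quantity = "E_mag",
                                    split_by_neighbor = FALSE,
                                    z_interface = 0) {
  mesh <- sol$mesh
  sel <- mesh$subdomain == subdomain
  if (!any(sel)) stop("empty subdomain '", subdomain, "'")
  vals <- sol[[quantity]]
  if (is.null(vals)) stop("quantity '", quantity, "' not computed on solution")
  w <- abs(if (ncol(mesh$elem) == 4) tet_volumes(mesh) else tri_areas(mesh))
  out <- list(max = max(vals[sel]),
              avg = sum(vals[sel] * w[sel]) / sum(w[sel]))
  if (split_by_neighbor) {
    zc <- elem_centroids(mesh)[, ncol(mesh$nodes)]
    for (side in c("gel", "cell")) {
      ss <- sel & if (side == "gel") zc < z_interface else zc >= z_interface
      if (any(ss)) {
        out[[paste0(side, "_side_max")]] <- max(vals[ss])
        out[[paste0(side, "_side_avg")]] <- sum(vals[ss] * w[ss]) / sum(w[ss])
      }
    }
  }
  out
}

#' Default configuration of the 3D stage
#' @return named list (SI units).
#' @export
config3d <- function() {
  list(h = 16e-9, V0 = 1.36e-3, menp_x = 0.325e-6, menp_radius = 70e-9,
       hap_flats = 50e-9, hap_length = 100e-9, clearance = 0.05e-6,
       mech_box_xy = 0.2e-6, mech_box_z = c(-0.45e-6, 0.3e-6))
}

#' Run the 3D coupled stage
#'
#' @param config `"interface"` or `"embedded"`.
#' @param run_config list as [config3d()]; entries may be overridden.
#' @param out_dir optional output directory for VTK snapshots and the summary.
#' @return object of class `coupled3d_result`: `E_max_hap`, `E_avg_hap`
#'   (V/m), gel-/cell-side maxima in the interface configuration,
#'   `E_cv_hap` (coefficient of variation, uniformity measure),
#'   `vm_cell_max`, `vm_gel_max` (Pa), plus meshes and solutions.
#' @export
run_3d_stage <- function(config = c("interface", "embedded"),
                         run_config = config3d(), out_dir = NULL) {
  config <- match.arg(config)
  cfg <- utils::modifyList(config3d(), run_config)
  mesh <- make_3d_mesh(config, h = cfg$h, menp_x = cfg$menp_x,
                       menp_radius = cfg$menp_radius,
                       hap_flats = cfg$hap_flats, hap_length = cfg$hap_length,
                       clearance = cfg$clearance)
  gel <- get_material("alginate"); cell <- get_material("cell")
  hap <- get_material("HAP")  # c-axis along z = rod axis (vertical, unrotated)
  sph_z <- if (config == "embedded") -cfg$clearance - cfg$menp_radius else 0
  centers <- rbind(c(-cfg$menp_x, 0, sph_z), c(cfg$menp_x, 0, sph_z))
  # conduction over gel + cell (hap insulating hole)
  sm <- submesh(mesh, c("gel", "cell"))
  dirichlet <- list(outer_top = 0, outer_bottom = 0, outer_side = 0)
  for (i in 1:2) {
    local({
      ci <- centers[i, ]
      dirichlet[[paste0("particle_surface_", i)]] <<-
        function(nodes) dipole_surface_potential(nodes, ci, c(0, 0, 1), cfg$V0)
    })
  }
  cond <- solve_conduction(sm$mesh, list(gel = gel, cell = cell), dirichlet)
  # mechanical neighbourhood of the rod: elements within the mech box
  cen <- elem_centroids(mesh)
  inbox <- abs(cen[, 1]) < cfg$mech_box_xy & abs(cen[, 2]) < cfg$mech_box_xy &
    cen[, 3] > cfg$mech_box_z[1] & cen[, 3] < cfg$mech_box_z[2]
  mb <- mech_box_submesh(mesh, inbox)
  hap_nodes_glob <- boundary_nodes(mesh, "hap_surface")
  v_trace <- cond$V[sm$node_map[hap_nodes_glob]]
  hap_nodes <- mb$node_map[hap_nodes_glob]
  sol <- solve_piezo(mb$mesh, list(gel = gel, cell = cell, hap = hap),
                     electric_subdomains = "hap",
                     elec_nodes = hap_nodes, elec_values = v_trace,
                     mech_fixed = "mech_box_cut")
  Eh <- subdomain_field_summary(sol, "hap", "E_mag",
                                split_by_neighbor = (config == "interface"))
  vol <- abs(tet_volumes(mb$mesh))
  hsel <- mb$mesh$subdomain == "hap"
  ecv <- sqrt(sum(vol[hsel] * (sol$E_mag[hsel] - Eh$avg)^2) / sum(vol[hsel])) /
    Eh$avg
  vm_cell <- if (any(mb$mesh$subdomain == "cell")) {
    subdomain_field_summary(sol, "cell", "vonMises")$max
  } else 0
  vm_gel <- subdomain_field_summary(sol, "gel", "vonMises")$max
  res <- structure(list(
    config = config,
    E_max_hap = Eh$max, E_avg_hap = Eh$avg,
    E_gel_side_max = Eh$gel_side_max, E_cell_side_max = Eh$cell_side_max,
    E_cv_hap = ecv,
    vm_cell_max = vm_cell, vm_gel_max = vm_gel,
    V0 = cfg$V0, mesh = mesh, conduction = cond, mech_mesh = mb$mesh,
    fields = sol
  ), class = "coupled3d_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(sm$mesh, file.path(out_dir, sprintf("coupled3d_%s_conduction.vtk", config)),
              point_data = list(V = cond$V),
              cell_data = list(E_mag = cond$E_mag))
    write_vtk(mb$mesh, file.path(out_dir, sprintf("coupled3d_%s_mech.vtk", config)),
              point_data = list(V = ifelse(is.na(sol$V), 0, sol$V)),
              cell_data = list(vonMises = sol$vonMises, E_mag = sol$E_mag))
    utils::write.csv(coupled3d_row(res),
                     file.path(out_dir, sprintf("coupled3d_%s.csv", config)),
                     row.names = FALSE)
    write_plane_slices(res, out_dir)
  }
  res
}

# Sub-mesh of the elements flagged in `inbox`; the cut surface (exterior
# facets that are not already tagged) is tagged `mech_box_cut` for clamping.
mech_box_submesh <- function(mesh, inbox) {
  elem <- mesh$elem[inbox, , drop = FALSE]
  used <- sort(unique(as.vector(elem)))
  map <- integer(nrow(mesh$nodes)); map[used] <- seq_along(used)
  elem2 <- matrix(map[elem], ncol = 4L)
  key <- .row_keys(.elem_facets(elem2))
  ext <- which(key %in% names(which(table(key) == 1)))
  f <- .elem_facets(elem2)[ext, , drop = FALSE]
  bkeep <- matrixStats_all(matrix(map[mesh$bfacets] > 0, ncol = 3))
  bf <- matrix(map[mesh$bfacets[bkeep, , drop = FALSE]], ncol = 3)
  bt <- mesh$btags[bkeep]
  # facets of the cut = exterior facets not present among the kept tags
  have <- .row_keys(bf)
  newf <- f[!(.row_keys(f) %in% have), , drop = FALSE]
  m <- mp_mesh(mesh$nodes[used, , drop = FALSE], elem2,
               mesh$subdomain[inbox],
               rbind(bf, newf),
               c(bt, rep("mech_box_cut", nrow(newf))), coord = "3d")
  list(mesh = m, node_map = map)
}

matrixStats_all <- function(m) {
  out <- m[, 1]
  for (j in 2:ncol(m)) out <- out & m[, j]
  out
}

coupled3d_row <- function(res) {
  data.frame(
    config = res$config,
    E_max_hap = res$E_max_hap, E_avg_hap = res$E_avg_hap,
    E_gel_side_max = ifelse(is.null(res$E_gel_side_max), NA, res$E_gel_side_max),
    E_cell_side_max = ifelse(is.null(res$E_cell_side_max), NA, res$E_cell_side_max),
    E_cv_hap = res$E_cv_hap,
    vm_cell_max = res$vm_cell_max, vm_gel_max = res$vm_gel_max
  )
}

# Plane-sliced VTK snapshots: XY at the interface, XZ and YZ through the rod
# mid-height (element fields sampled on the slice planes).
write_plane_slices <- function(res, out_dir) {
  mesh <- res$mech_mesh
  cen <- elem_centroids(mesh)
  vm <- res$fields$vonMises
  # XY at the gel-cell interface; XZ and YZ through the rod axis
  slices <- list(XY = list(ax = 3, at = 0), XZ = list(ax = 2, at = 0),
                 YZ = list(ax = 1, at = 0))
  for (nm in names(slices)) {
    s <- slices[[nm]]
    sel <- abs(cen[, s$ax] - s$at) < 15e-9
    df <- data.frame(x = cen[sel, 1], y = cen[sel, 2], z = cen[sel, 3],
                     vonMises = vm[sel], E_mag = res$fields$E_mag[sel])
    utils::write.csv(df, file.path(out_dir,
                                   sprintf("slice_%s_%s.csv", nm, res$config)),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.coupled3d_result <- function(x, ...) {
  cat("<coupled3d_result>", x$config, "configuration\n")
  cat("  E on rod: avg", format(x$E_avg_hap, digits = 4), "V/m, max",
      format(x$E_max_hap, digits = 4), "V/m (CV",
      format(x$E_cv_hap, digits = 3), ")\n")
  if (!is.null(x$E_gel_side_max)) {
    cat("  gel-side max", format(x$E_gel_side_max, digits = 4),
        "/ cell-side max", format(x$E_cell_side_max, digits = 4), "V/m\n")
  }
  cat("  vm max: cell", format(x$vm_cell_max, digits = 4), "Pa, gel",
      format(x$vm_gel_max, digits = 4), "Pa\n")
  invisible(x)
}
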