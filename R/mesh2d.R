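#' @title Structured 2D mesh generation
#' @description
#' All planar and axisymmetric meshes are generated programmatically with a
#' structured "star-ray" scheme: a region bounded by an inner star-shaped
#' curve (particle circle, hydroxyapatite rectangle) and an outer rectangle is
#' meshed by connecting matching points on both curves along rays through the
#' region centre, with geometric grading of the radial layers. Shared block
#' edges take their node positions from common cut-line tables, so multi-block
#' meshes are conforming by construction.
#' @name mesh2d
NULL

# Uniformly spaced points on [a, b] with target spacing delta (endpoints kept).
seq_spaced <- function(a, b, delta) {
  n <- max(1L, as.integer(round(abs(b - a) / delta)))
  seq(a, b, length.out = n + 1L)
}

# Radial layer fractions 0 = inner .. 1 = outer, first layer ~ h/L, geometric.
geom_fractions <- function(L, h, grading = 1.35) {
  if (h >= L) return(c(0, 1))
  n <- max(2L, ceiling(log(1 + L * (grading - 1) / h) / log(grading)))
  s <- (grading^(0:n) - 1) / (grading^n - 1)
  s
}

# Radius function of a disc centred at the ray origin.
disc_rho <- function(radius) function(phi) rep(radius, length(phi))

# Radius function of a rectangle (half-width hw along x, half-length hl along
# y in the body frame) rotated by alpha_deg, centred at the ray origin.
rect_rho <- function(hw, hl, alpha_deg) {
  a <- alpha_deg * pi / 180
  function(phi) {
    dx <- cos(phi - a); dy <- sin(phi - a)
    1 / pmax(abs(dx) / hw, abs(dy) / hl)
  }
}

# World polar angles of the rectangle corners.
rect_corner_angles <- function(hw, hl, alpha_deg) {
  a <- alpha_deg * pi / 180
  cs <- rbind(c(hw, hl), c(-hw, hl), c(-hw, -hl), c(hw, -hl))
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  w <- cs %*% t(R)
  atan2(w[, 2], w[, 1])
}

# Mesh the band between an inner curve rho(phi) around `center` and a closed
# CCW perimeter polyline (matrix K x 2, no repeated first point). Returns a
# sub-mesh part for merge_meshes(). `outer_tags` has one entry per perimeter
# segment (k -> k+1, wrapping); NA entries produce no boundary facet.
ray_band_mesh <- function(center, rho_fun, perim, outer_tags,
                          h_near, grading = 1.35,
                          subdomain = "gel", inner_tag = NULL) {
  K <- nrow(perim)
  dx <- perim[, 1] - center[1]; dy <- perim[, 2] - center[2]
  phi <- atan2(dy, dx)
  rin <- rho_fun(phi)
  qx <- center[1] + rin * cos(phi); qy <- center[2] + rin * sin(phi)
  raylen <- sqrt((perim[, 1] - qx)^2 + (perim[, 2] - qy)^2)
  if (any(raylen <= 0)) stop("ray_band_mesh: inner curve touches the perimeter")
  s <- geom_fractions(max(raylen), h_near, grading)
  nl <- length(s)
  # node lattice: ring-major, rings j = 1..nl from inner to outer
  X <- outer(qx, rep(1, nl)) + outer(perim[, 1] - qx, s)
  Y <- outer(qy, rep(1, nl)) + outer(perim[, 2] - qy, s)
  nodes <- cbind(as.vector(X), as.vector(Y))
  idx <- matrix(seq_len(K * nl), K, nl)
  k2 <- c(2:K, 1L)
  tri <- vector("list", nl - 1L)
  for (j in seq_len(nl - 1L)) {
    a <- idx[, j]; b <- idx[k2, j]; cc <- idx[k2, j + 1L]; d <- idx[, j + 1L]
    # split each quad along its shorter diagonal
    dac <- (nodes[a, 1] - nodes[cc, 1])^2 + (nodes[a, 2] - nodes[cc, 2])^2
    dbd <- (nodes[b, 1] - nodes[d, 1])^2 + (nodes[b, 2] - nodes[d, 2])^2
    use_ac <- dac <= dbd
    tri[[j]] <- rbind(
      cbind(a, b, cc)[use_ac, , drop = FALSE],
      cbind(a, cc, d)[use_ac, , drop = FALSE],
      cbind(a, b, d)[!use_ac, , drop = FALSE],
      cbind(b, cc, d)[!use_ac, , drop = FALSE]
    )
  }
  tri <- do.call(rbind, tri)
  bf <- NULL; bt <- NULL
  if (!is.null(inner_tag)) {
    bf <- cbind(idx[, 1], idx[k2, 1])
    bt <- rep(inner_tag, K)
  }
  keep <- !is.na(outer_tags)
  if (any(keep)) {
    bf <- rbind(bf, cbind(idx[keep, nl], idx[k2, nl][keep]))
    bt <- c(bt, outer_tags[keep])
  }
  list(nodes = nodes, elem = tri,
       subdomain = rep(subdomain, nrow(tri)),
       bfacets = bf, btags = bt)
}

# Mesh the interior of a star-shaped polygon given its boundary nodes (K x 2,
# CCW) by shrinking rings towards `center`, ending in a fan.
star_interior_mesh <- function(center, ring, h, subdomain,
                               boundary_tag = NULL) {
  K <- nrow(ring)
  rho <- sqrt((ring[, 1] - center[1])^2 + (ring[, 2] - center[2])^2)
  nr <- max(2L, ceiling(min(rho) / h))
  sc <- seq(1, 1 / nr, length.out = nr)  # ring scales, outermost first
  X <- outer(ring[, 1] - center[1], sc) + center[1]
  Y <- outer(ring[, 2] - center[2], sc) + center[2]
  nodes <- rbind(cbind(as.vector(X), as.vector(Y)), center)
  ctr <- K * nr + 1L
  idx <- matrix(seq_len(K * nr), K, nr)
  k2 <- c(2:K, 1L)
  tri <- vector("list", nr)
  for (j in seq_len(nr - 1L)) {
    a <- idx[, j]; b <- idx[k2, j]; cc <- idx[k2, j + 1L]; d <- idx[, j + 1L]
    tri[[j]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  tri[[nr]] <- cbind(idx[, nr], idx[k2, nr], rep(ctr, K))
  tri <- do.call(rbind, tri)
  bf <- NULL; bt <- NULL
  if (!is.null(boundary_tag)) {
    bf <- cbind(idx[, 1], idx[k2, 1])
    bt <- rep(boundary_tag, K)
  }
  list(nodes = nodes, elem = tri,
       subdomain = rep(subdomain, nrow(tri)),
       bfacets = bf, btags = bt)
}

#' Structured rectangle mesh
#'
#' Plain right-triangle grid over a rectangle, used for analytic benchmark
#' problems (parallel plates, free piezoelectric bar).
#'
#' @param xlim,ylim extents, m.
#' @param nx,ny number of cells per direction.
#' @param subdomain element label.
#' @param coord `"planar"` or `"axisym"`.
#' @return `mp_mesh` with boundary tags `left`, `right`, `bottom`, `top`.
#' @export
rect_grid_mesh <- function(xlim, ylim, nx, ny, subdomain = "gel",
                           coord = "planar") {
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1L)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(1:nx, times = ny); j <- rep(1:ny, each = nx)
  a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  bf <- rbind(
    cbind(id(1:nx, 1L), id(2:(nx + 1L), 1L)),
    cbind(id(1:nx, ny + 1L), id(2:(nx + 1L), ny + 1L)),
    cbind(id(1L, 1:ny), id(1L, 2:(ny + 1L))),
    cbind(id(nx + 1L, 1:ny), id(nx + 1L, 2:(ny + 1L)))
  )
  bt <- c(rep("bottom", nx), rep("top", nx), rep("left", ny), rep("right", ny))
  orient_mesh(mp_mesh(nodes, tri, rep(subdomain, nrow(tri)), bf, bt,
                      coord = coord))
}

#' Axisymmetric particle-in-cylinder mesh
#'
#' Generic generator for axisymmetric geometries: one particle made of
#' concentric spherical layers centred at the origin of the r-z half-plane,
#' inside a cylindrical box. Used for the core-shell nanoparticle model and
#' for the dielectric/magnetizable-sphere benchmark oracles.
#'
#' @param radii increasing interface radii of the particle layers, m.
#' @param layer_names subdomain label per layer (length of `radii`).
#' @param box_r outer cylinder radius, m.
#' @param box_z half-height of the cylinder, m.
#' @param h element size near the particle, m.
#' @param medium_name subdomain label of the surrounding medium.
#' @param hole if TRUE the particle interior is left unmeshed and its surface
#'   becomes a tagged hole boundary (`particle_surface_1`).
#' @param grading geometric growth factor of the far-field layers.
#' @return `mp_mesh` (coord `"axisym"`) with boundary tags `axis`,
#'   `outer_top`, `outer_bottom`, `outer_side`, `particle_surface_1` and, for
#'   multi-layer particles, interior interface tags `<name1>_<name2>_interface`.
#' @export
make_axisym_particle_mesh <- function(radii, layer_names, box_r, box_z, h,
                                      medium_name = "gel", hole = FALSE,
                                      grading = 1.35) {
  stopifnot(length(radii) == length(layer_names), all(diff(c(0, radii)) > 0))
  Rp <- radii[length(radii)]
  if (box_r <= Rp || box_z <= Rp) stop("particle does not fit in the box")
  n_theta <- max(16L, ceiling(pi * Rp / h))
  theta <- seq(0, pi, length.out = n_theta + 1L)
  corner <- c(atan2(box_r, box_z), atan2(box_r, -box_z))
  for (th in corner) {
    if (min(abs(theta - th)) > 1e-9) theta <- sort(c(theta, th))
  }
  nt <- length(theta)
  st <- sin(theta); ct <- cos(theta)
  st[c(1, nt)] <- 0  # exact axis
  # ring radii inside the particle
  ring_r <- c(); ring_sub <- c()
  prev <- 0
  if (!hole) {
    for (L in seq_along(radii)) {
      thick <- radii[L] - prev
      nL <- max(if (L == length(radii)) 2L else 3L, ceiling(thick / h))
      rr <- prev + thick * seq_len(nL) / nL
      ring_r <- c(ring_r, rr)
      ring_sub <- c(ring_sub, rep(layer_names[L], nL))
      prev <- radii[L]
    }
  }
  # outer boundary distance per ray
  t_out <- rep(Inf, nt)
  pos <- st > 1e-14
  t_out[pos] <- box_r / st[pos]
  up <- ct > 1e-14; dn <- ct < -1e-14
  t_out[up] <- pmin(t_out[up], box_z / ct[up])
  t_out[dn] <- pmin(t_out[dn], -box_z / ct[dn])
  s <- geom_fractions(max(t_out) - Rp, h, grading)
  # lattice: columns = rings (particle rings then gel rings), rows = theta;
  # with a hole the particle-surface ring itself opens the lattice
  rad_mat <- if (hole) {
    Rp + outer(t_out - Rp, s)
  } else {
    cbind(matrix(ring_r, nt, length(ring_r), byrow = TRUE),
          Rp + outer(t_out - Rp, s[-1]))
  }
  nring <- ncol(rad_mat)
  Rr <- rad_mat * st
  Zz <- rad_mat * ct
  nodes <- cbind(as.vector(Rr), as.vector(Zz))
  idx <- matrix(seq_len(nt * nring), nt, nring)
  parts_nodes <- nodes
  tri <- list(); sub <- list()
  ring_labels <- c(ring_sub, rep(medium_name, nring - length(ring_sub)))
  if (!hole) {
    # centre fan
    ctr <- nrow(parts_nodes) + 1L
    parts_nodes <- rbind(parts_nodes, c(0, 0))
    tri[[1]] <- cbind(idx[1:(nt - 1L), 1], idx[2:nt, 1], rep(ctr, nt - 1L))
    sub[[1]] <- rep(ring_labels[1], nt - 1L)
  }
  for (j in seq_len(nring - 1L)) {
    a <- idx[1:(nt - 1L), j]; b <- idx[2:nt, j]
    cc <- idx[2:nt, j + 1L]; d <- idx[1:(nt - 1L), j + 1L]
    tri[[length(tri) + 1L]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
    sub[[length(sub) + 1L]] <- rep(ring_labels[j + 1L], 2L * (nt - 1L))
  }
  tri <- do.call(rbind, tri)
  sub <- unlist(sub)
  # boundary facets
  bf <- list(); bt <- list()
  add_b <- function(mat, tag) {
    bf[[length(bf) + 1L]] <<- mat
    bt[[length(bt) + 1L]] <<- rep(tag, nrow(mat))
  }
  # axis: theta = 0 and theta = pi columns (+ centre fan edge if meshed)
  ax1 <- idx[1L, ]; ax2 <- idx[nt, ]
  if (!hole) {
    ctr <- nrow(parts_nodes)
    add_b(rbind(c(ctr, ax1[1]), c(ctr, ax2[1])), "axis")
  }
  add_b(cbind(ax1[-nring], ax1[-1]), "axis")
  add_b(cbind(ax2[-nring], ax2[-1]), "axis")
  # outer boundary ring, tagged by face
  out_n <- idx[, nring]
  px <- parts_nodes[out_n, 1]; pz <- parts_nodes[out_n, 2]
  for (k in seq_len(nt - 1L)) {
    zmid <- (pz[k] + pz[k + 1]) / 2; rmid <- (px[k] + px[k + 1]) / 2
    tag <- if (abs(zmid - box_z) < 1e-12 * box_z) "outer_top"
           else if (abs(zmid + box_z) < 1e-12 * box_z) "outer_bottom"
           else "outer_side"
    add_b(matrix(c(out_n[k], out_n[k + 1]), 1, 2), tag)
  }
  # particle surface and layer interfaces
  surf_col <- if (hole) 1L else length(ring_sub)
  if (hole) {
    add_b(cbind(idx[-nt, 1L], idx[-1L, 1L]), "particle_surface_1")
  } else {
    add_b(cbind(idx[-nt, surf_col], idx[-1L, surf_col]), "particle_surface_1")
    if (length(radii) > 1) {
      for (L in seq_len(length(radii) - 1L)) {
        colL <- max(which(ring_sub == layer_names[L]))
        add_b(cbind(idx[-nt, colL], idx[-1L, colL]),
              paste0(layer_names[L], "_", layer_names[L + 1L], "_interface"))
      }
    }
  }
  m <- mp_mesh(parts_nodes, tri, sub, do.call(rbind, bf), unlist(bt),
               coord = "axisym")
  m$nodes[abs(m$nodes[, 1]) < 1e-20, 1] <- 0
  orient_mesh(m)
}

#' Axisymmetric core-shell nanoparticle mesh
#'
#' Half-plane (r >= 0) mesh of a magnetostrictive core, piezoelectric shell
#' and surrounding hydrogel cylinder, graded finer near the core-shell
#' interface.
#'
#' @param core_radius core radius, m (default 45 nm).
#' @param shell_thickness shell thickness, m (default 25 nm).
#' @param gel_side side of the square gel cross-section, m (default 1 um).
#' @param h element size near the particle, m; must resolve the shell with at
#'   least two elements across its thickness.
#' @return `mp_mesh` with subdomains `core`, `shell`, `gel`.
#' @export
make_menp_axisym_mesh <- function(core_radius = 45e-9,
                                  shell_thickness = 25e-9,
                                  gel_side = 1e-6, h = 6e-9) {
  stopifnot(core_radius > 0, shell_thickness > 0, h > 0)
  if (gel_side <= 2 * (core_radius + shell_thickness)) {
    stop("gel_side must exceed the particle diameter")
  }
  if (shell_thickness / h < 2) {
    stop("h = ", h, " m too coarse: fewer than 2 elements across the ",
         shell_thickness, " m shell")
  }
  make_axisym_particle_mesh(
    radii = c(core_radius, core_radius + shell_thickness),
    layer_names = c("core", "shell"),
    box_r = gel_side / 2, box_z = gel_side / 2, h = h, medium_name = "gel"
  )
}

#' Extract the sub-mesh of selected subdomains
#'
#' Elements outside `subdomains` are dropped and nodes renumbered; boundary
#' facets whose nodes survive are kept. Facet tags listed in `keep_tags` are
#' retained even if they become interior.
#'
#' @param mesh `mp_mesh`.
#' @param subdomains labels to keep.
#' @return list with `mesh` (the sub-mesh) and `node_map` (new index for each
#'   old node, NA if dropped).
#' @export
submesh <- function(mesh, subdomains) {
  keep <- mesh$subdomain %in% subdomains
  elem <- mesh$elem[keep, , drop = FALSE]
  used <- sort(unique(as.vector(elem)))
  map <- rep(NA_integer_, nrow(mesh$nodes))
  map[used] <- seq_along(used)
  bkeep <- apply(matrix(map[mesh$bfacets], ncol = ncol(mesh$bfacets)), 1,
                 function(r) !anyNA(r))
  m <- mp_mesh(mesh$nodes[used, , drop = FALSE],
               matrix(map[elem], ncol = ncol(elem)),
               mesh$subdomain[keep],
               matrix(map[mesh$bfacets[bkeep, , drop = FALSE]],
                      ncol = ncol(mesh$bfacets)),
               mesh$btags[bkeep], coord = mesh$coord)
  list(mesh = m, node_map = map)
}
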