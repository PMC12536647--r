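#' Dipole representation of nanoparticle arrays
#'
#' In the concentration and interaction stages each magnetoelectric
#' nanoparticle is reduced to an individual electric dipole: a circular
#' (2D) or spherical (3D) surface of radius 70 nm carrying the prescribed
#' potential `V0 * cos(theta)`, with `theta` measured from the magnetic-field
#' axis and `V0` the surface-potential amplitude of the single-particle
#' magnetoelectric solve.
#'
#' @name dipoles
NULL

#' Build a square grid of dipole particles
#'
#' Particles are placed on a uniform square grid with the given spacing,
#' centred in the gel domain, with `floor(gel_side / spacing)` particles per
#' side. With `jitter = "random"` each centre is displaced uniformly within a
#' disc of radius `spacing/2 - radius` (seeded, rejection-enforced
#' non-overlap), which keeps every particle inside its own grid cell.
#'
#' @param gel_side side of the square gel domain, m (default 10 um).
#' @param spacing inter-particle distance, m.
#' @param radius particle radius, m (default 70 nm).
#' @param jitter `"none"` or `"random"`.
#' @param seed RNG seed used when `jitter = "random"`.
#' @param V0 surface potential amplitude, V (default 1.36 mV, the reported
#'   single-particle shell potential).
#' @return object of class `dipole_array` with fields `centers`, `radius`,
#'   `axis`, `V0`, `spacing`, `gel_side`, `nominal`.
#' @export
make_dipole_grid <- function(gel_side = 10e-6, spacing,
                             radius = 70e-9,
                             jitter = c("none", "random"), seed = 1L,
                             V0 = 1.36e-3) {
  jitter <- match.arg(jitter)
  if (spacing <= 2 * radius) {
    stop("spacing must exceed the particle diameter (2 * radius)")
  }
  n <- floor(gel_side / spacing + 1e-9)
  if (n < 1) stop("spacing larger than the gel side: no particle fits")
  x0 <- -((n - 1) / 2) * spacing
  xs <- x0 + (seq_len(n) - 1L) * spacing
  nominal <- cbind(rep(xs, times = n), rep(xs, each = n))
  centers <- nominal
  if (jitter == "random") {
    rj <- spacing / 2 - radius
    centers <- with_local_seed(seed, {
      repeat {
        u <- sqrt(stats::runif(nrow(nominal))) * rj
        ph <- stats::runif(nrow(nominal), 0, 2 * pi)
        cand <- nominal + cbind(u * cos(ph), u * sin(ph))
        dmin <- min(stats::dist(cand))
        if (dmin > 2 * radius) break
      }
      cand
    })
  }
  structure(list(centers = centers, radius = radius, axis = c(0, 1),
                 V0 = V0, spacing = spacing, gel_side = gel_side,
                 nominal = nominal, placement = jitter),
            class = "dipole_array")
}

#' @export
print.dipole_array <- function(x, ...) {
  cat("<dipole_array>", nrow(x$centers), "particles, spacing",
      format(x$spacing * 1e6, digits = 3), "um, radius",
      format(x$radius * 1e9, digits = 3), "nm, V0",
      format(x$V0 * 1e3, digits = 3), "mV,", x$placement, "placement\n")
  invisible(x)
}

#' Mesh the gel domain around a dipole array
#'
#' One structured star-ray block per grid cell (particle interiors excluded as
#' holes), conforming across cells through shared cut-line node tables.
#'
#' @param dipoles `dipole_array` from [make_dipole_grid()].
#' @param delta target element size on the cell boundaries, m (default
#'   spacing/10).
#' @param h element size at the particle surfaces, m (default radius/2).
#' @return planar `mp_mesh` with subdomain `gel`, boundary tags `outer_*` and
#'   `particle_surface_<i>`.
#' @export
make_dipole_array_mesh <- function(dipoles, delta = NULL, h = NULL) {
  L <- dipoles$gel_side
  n <- as.integer(sqrt(nrow(dipoles$nominal)))
  sp <- dipoles$spacing
  if (is.null(delta)) delta <- sp / 10
  if (is.null(h)) h <- dipoles$radius / 2
  xs <- sort(unique(dipoles$nominal[, 1]))
  cuts <- c(-L / 2, (xs[-1] + xs[-n]) / 2, L / 2)
  seg <- lapply(seq_len(n), function(i) seq_spaced(cuts[i], cuts[i + 1], delta))
  parts <- vector("list", n * n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      pid <- (j - 1L) * n + i  # matches row order of `centers`
      bot <- cbind(seg[[i]], cuts[j])
      rgt <- cbind(cuts[i + 1], seg[[j]])
      top <- cbind(rev(seg[[i]]), cuts[j + 1])
      lft <- cbind(cuts[i], rev(seg[[j]]))
      perim <- rbind(bot[-nrow(bot), ], rgt[-nrow(rgt), ],
                     top[-nrow(top), ], lft[-nrow(lft), ])
      tags <- c(
        rep(if (j == 1) "outer_bottom" else NA_character_, nrow(bot) - 1L),
        rep(if (i == n) "outer_side" else NA_character_, nrow(rgt) - 1L),
        rep(if (j == n) "outer_top" else NA_character_, nrow(top) - 1L),
        rep(if (i == 1) "outer_side" else NA_character_, nrow(lft) - 1L)
      )
      parts[[pid]] <- ray_band_mesh(
        center = dipoles$centers[pid, ],
        rho_fun = disc_rho(dipoles$radius),
        perim = perim, outer_tags = tags, h_near = h,
        subdomain = "gel",
        inner_tag = paste0("particle_surface_", pid)
      )
    }
  }
  merge_meshes(parts, coord = "planar")
}

#' Dipole surface potential values at mesh nodes
#'
#' `V0 * cos(theta)` with `theta` measured from the dipole axis at each node
#' of the given particle surface, relative to the particle centre.
#'
#' @param nodes node coordinate matrix.
#' @param center particle centre.
#' @param axis dipole axis unit vector.
#' @param V0 amplitude, V.
#' @return numeric vector of potentials, V.
#' @export
dipole_surface_potential <- function(nodes, center, axis, V0) {
  d <- sweep(nodes, 2, center)
  r <- sqrt(rowSums(d^2))
  ct <- as.vector(d %*% axis) / pmax(r, 1e-300)
  V0 * ct
}
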