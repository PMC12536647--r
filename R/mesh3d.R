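#' @title Structured 3D mesh generation
#' @description
#' The 3D gel/cell model is meshed on a graded tensor grid. Grid cells away
#' from the particles become 12 tetrahedra each (centroid cone over the
#' min-index triangulation of the cell faces, which makes shared faces
#' conform automatically). Around each particle a rectangular block of the
#' grid is replaced by a star-ray shell: rays run from the block surface
#' nodes to the particle surface (sphere, or hexagonal prism), with
#' geometrically graded layers; the resulting warped hexahedra are split the
#' same way. Sphere interiors are holes carrying the dipole boundary
#' condition; the prism interior is meshed by coning its surface
#' triangulation to its centroid.
#' @name mesh3d
NULL

# Graded 1D axis: segments is a matrix with columns from, to, h.
graded_axis <- function(segments) {
  out <- segments[1, 1]
  for (r in seq_len(nrow(segments))) {
    s <- seq_spaced(segments[r, 1], segments[r, 2], segments[r, 3])
    out <- c(out, s[-1])
  }
  out
}

# Min-index triangulation of quads given as an n x 4 id matrix (cyclic order).
# Returns 2n x 3 triangles; shared quads triangulate identically on both sides.
quad_split <- function(q) {
  m0 <- max.col(-q)  # position of the smallest id
  idx <- function(off) q[cbind(seq_len(nrow(q)), (m0 - 1L + off) %% 4L + 1L)]
  a <- idx(0L); b <- idx(1L); cc <- idx(2L); d <- idx(3L)
  rbind(cbind(a, b, cc), cbind(a, cc, d))
}

# 12-tet centroid-cone split of hexes: hex8 is n x 8 (bottom ring 1:4, top
# ring 5:8, rings in the same cyclic sense), ctr is the centroid node id.
hex_cone_tets <- function(hex8, ctr) {
  faces <- list(hex8[, c(1, 2, 3, 4), drop = FALSE],
                hex8[, c(5, 6, 7, 8), drop = FALSE],
                hex8[, c(1, 2, 6, 5), drop = FALSE],
                hex8[, c(2, 3, 7, 6), drop = FALSE],
                hex8[, c(3, 4, 8, 7), drop = FALSE],
                hex8[, c(4, 1, 5, 8), drop = FALSE])
  do.call(rbind, lapply(faces, function(f) cbind(quad_split(f), rep(ctr, 2L))))
}

# Ray-box / ray-object distance functions for the 3D objects.
sphere_rho3 <- function(radius) function(d) rep(radius, nrow(d))
# Hexagonal prism: flats normal to angles 0/60/120 deg in xy, apothem w/2,
# caps at +-L/2 (directions in the object frame).
hexprism_rho3 <- function(across_flats, length_z) {
  ap <- across_flats / 2
  nx <- cos(c(0, pi / 3, 2 * pi / 3)); ny <- sin(c(0, pi / 3, 2 * pi / 3))
  function(d) {
    t <- rep(Inf, nrow(d))
    for (k in 1:3) {
      den <- abs(d[, 1] * nx[k] + d[, 2] * ny[k])
      t <- pmin(t, ifelse(den > 1e-14, ap / den, Inf))
    }
    den <- abs(d[, 3])
    pmin(t, ifelse(den > 1e-14, (length_z / 2) / den, Inf))
  }
}

#' Mesh the 3D gel / cell / dipole-pair / hydroxyapatite model
#'
#' Gel slab below, cell slab above (interface plane z = 0), two spherical
#' dipole holes flanking a vertical hexagonal hydroxyapatite rod along x.
#' In the `embedded` configuration all particles sit entirely in the gel with
#' a 0.05 um clearance between the rod's top face and the interface; in the
#' `interface` configuration the rod straddles the interface at mid-height
#' and the sphere centres lie on the interface plane.
#'
#' @param config `"interface"` or `"embedded"`.
#' @param h element size near the hydroxyapatite rod, m; must resolve the rod
#'   width with at least 2 elements.
#' @param domain_half half-extent of the footprint in x and y, m.
#' @param gel_depth,cell_height slab thicknesses, m.
#' @param menp_x sphere centre offset along x, m.
#' @param menp_radius sphere radius, m.
#' @param hap_flats rod edge-to-edge (across-flats) diameter, m.
#' @param hap_length rod length, m.
#' @param clearance embedded-configuration clearance below the interface, m.
#' @return 3D `mp_mesh` with subdomains `gel`, `cell`, `hap`; boundary tags
#'   `outer_top`, `outer_bottom`, `outer_side`, `particle_surface_1/2`,
#'   `hap_surface`, and (on grid faces) `gel_cell_interface`.
#' @export
make_3d_mesh <- function(config = c("interface", "embedded"), h = 13e-9,
                         domain_half = 0.5e-6, gel_depth = 1e-6,
                         cell_height = 1e-6, menp_x = 0.325e-6,
                         menp_radius = 70e-9, hap_flats = 50e-9,
                         hap_length = 100e-9, clearance = 0.05e-6) {
  config <- match.arg(config)
  if (hap_flats / h < 2) {
    stop("h = ", h, " m too coarse: fewer than 2 elements across the ",
         hap_flats, " m rod width")
  }
  R <- menp_radius
  if (config == "embedded") {
    hap_z <- c(-clearance - hap_length, -clearance)
    sph_z <- -clearance - R
  } else {
    hap_z <- c(-hap_length / 2, hap_length / 2)
    sph_z <- 0
  }
  hap_zc <- mean(hap_z)
  # block extents (grid-aligned boxes around each object)
  pad_s <- R * 0.5
  pad_h <- hap_flats * 0.8
  blk <- list(
    s1 = list(lo = c(-menp_x - R - pad_s, -R - pad_s, sph_z - R - pad_s),
              hi = c(-menp_x + R + pad_s, R + pad_s, sph_z + R + pad_s),
              center = c(-menp_x, 0, sph_z), rho = sphere_rho3(R),
              tag = "particle_surface_1", hole = TRUE),
    s2 = list(lo = c(menp_x - R - pad_s, -R - pad_s, sph_z - R - pad_s),
              hi = c(menp_x + R + pad_s, R + pad_s, sph_z + R + pad_s),
              center = c(menp_x, 0, sph_z), rho = sphere_rho3(R),
              tag = "particle_surface_2", hole = TRUE),
    hap = list(lo = c(-hap_flats / 2 - pad_h, -hap_flats / 2 - pad_h,
                      hap_z[1] - pad_h),
               hi = c(hap_flats / 2 + pad_h, hap_flats / 2 + pad_h,
                      hap_z[2] + pad_h),
               center = c(0, 0, hap_zc),
               rho = hexprism_rho3(hap_flats, hap_length),
               tag = "hap_surface", hole = FALSE)
  )
  H <- domain_half
  hs <- 2.3 * h   # sphere-block element size
  hm <- 2.8 * h   # between particles
  hf <- 7 * h     # far field
  xb <- rbind(c(-H, blk$s1$lo[1], hf), c(blk$s1$lo[1], blk$s1$hi[1], hs),
              c(blk$s1$hi[1], blk$hap$lo[1], hm),
              c(blk$hap$lo[1], blk$hap$hi[1], h),
              c(blk$hap$hi[1], blk$s2$lo[1], hm),
              c(blk$s2$lo[1], blk$s2$hi[1], hs), c(blk$s2$hi[1], H, hf))
  yb <- rbind(c(-H, blk$s1$lo[2], hf), c(blk$s1$lo[2], blk$hap$lo[2], hs),
              c(blk$hap$lo[2], blk$hap$hi[2], h),
              c(blk$hap$hi[2], blk$s1$hi[2], hs), c(blk$s1$hi[2], H, hf))
  zcuts <- sort(unique(c(-gel_depth, -0.35e-6, blk$s1$lo[3], blk$s1$hi[3],
                         blk$hap$lo[3], blk$hap$hi[3], 0, 0.25e-6,
                         cell_height)))
  zb <- NULL
  for (q in seq_len(length(zcuts) - 1L)) {
    mid <- (zcuts[q] + zcuts[q + 1]) / 2
    inblk <- (mid >= blk$hap$lo[3] && mid <= blk$hap$hi[3])
    insph <- (mid >= blk$s1$lo[3] && mid <= blk$s1$hi[3])
    hz <- if (inblk) h else if (insph) hs
      else if (abs(mid) < 0.36e-6) hm * 1.5 else hf * 1.6
    zb <- rbind(zb, c(zcuts[q], zcuts[q + 1], hz))
  }
  xs <- graded_axis(xb); ys <- graded_axis(yb); zs <- graded_axis(zb)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  ngrid <- nx * ny * nz
  grid_nodes <- cbind(rep(xs, times = ny * nz),
                      rep(rep(ys, each = nx), times = nz),
                      rep(zs, each = nx * ny))
  xtra <- list()  # appended nodes (centroids, shell layers, prism centre)
  n_extra <- 0L
  add_nodes <- function(coords) {
    xtra[[length(xtra) + 1L]] <<- coords
    ids <- ngrid + n_extra + seq_len(nrow(coords))
    n_extra <<- n_extra + nrow(coords)
    ids
  }
  # block index ranges (cells i: xs[i]..xs[i+1])
  cellidx <- function(vals, lo, hi) {
    i0 <- which.min(abs(vals - lo)); i1 <- which.min(abs(vals - hi))
    c(i0, i1 - 1L)
  }
  for (b in names(blk)) {
    blk[[b]]$ix <- cellidx(xs, blk[[b]]$lo[1], blk[[b]]$hi[1])
    blk[[b]]$iy <- cellidx(ys, blk[[b]]$lo[2], blk[[b]]$hi[2])
    blk[[b]]$iz <- cellidx(zs, blk[[b]]$lo[3], blk[[b]]$hi[3])
  }
  in_block <- function(i, j, k) {
    out <- rep(FALSE, length(i))
    for (b in blk) {
      out <- out | (i >= b$ix[1] & i <= b$ix[2] & j >= b$iy[1] & j <= b$iy[2] &
                      k >= b$iz[1] & k <= b$iz[2])
    }
    out
  }
  # ---- voxel region -------------------------------------------------------
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  keep <- !in_block(ci, cj, ck)
  ci <- ci[keep]; cj <- cj[keep]; ck <- ck[keep]
  n000 <- nid(ci, cj, ck); n100 <- nid(ci + 1L, cj, ck)
  n110 <- nid(ci + 1L, cj + 1L, ck); n010 <- nid(ci, cj + 1L, ck)
  n001 <- nid(ci, cj, ck + 1L); n101 <- nid(ci + 1L, cj, ck + 1L)
  n111 <- nid(ci + 1L, cj + 1L, ck + 1L); n011 <- nid(ci, cj + 1L, ck + 1L)
  hexv <- cbind(n000, n100, n110, n010, n001, n101, n111, n011)
  zmid <- (zs[ck] + zs[ck + 1L]) / 2
  ctr_ids <- add_nodes(cbind((xs[ci] + xs[ci + 1L]) / 2,
                             (ys[cj] + ys[cj + 1L]) / 2, zmid))
  tets <- list(hex_cone_tets(hexv, ctr_ids))
  subs <- list(rep(ifelse(zmid > 0, "cell", "gel"), times = 12L))
  bf <- list(); bt <- list()
  add_bf <- function(tris, tag) {
    bf[[length(bf) + 1L]] <<- tris
    bt[[length(bt) + 1L]] <<- rep(tag, nrow(tris))
  }
  # domain boundary quads
  face_quads <- function(fix_axis, fix_idx, tag) {
    if (fix_axis == 1L) {
      jj <- rep(seq_len(ny - 1L), times = nz - 1L)
      kk <- rep(seq_len(nz - 1L), each = ny - 1L)
      q <- cbind(nid(fix_idx, jj, kk), nid(fix_idx, jj + 1L, kk),
                 nid(fix_idx, jj + 1L, kk + 1L), nid(fix_idx, jj, kk + 1L))
    } else if (fix_axis == 2L) {
      ii <- rep(seq_len(nx - 1L), times = nz - 1L)
      kk <- rep(seq_len(nz - 1L), each = nx - 1L)
      q <- cbind(nid(ii, fix_idx, kk), nid(ii + 1L, fix_idx, kk),
                 nid(ii + 1L, fix_idx, kk + 1L), nid(ii, fix_idx, kk + 1L))
    } else {
      ii <- rep(seq_len(nx - 1L), times = ny - 1L)
      jj <- rep(seq_len(ny - 1L), each = nx - 1L)
      q <- cbind(nid(ii, jj, fix_idx), nid(ii + 1L, jj, fix_idx),
                 nid(ii + 1L, jj + 1L, fix_idx), nid(ii, jj + 1L, fix_idx))
    }
    add_bf(quad_split(q), tag)
  }
  face_quads(1L, 1L, "outer_side"); face_quads(1L, nx, "outer_side")
  face_quads(2L, 1L, "outer_side"); face_quads(2L, ny, "outer_side")
  face_quads(3L, 1L, "outer_bottom"); face_quads(3L, nz, "outer_top")
  # interface plane (voxel faces at z = 0 outside the blocks)
  k0 <- which(abs(zs) < 1e-15)
  if (length(k0) == 1L && k0 > 1L && k0 < nz) {
    ii <- rep(seq_len(nx - 1L), times = ny - 1L)
    jj <- rep(seq_len(ny - 1L), each = nx - 1L)
    okf <- !in_block(ii, jj, rep(k0, length(ii))) &
      !in_block(ii, jj, rep(k0 - 1L, length(ii)))
    q <- cbind(nid(ii, jj, k0), nid(ii + 1L, jj, k0),
               nid(ii + 1L, jj + 1L, k0), nid(ii, jj + 1L, k0))[okf, , drop = FALSE]
    if (nrow(q)) add_bf(quad_split(q), "gel_cell_interface")
  }
  # ---- particle blocks ----------------------------------------------------
  for (b in blk) {
    ix <- b$ix; iy <- b$iy; iz <- b$iz
    # surface quads of the block, outward ordering not required (orient later)
    sq <- list()
    grd <- function(ii, jj, kk) nid(ii, jj, kk)
    # x faces
    for (side in 1:2) {
      fi <- if (side == 1) ix[1] else ix[2] + 1L
      jj <- rep(iy[1]:iy[2], times = iz[2] - iz[1] + 1L)
      kk <- rep(iz[1]:iz[2], each = iy[2] - iy[1] + 1L)
      sq[[length(sq) + 1L]] <- cbind(grd(fi, jj, kk), grd(fi, jj + 1L, kk),
                                     grd(fi, jj + 1L, kk + 1L), grd(fi, jj, kk + 1L))
    }
    for (side in 1:2) {
      fj <- if (side == 1) iy[1] else iy[2] + 1L
      ii <- rep(ix[1]:ix[2], times = iz[2] - iz[1] + 1L)
      kk <- rep(iz[1]:iz[2], each = ix[2] - ix[1] + 1L)
      sq[[length(sq) + 1L]] <- cbind(grd(ii, fj, kk), grd(ii + 1L, fj, kk),
                                     grd(ii + 1L, fj, kk + 1L), grd(ii, fj, kk + 1L))
    }
    for (side in 1:2) {
      fk <- if (side == 1) iz[1] else iz[2] + 1L
      ii <- rep(ix[1]:ix[2], times = iy[2] - iy[1] + 1L)
      jj <- rep(iy[1]:iy[2], each = ix[2] - ix[1] + 1L)
      sq[[length(sq) + 1L]] <- cbind(grd(ii, jj, fk), grd(ii + 1L, jj, fk),
                                     grd(ii + 1L, jj + 1L, fk), grd(ii, jj + 1L, fk))
    }
    squads <- do.call(rbind, sq)
    snodes <- sort(unique(as.vector(squads)))
    P <- grid_nodes[snodes, , drop = FALSE]
    d <- sweep(P, 2, b$center)
    dn <- sqrt(rowSums(d^2))
    dhat <- d / dn
    rho <- b$rho(dhat)
    Q <- sweep(dhat * rho, 2, b$center, `+`)
    raylen <- dn - rho
    if (any(raylen <= 0)) stop("3D block: particle touches the block surface")
    nlay <- 4L
    gfrac <- rev((1.6^(0:nlay) - 1) / (1.6^nlay - 1))  # 1 at surface ... 0 at object
    layer_ids <- matrix(0L, length(snodes), nlay + 1L)
    layer_ids[, 1] <- snodes
    for (l in seq_len(nlay)) {
      f <- gfrac[l + 1L]
      layer_ids[, l + 1L] <- add_nodes(Q + (P - Q) * f)
    }
    smap <- integer(ngrid)
    smap[snodes] <- seq_along(snodes)
    # all layer coordinates indexed like layer_ids
    layer_xyz <- vector("list", nlay + 1L)
    layer_xyz[[1]] <- P
    for (l in seq_len(nlay)) layer_xyz[[l + 1L]] <- Q + (P - Q) * gfrac[l + 1L]
    sq_loc <- matrix(smap[as.vector(squads)], nrow(squads), 4L)
    for (l in seq_len(nlay)) {
      out <- matrix(layer_ids[cbind(as.vector(sq_loc), l)], nrow(squads), 4L)
      inn <- matrix(layer_ids[cbind(as.vector(sq_loc), l + 1L)], nrow(squads), 4L)
      hexs <- cbind(out, inn)
      co <- layer_xyz[[l]][as.vector(sq_loc), , drop = FALSE]
      cn <- layer_xyz[[l + 1L]][as.vector(sq_loc), , drop = FALSE]
      cen <- sapply(1:3, function(dd) {
        (rowSums(matrix(co[, dd], nrow(squads), 4L)) +
           rowSums(matrix(cn[, dd], nrow(squads), 4L))) / 8
      })
      if (nrow(squads) == 1L) cen <- matrix(cen, 1L, 3L)
      ctrs <- add_nodes(cen)
      tets[[length(tets) + 1L]] <- hex_cone_tets(hexs, ctrs)
      subs[[length(subs) + 1L]] <- rep(ifelse(cen[, 3] > 0, "cell", "gel"),
                                       times = 12L)
    }
    inner_q <- matrix(layer_ids[cbind(as.vector(sq_loc), nlay + 1L)],
                      nrow(squads), 4L)
    stris <- quad_split(inner_q)
    add_bf(stris, b$tag)
    if (!b$hole) {
      ctr_id <- add_nodes(matrix(b$center, 1))
      tets[[length(tets) + 1L]] <- cbind(stris, ctr_id)
      subs[[length(subs) + 1L]] <- rep("hap", nrow(stris))
    }
  }
  nodes <- rbind(grid_nodes, do.call(rbind, xtra))
  elem <- do.call(rbind, tets)
  sub <- unlist(subs)
  bfm <- do.call(rbind, bf)
  mesh <- mp_mesh(nodes, elem, sub, bfm, unlist(bt), coord = "3d")
  # drop unused grid nodes (block interiors, sphere holes)
  used <- sort(unique(c(as.vector(mesh$elem), as.vector(mesh$bfacets))))
  map <- integer(nrow(nodes)); map[used] <- seq_along(used)
  mesh$nodes <- nodes[used, , drop = FALSE]
  mesh$elem <- matrix(map[mesh$elem], ncol = 4L)
  mesh$bfacets <- matrix(map[mesh$bfacets], ncol = 3L)
  orient_mesh(mesh)
}

# Coordinates of node ids spanning the grid and appended extra nodes.
grid_nodes_at <- function(grid_nodes, xtra, ngrid, ids) {
  idv <- as.vector(ids)
  out <- matrix(0, length(idv), 3L)
  g <- idv <= ngrid
  out[g, ] <- grid_nodes[idv[g], , drop = FALSE]
  if (any(!g)) {
    xn <- do.call(rbind, xtra)
    out[!g, ] <- xn[idv[!g] - ngrid, , drop = FALSE]
  }
  out
}
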