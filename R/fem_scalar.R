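#' @title Linear P1 finite elements: scalar problems
#' @description
#' Assembly and solution of scalar diffusion problems
#' (`div(k grad u) = 0` plus optional uniform background drive) with linear
#' triangle or tetrahedral elements. Planar, axisymmetric (measure `2*pi*r`)
#' and 3D variants share the same code path. Used for stationary electric
#' conduction, electrostatics and the reduced-scalar-potential magnetostatics.
#' @name fem_scalar
NULL

# Per-element shape-function gradients and measures.
# 2D: returns b, c (m x 3) with grad(N_i) = (b_i, c_i), area A, centroid.
tri_geom <- function(mesh) {
  p <- mesh$nodes; e <- mesh$elem
  x <- matrix(p[e, 1], ncol = 3); y <- matrix(p[e, 2], ncol = 3)
  A <- 0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
                (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / (2 * A)
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / (2 * A)
  list(b = b, c = cc, A = A, rc = rowMeans(x), zc = rowMeans(y))
}

# 3D: grad(N_i) stored as an m x 4 x 3 array; volume V.
tet_geom <- function(mesh) {
  p <- mesh$nodes; e <- mesh$elem
  a <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  b <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cc <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  crossr <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
  bc <- crossr(b, cc); ca <- crossr(cc, a); ab <- crossr(a, b)
  det <- rowSums(a * bc)  # 6V
  g <- array(0, c(nrow(e), 4L, 3L))
  g[, 2, ] <- bc / det
  g[, 3, ] <- ca / det
  g[, 4, ] <- ab / det
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  list(g = g, V = det / 6)
}

# Element integration weights: area (planar), 2*pi*r_c*area (axisym), volume.
elem_weights <- function(mesh, geom = NULL) {
  if (mesh$coord == "3d") {
    if (is.null(geom)) geom <- tet_geom(mesh)
    geom$V
  } else {
    if (is.null(geom)) geom <- tri_geom(mesh)
    if (mesh$coord == "axisym") 2 * pi * geom$rc * geom$A else geom$A
  }
}

# Map a per-subdomain scalar onto elements.
coef_by_subdomain <- function(mesh, values) {
  out <- values[mesh$subdomain]
  if (anyNA(out)) {
    stop("missing coefficient for subdomain(s): ",
         paste(setdiff(unique(mesh$subdomain), names(values)), collapse = ", "))
  }
  unname(out)
}

# Assemble the stiffness matrix of div(k grad u) and optionally the load
# vector of a uniform background field G (per element rows): f_i = w k grad(N_i).G
scalar_system <- function(mesh, k_elem, G_elem = NULL) {
  n <- nrow(mesh$nodes)
  if (mesh$coord == "3d") {
    gm <- tet_geom(mesh)
    w <- k_elem * gm$V
    nl <- 4L
    gr <- function(i, d) gm$g[, i, d]
  } else {
    gm <- tri_geom(mesh)
    w <- k_elem * elem_weights(mesh, gm)
    nl <- 3L
    gr <- function(i, d) if (d == 1) gm$b[, i] else gm$c[, i]
  }
  m <- nrow(mesh$elem)
  nd <- if (mesh$coord == "3d") 3L else 2L
  ii <- jj <- xx <- vector("list", nl * nl)
  q <- 0L
  for (i in seq_len(nl)) {
    for (j in seq_len(nl)) {
      q <- q + 1L
      v <- 0
      for (d in seq_len(nd)) v <- v + gr(i, d) * gr(j, d)
      ii[[q]] <- mesh$elem[, i]; jj[[q]] <- mesh$elem[, j]; xx[[q]] <- w * v
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  f <- numeric(n)
  if (!is.null(G_elem)) {
    for (i in seq_len(nl)) {
      v <- 0
      for (d in seq_len(nd)) v <- v + gr(i, d) * G_elem[, d]
      f <- f + as.vector(tapply_add(w * v, mesh$elem[, i], n))
    }
  }
  list(K = K, f = f)
}

# Fast scatter-add of values into a length-n accumulator.
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Solve K u = f with Dirichlet constraints (indices dn, values dv).
solve_constrained <- function(K, f, dn, dv) {
  n <- nrow(K)
  if (!length(dn)) stop("no Dirichlet constraint: singular system")
  free <- setdiff(seq_len(n), dn)
  u <- numeric(n)
  u[dn] <- dv
  rhs <- f[free] - as.vector(K[free, dn, drop = FALSE] %*% dv)
  u[free] <- as.vector(Matrix::solve(K[free, free], rhs))
  u
}

# Element-wise gradient of a nodal scalar field.
nodal_gradient <- function(mesh, u, geom = NULL) {
  if (mesh$coord == "3d") {
    if (is.null(geom)) geom <- tet_geom(mesh)
    e <- mesh$elem
    cbind(
      rowSums(sapply(1:4, function(i) geom$g[, i, 1] * u[e[, i]])),
      rowSums(sapply(1:4, function(i) geom$g[, i, 2] * u[e[, i]])),
      rowSums(sapply(1:4, function(i) geom$g[, i, 3] * u[e[, i]]))
    )
  } else {
    if (is.null(geom)) geom <- tri_geom(mesh)
    e <- mesh$elem
    gx <- geom$b[, 1] * u[e[, 1]] + geom$b[, 2] * u[e[, 2]] + geom$b[, 3] * u[e[, 3]]
    gy <- geom$c[, 1] * u[e[, 1]] + geom$c[, 2] * u[e[, 2]] + geom$c[, 3] * u[e[, 3]]
    cbind(gx, gy)
  }
}

# Resolve a Dirichlet specification (list tag -> constant or function of the
# node coordinates) into node indices and values.
resolve_dirichlet <- function(mesh, dirichlet) {
  dn <- integer(0); dv <- numeric(0)
  for (tag in names(dirichlet)) {
    nodes <- boundary_nodes(mesh, tag)
    if (!length(nodes)) next
    spec <- dirichlet[[tag]]
    vals <- if (is.function(spec)) {
      spec(mesh$nodes[nodes, , drop = FALSE])
    } else rep(spec, length(nodes))
    keep <- !(nodes %in% dn)
    dn <- c(dn, nodes[keep]); dv <- c(dv, vals[keep])
  }
  list(nodes = dn, values = dv)
}

#' Solve a stationary electric conduction problem
#'
#' Solves `div(sigma grad V) = 0` with Dirichlet boundary values and natural
#' (insulating) conditions elsewhere; returns the potential and the electric
#' field `E = -grad V` per element.
#'
#' @param mesh `mp_mesh`.
#' @param materials named list mapping each subdomain to a
#'   [get_material()] record (or a list with a `conductivity` field).
#' @param dirichlet named list: boundary tag -> potential (constant in volts,
#'   or a function of the node-coordinate matrix returning volts).
#' @return `field_solution` with nodal `V`, element `E` and `E_mag`.
#' @export
solve_conduction <- function(mesh, materials, dirichlet) {
  sig <- vapply(materials, function(m) m$conductivity, numeric(1))
  if (any(sig[unique(mesh$subdomain)] <= 0)) {
    stop("conducting subdomains must have positive conductivity")
  }
  k <- coef_by_subdomain(mesh, sig)
  sys <- scalar_system(mesh, k)
  d <- resolve_dirichlet(mesh, dirichlet)
  if (!length(d$nodes)) stop("floating potential: at least one Dirichlet boundary required")
  V <- solve_constrained(sys$K, sys$f, d$nodes, d$values)
  E <- -nodal_gradient(mesh, V)
  field_solution(mesh, V = V, E = E)
}

#' Solve a magnetostatic problem with a reduced scalar potential
#'
#' Background field `H0 = B_applied / mu0` along `axis`; solves
#' `div(mu_r (H0 - grad phi)) = 0` with `phi = 0` on the outer boundary and
#' returns `H = H0 - grad phi` and the magnetization
#' `M = (mu_r - 1) H`, capped in magnitude at the saturation magnetization of
#' each subdomain.
#'
#' @param mesh `mp_mesh`.
#' @param materials named list of material records per subdomain (must carry
#'   `mu_r`; `Ms` used for the saturation cap, `Ms = 0` meaning no cap needed).
#' @param B_applied applied flux density, T.
#' @param axis unit vector of the applied field (length = mesh dimension);
#'   default +z (the second coordinate in 2D/axisymmetric meshes).
#' @return `field_solution` with `phi`, element fields `H`, `M` and `M_mag`.
#' @export
solve_magnetostatics <- function(mesh, materials, B_applied, axis = NULL) {
  if (B_applied < 0) stop("B_applied must be non-negative")
  mur <- vapply(materials, function(m) {
    if (is.null(m$mu_r)) stop("material without mu_r") else m$mu_r
  }, numeric(1))
  k <- coef_by_subdomain(mesh, mur)
  nd <- if (mesh$coord == "3d") 3L else 2L
  if (is.null(axis)) axis <- c(rep(0, nd - 1L), 1)
  H0 <- B_applied / mu0
  G <- matrix(rep(H0 * axis, each = nrow(mesh$elem)), ncol = nd)
  sys <- scalar_system(mesh, k, G_elem = G)
  outer_tags <- grep("^outer", unique(mesh$btags), value = TRUE)
  d <- resolve_dirichlet(mesh, stats::setNames(as.list(rep(0, length(outer_tags))),
                                               outer_tags))
  phi <- solve_constrained(sys$K, sys$f, d$nodes, d$values)
  H <- -nodal_gradient(mesh, phi)
  H <- sweep(H, 2, H0 * axis, `+`)
  chi <- coef_by_subdomain(mesh, mur) - 1
  M <- H * chi
  Ms <- coef_by_subdomain(mesh, vapply(materials, function(m) {
    if (is.null(m$Ms)) 0 else m$Ms
  }, numeric(1)))
  Mmag <- sqrt(rowSums(M^2))
  over <- Ms > 0 & Mmag > Ms
  if (any(over)) M[over, ] <- M[over, ] * (Ms[over] / Mmag[over])
  field_solution(mesh, phi = phi, H = H, M = M)
}

#' Field solution container
#'
#' Nodal and element fields from a solve, with derived magnitudes.
#'
#' @param mesh the mesh the fields live on.
#' @param ... named fields: nodal vectors (`V`, `phi`), nodal displacement
#'   matrix `u`, element matrices (`E`, `H`, `M`, Voigt `strain`/`stress`).
#' @return object of class `field_solution`.
#' @export
field_solution <- function(mesh, ...) {
  out <- list(mesh = mesh, ...)
  if (!is.null(out$E)) out$E_mag <- sqrt(rowSums(out$E^2))
  if (!is.null(out$M)) out$M_mag <- sqrt(rowSums(out$M^2))
  if (!is.null(out$stress)) out$vonMises <- von_mises_rows(out$stress)
  class(out) <- "field_solution"
  out
}

#' @export
print.field_solution <- function(x, ...) {
  flds <- setdiff(names(x), "mesh")
  cat("<field_solution> on", nrow(x$mesh$nodes), "nodes /",
      nrow(x$mesh$elem), "elements; fields:", paste(flds, collapse = ", "), "\n")
  invisible(x)
}
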