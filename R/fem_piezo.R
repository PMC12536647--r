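#' @title Linear P1 finite elements: elasticity and piezoelectricity
#' @description
#' Monolithic assembly of the coupled displacement/potential problem in
#' stress-charge form, `sigma = cE eps - t(e) E`, `D = e eps + eps0 eps_rs E`,
#' on triangles (plane strain or axisymmetric) and tetrahedra. Non-piezo
#' subdomains contribute plain elasticity and, inside the electric domain,
#' plain dielectric terms. Magnetostrictive loading enters as an eigenstrain
#' (stress-free strain) body load. The assembled block system
#' `[[Kuu, Kuv], [t(Kuv), -Kvv]]` is symmetric indefinite; symmetry is
#' asserted after assembly.
#' @name fem_piezo
NULL

# Strain interpolation structure per subdomain slice: for each Voigt index s,
# the nonzero element-dof columns and their per-element values.
.strain_ops <- function(mesh, geom, els) {
  nl <- ncol(mesh$elem)
  if (mesh$coord == "3d") {
    g <- geom$g[els, , , drop = FALSE]
    cols_c <- function(comp) comp + 3 * (0:3)
    gi <- function(i, d) g[, i, d]
    B <- vector("list", 6)
    B[[1]] <- list(cols = cols_c(1), vals = sapply(1:4, gi, d = 1))
    B[[2]] <- list(cols = cols_c(2), vals = sapply(1:4, gi, d = 2))
    B[[3]] <- list(cols = cols_c(3), vals = sapply(1:4, gi, d = 3))
    B[[4]] <- list(cols = c(cols_c(2), cols_c(3)),
                   vals = cbind(sapply(1:4, gi, d = 3), sapply(1:4, gi, d = 2)))
    B[[5]] <- list(cols = c(cols_c(1), cols_c(3)),
                   vals = cbind(sapply(1:4, gi, d = 3), sapply(1:4, gi, d = 1)))
    B[[6]] <- list(cols = c(cols_c(1), cols_c(2)),
                   vals = cbind(sapply(1:4, gi, d = 2), sapply(1:4, gi, d = 1)))
    Gm <- lapply(1:3, function(d) sapply(1:4, gi, d = d))
    return(list(B = B, G = Gm, dir = 1:3, ndu = 3L, nl = nl))
  }
  b <- geom$b[els, , drop = FALSE]; cc <- geom$c[els, , drop = FALSE]
  xcols <- c(1L, 3L, 5L); ycols <- c(2L, 4L, 6L)
  B <- vector("list", 6)
  if (mesh$coord == "axisym") {
    rc <- geom$rc[els]
    B[[1]] <- list(cols = xcols, vals = b)                    # eps_rr
    B[[2]] <- list(cols = xcols,
                   vals = matrix(1 / (3 * rc), length(els), 3))  # eps_theta
    B[[3]] <- list(cols = ycols, vals = cc)                   # eps_zz
    B[[5]] <- list(cols = c(xcols, ycols), vals = cbind(cc, b))  # gamma_rz
    dir <- c(1L, 3L)
  } else {
    B[[1]] <- list(cols = xcols, vals = b)
    B[[2]] <- list(cols = ycols, vals = cc)
    B[[6]] <- list(cols = c(xcols, ycols), vals = cbind(cc, b))
    dir <- c(1L, 2L)
  }
  list(B = B, G = list(b, cc), dir = dir, ndu = 2L, nl = nl)
}

# Assemble the coupled system. Returns the block matrix, the load vector, the
# u-dof count and the V-dof map (0 = node outside the electric domain).
assemble_piezo <- function(mesh, materials, electric_subs, eigenstrain = NULL) {
  n <- nrow(mesh$nodes)
  nl <- ncol(mesh$elem)
  geom <- if (mesh$coord == "3d") tet_geom(mesh) else tri_geom(mesh)
  w_all <- elem_weights(mesh, geom)
  ndu <- if (mesh$coord == "3d") 3L else 2L
  nu <- ndu * n
  enodes <- sort(unique(as.vector(
    mesh$elem[mesh$subdomain %in% electric_subs, , drop = FALSE])))
  vmap <- integer(n)
  vmap[enodes] <- seq_along(enodes)
  nV <- length(enodes)

  ti <- list(); tj <- list(); tx <- list()
  add_trip <- function(i, j, x) {
    ti[[length(ti) + 1L]] <<- i
    tj[[length(tj) + 1L]] <<- j
    tx[[length(tx) + 1L]] <<- x
  }
  Fv <- numeric(nu + nV)

  for (sd in unique(mesh$subdomain)) {
    mat <- materials[[sd]]
    if (is.null(mat)) stop("no material for subdomain '", sd, "'")
    els <- which(mesh$subdomain == sd)
    w <- w_all[els]
    ops <- .strain_ops(mesh, geom, els)
    elem <- mesh$elem[els, , drop = FALSE]
    eldof <- matrix(0L, length(els), ndu * nl)
    for (i in seq_len(nl)) for (d in seq_len(ndu)) {
      eldof[, ndu * (i - 1L) + d] <- ndu * (elem[, i] - 1L) + d
    }
    C <- mat$elasticity_cE
    ndof <- ndu * nl
    acc <- vector("list", ndof * ndof)
    for (s in 1:6) {
      Bs <- ops$B[[s]]; if (is.null(Bs)) next
      for (t in 1:6) {
        Bt <- ops$B[[t]]; if (is.null(Bt) || C[s, t] == 0) next
        for (ip in seq_along(Bs$cols)) {
          vi <- w * C[s, t] * Bs$vals[, ip]
          for (iq in seq_along(Bt$cols)) {
            k <- (Bs$cols[ip] - 1L) * ndof + Bt$cols[iq]
            v <- vi * Bt$vals[, iq]
            acc[[k]] <- if (is.null(acc[[k]])) v else acc[[k]] + v
          }
        }
      }
    }
    for (k in which(!vapply(acc, is.null, TRUE))) {
      p <- (k - 1L) %/% ndof + 1L; q <- (k - 1L) %% ndof + 1L
      add_trip(eldof[, p], eldof[, q], acc[[k]])
    }
    # eigenstrain load: F += w * t(B) %*% (C %*% eps*)
    if (!is.null(eigenstrain)) {
      es <- eigenstrain[els, , drop = FALSE]
      if (any(es != 0)) {
        sig0 <- es %*% t(C)
        for (s in 1:6) {
          Bs <- ops$B[[s]]; if (is.null(Bs) || all(sig0[, s] == 0)) next
          for (ip in seq_along(Bs$cols)) {
            v <- w * sig0[, s] * Bs$vals[, ip]
            Fv[seq_len(nu)] <- Fv[seq_len(nu)] +
              tapply_add(v, eldof[, Bs$cols[ip]], nu)
          }
        }
      }
    }
    if (!sd %in% electric_subs) next
    elv <- matrix(nu + vmap[elem], length(els), nl)
    e_m <- mat$piezo_e
    epsm <- eps0 * mat$permittivity_rs
    # coupling block Kuv (only where e is nonzero)
    for (s in 1:6) {
      Bs <- ops$B[[s]]; if (is.null(Bs)) next
      for (dd in seq_along(ops$dir)) {
        ee <- e_m[ops$dir[dd], s]
        if (ee == 0) next
        Gd <- ops$G[[dd]]
        for (ip in seq_along(Bs$cols)) {
          vi <- w * ee * Bs$vals[, ip]
          for (q in seq_len(nl)) {
            v <- vi * Gd[, q]
            add_trip(eldof[, Bs$cols[ip]], elv[, q], v)
            add_trip(elv[, q], eldof[, Bs$cols[ip]], v)
          }
        }
      }
    }
    # dielectric block -Kvv
    for (d1 in seq_along(ops$dir)) {
      for (d2 in seq_along(ops$dir)) {
        ep <- epsm[ops$dir[d1], ops$dir[d2]]
        if (ep == 0) next
        G1 <- ops$G[[d1]]; G2 <- ops$G[[d2]]
        for (p in seq_len(nl)) {
          vi <- w * ep * G1[, p]
          for (q in seq_len(nl)) {
            add_trip(elv[, p], elv[, q], -vi * G2[, q])
          }
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nu + nV, nu + nV))
  list(A = A, F = Fv, nu = nu, vmap = vmap, geom = geom, ndu = ndu)
}

#' Solve a (piezo)elastic boundary-value problem
#'
#' Monolithic coupled solve of displacement and electric potential. The
#' electric potential is carried on the subdomains listed in
#' `electric_subdomains`; piezoelectric coupling acts wherever the material's
#' coupling matrix is nonzero. The drive may be given as Dirichlet potential
#' boundary conditions (`elec_dirichlet`, by tag) or as explicit nodal values
#' (`elec_nodes`/`elec_values`, e.g. the trace of a conduction solution on the
#' particle surface). Rigid-body modes must be removed through `mech_fixed`
#' tags (all displacement components set to zero there); on axisymmetric
#' meshes the radial displacement is constrained on the axis automatically.
#'
#' @param mesh `mp_mesh`.
#' @param materials named list of material records per subdomain.
#' @param electric_subdomains subdomains carrying the potential unknown.
#' @param elec_dirichlet named list tag -> potential (V or function).
#' @param elec_nodes,elec_values explicit nodal potential constraints.
#' @param mech_fixed character vector of boundary tags clamped to u = 0.
#' @param mech_roller named list: boundary tag -> displacement component index
#'   constrained to zero (sliding support).
#' @param mech_point_fix optional integer node indices fully clamped (used to
#'   suppress rigid modes on free benchmark bodies).
#' @param eigenstrain optional m x 6 Voigt eigenstrain matrix (stress-free
#'   strain, engineering shears).
#' @return `field_solution` with nodal `u`, `V`, element `strain`, `stress`,
#'   `E`, `D`, `vonMises`.
#' @export
solve_piezo <- function(mesh, materials, electric_subdomains,
                        elec_dirichlet = NULL,
                        elec_nodes = NULL, elec_values = NULL,
                        mech_fixed = character(0),
                        mech_roller = NULL,
                        mech_point_fix = integer(0),
                        eigenstrain = NULL) {
  sys <- assemble_piezo(mesh, materials, electric_subdomains, eigenstrain)
  asym <- max(abs(sys$A - Matrix::t(sys$A)))
  if (asym > 1e-8 * max(abs(sys$A))) {
    stop("assembled piezo system lost symmetry (", asym, ")")
  }
  ndu <- sys$ndu
  fix_n <- integer(0)
  for (tag in mech_fixed) fix_n <- union(fix_n, boundary_nodes(mesh, tag))
  fix_n <- union(fix_n, mech_point_fix)
  dn <- as.vector(outer(seq_len(ndu), ndu * (fix_n - 1L), `+`))
  dv <- numeric(length(dn))
  for (tag in names(mech_roller)) {
    rn <- boundary_nodes(mesh, tag)
    dn <- c(dn, ndu * (rn - 1L) + mech_roller[[tag]])
    dv <- c(dv, numeric(length(rn)))
  }
  if (mesh$coord == "axisym") {
    ax <- which(abs(mesh$nodes[, 1]) < 1e-18)
    dn <- c(dn, ndu * (ax - 1L) + 1L)
    dv <- c(dv, numeric(length(ax)))
  }
  if (!is.null(elec_dirichlet)) {
    d <- resolve_dirichlet(mesh, elec_dirichlet)
    elec_nodes <- c(elec_nodes, d$nodes)
    elec_values <- c(elec_values, d$values)
  }
  if (length(elec_nodes)) {
    vd <- sys$vmap[elec_nodes]
    if (any(vd == 0)) stop("electric Dirichlet node outside the electric domain")
    dn <- c(dn, sys$nu + vd)
    dv <- c(dv, elec_values)
  }
  keep <- !duplicated(dn)
  dn <- dn[keep]; dv <- dv[keep]
  # equilibrate the u and V blocks (their diagonals differ by many decades)
  ntot <- nrow(sys$A)
  dg <- abs(Matrix::diag(sys$A))
  su <- sqrt(stats::median(dg[seq_len(sys$nu)][dg[seq_len(sys$nu)] > 0]))
  sv <- if (ntot > sys$nu) {
    sqrt(stats::median(dg[(sys$nu + 1):ntot][dg[(sys$nu + 1):ntot] > 0]))
  } else su
  scl <- c(rep(1 / su, sys$nu), rep(1 / sv, ntot - sys$nu))
  Dm <- Matrix::Diagonal(x = scl)
  A2 <- Dm %*% sys$A %*% Dm
  y <- solve_constrained(A2, scl * sys$F, dn, dv / scl[dn])
  x <- scl * y
  n <- nrow(mesh$nodes)
  u <- matrix(x[seq_len(sys$nu)], ncol = ndu, byrow = TRUE)
  V <- rep(NA_real_, n)
  V[sys$vmap > 0] <- x[sys$nu + seq_len(sum(sys$vmap > 0))]
  recover_fields(mesh, materials, u, V, eigenstrain, sys$geom,
                 electric_subdomains)
}

# Element strain / stress / E / D recovery.
recover_fields <- function(mesh, materials, u, V, eigenstrain, geom,
                           electric_subs) {
  m <- nrow(mesh$elem)
  strain <- matrix(0, m, 6)
  Efld <- matrix(0, m, 3)
  for (sd in unique(mesh$subdomain)) {
    els <- which(mesh$subdomain == sd)
    ops <- .strain_ops(mesh, geom, els)
    elem <- mesh$elem[els, , drop = FALSE]
    ndu <- ops$ndu
    for (s in 1:6) {
      Bs <- ops$B[[s]]; if (is.null(Bs)) next
      acc <- 0
      for (ip in seq_along(Bs$cols)) {
        node <- (Bs$cols[ip] - 1L) %/% ndu + 1L
        comp <- (Bs$cols[ip] - 1L) %% ndu + 1L
        acc <- acc + Bs$vals[, ip] * u[elem[, node], comp]
      }
      strain[els, s] <- acc
    }
    if (sd %in% electric_subs) {
      Vl <- V[elem]
      dim(Vl) <- dim(elem)
      for (dd in seq_along(ops$dir)) {
        Gd <- ops$G[[dd]]
        acc <- 0
        for (q in seq_len(ncol(elem))) acc <- acc + Gd[, q] * Vl[, q]
        Efld[els, ops$dir[dd]] <- -acc
      }
    }
  }
  stress <- matrix(0, m, 6)
  Dfld <- matrix(0, m, 3)
  for (sd in unique(mesh$subdomain)) {
    els <- which(mesh$subdomain == sd)
    mat <- materials[[sd]]
    es <- strain[els, , drop = FALSE]
    if (!is.null(eigenstrain)) es <- es - eigenstrain[els, , drop = FALSE]
    stress[els, ] <- es %*% t(mat$elasticity_cE) -
      Efld[els, , drop = FALSE] %*% mat$piezo_e
    Dfld[els, ] <- strain[els, , drop = FALSE] %*% t(mat$piezo_e) +
      Efld[els, , drop = FALSE] %*% (eps0 * t(mat$permittivity_rs))
  }
  E_out <- switch(mesh$coord,
    axisym = Efld[, c(1, 3), drop = FALSE],
    planar = Efld[, 1:2, drop = FALSE],
    Efld)
  field_solution(mesh, u = u, V = V, strain = strain, stress = stress,
                 E = E_out, D = Dfld)
}

#' Magnetostrictive eigenstrain from a magnetization field
#'
#' Isotropic quadratic small-signal model
#' `eps_me = (3/2) (lambda_s / Ms^2) (M ox M - |M|^2/3 I)`; traceless by
#' construction, reaching `eps_zz = lambda_s` at saturation along z.
#'
#' @param M magnetization, A/m: a length-2/3 vector or an m x 2 / m x 3
#'   matrix of element values (2-column input is interpreted as the r-z or
#'   x-z plane components).
#' @param Ms saturation magnetization, A/m (> 0).
#' @param lambda_s saturation magnetostriction (dimensionless).
#' @return Voigt 6-vector (engineering shears), or an m x 6 matrix.
#' @export
magnetostrictive_strain <- function(M, Ms, lambda_s) {
  if (Ms <= 0) stop("Ms must be positive")
  if (!is.matrix(M)) M <- matrix(M, 1)
  if (ncol(M) == 2) M <- cbind(M[, 1], 0, M[, 2])
  f <- 1.5 * lambda_s / Ms^2
  M2 <- rowSums(M^2)
  out <- cbind(
    f * (M[, 1]^2 - M2 / 3),
    f * (M[, 2]^2 - M2 / 3),
    f * (M[, 3]^2 - M2 / 3),
    2 * f * M[, 2] * M[, 3],
    2 * f * M[, 1] * M[, 3],
    2 * f * M[, 1] * M[, 2]
  )
  if (nrow(out) == 1) drop(out) else out
}
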