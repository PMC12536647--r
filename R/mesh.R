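#' Simplex mesh container
#'
#' Unstructured simplicial mesh used by every stage: triangles in 2D (planar
#' or axisymmetric r-z half-plane) or tetrahedra in 3D, with a subdomain label
#' per element and tagged boundary facets (edges in 2D, triangles in 3D).
#'
#' @param nodes numeric matrix, one row per node (m).
#' @param elem integer matrix, one row per simplex (3 or 4 columns).
#' @param subdomain character vector, one label per element.
#' @param bfacets integer matrix of boundary facets (2 or 3 columns).
#' @param btags character vector, one tag per boundary facet.
#' @param coord `"planar"`, `"axisym"` (x = r, y = z) or `"3d"`.
#' @return object of class `mp_mesh`.
#' @export
mp_mesh <- function(nodes, elem, subdomain, bfacets, btags,
                    coord = c("planar", "axisym", "3d")) {
  coord <- match.arg(coord)
  storage.mode(elem) <- "integer"
  storage.mode(bfacets) <- "integer"
  structure(list(nodes = nodes, elem = elem,
                 subdomain = as.character(subdomain),
                 bfacets = bfacets, btags = as.character(btags),
                 coord = coord, dim = ncol(nodes)),
            class = "mp_mesh")
}

#' @export
print.mp_mesh <- function(x, ...) {
  cat("<mp_mesh>", x$coord, ":", nrow(x$nodes), "nodes,",
      nrow(x$elem), "elements\n")
  cat("  subdomains:", paste(sort(unique(x$subdomain)), collapse = ", "), "\n")
  cat("  boundary tags:", paste(sort(unique(x$btags)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed areas of the triangles of a 2D mesh
#' @param mesh `mp_mesh` with triangle elements.
#' @return numeric vector, m^2 (planar measure; axisymmetric meshes return the
#'   r-z half-plane area).
#' @export
tri_areas <- function(mesh) {
  p <- mesh$nodes; e <- mesh$elem
  x1 <- p[e[, 1], 1]; y1 <- p[e[, 1], 2]
  x2 <- p[e[, 2], 1]; y2 <- p[e[, 2], 2]
  x3 <- p[e[, 3], 1]; y3 <- p[e[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Signed volumes of the tetrahedra of a 3D mesh
#' @param mesh `mp_mesh` with tetrahedral elements.
#' @return numeric vector, m^3.
#' @export
tet_volumes <- function(mesh) {
  p <- mesh$nodes; e <- mesh$elem
  a <- p[e[, 2], ] - p[e[, 1], ]
  b <- p[e[, 3], ] - p[e[, 1], ]
  d <- p[e[, 4], ] - p[e[, 1], ]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# Orient all simplices positively (swap two vertices where measure < 0).
orient_mesh <- function(mesh) {
  s <- if (ncol(mesh$elem) == 3) tri_areas(mesh) else tet_volumes(mesh)
  bad <- which(s < 0)
  if (length(bad)) {
    tmp <- mesh$elem[bad, 2]
    mesh$elem[bad, 2] <- mesh$elem[bad, 3]
    mesh$elem[bad, 3] <- tmp
  }
  mesh
}

#' Element centroids
#' @param mesh `mp_mesh`.
#' @return matrix of centroid coordinates, one row per element.
#' @export
elem_centroids <- function(mesh) {
  p <- mesh$nodes; e <- mesh$elem
  out <- 0
  for (k in seq_len(ncol(e))) out <- out + p[e[, k], , drop = FALSE]
  out / ncol(e)
}

#' Nodes lying on boundary facets with a given tag
#' @param mesh `mp_mesh`.
#' @param tag boundary tag (or vector of tags).
#' @return integer vector of node indices.
#' @export
boundary_nodes <- function(mesh, tag) {
  sel <- mesh$btags %in% tag
  sort(unique(as.vector(mesh$bfacets[sel, , drop = FALSE])))
}

# Sort small integer tuples row-wise (vectorized).
.sort_rows <- function(f) {
  if (ncol(f) == 2) {
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))
  } else {
    lo <- pmin(f[, 1], f[, 2], f[, 3])
    hi <- pmax(f[, 1], f[, 2], f[, 3])
    cbind(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
  }
}

.row_keys <- function(f) {
  s <- .sort_rows(f)
  do.call(paste, c(lapply(seq_len(ncol(s)), function(j) s[, j]), sep = "_"))
}

# Canonical facet keys (sorted vertex tuples) of all element facets.
.elem_facets <- function(elem) {
  if (ncol(elem) == 3) {
    f <- rbind(elem[, c(1, 2)], elem[, c(2, 3)], elem[, c(3, 1)])
  } else {
    f <- rbind(elem[, c(1, 2, 3)], elem[, c(1, 2, 4)],
               elem[, c(1, 3, 4)], elem[, c(2, 3, 4)])
  }
  .sort_rows(f)
}

#' Audit mesh conformity
#'
#' Checks that every element has positive measure, that no node is orphaned,
#' and that every exterior facet of the element complex (a facet referenced by
#' exactly one element) carries a boundary tag.
#'
#' @param mesh `mp_mesh`.
#' @return invisibly TRUE; errors with a description on failure.
#' @export
mesh_audit <- function(mesh) {
  s <- if (ncol(mesh$elem) == 3) tri_areas(mesh) else tet_volumes(mesh)
  if (any(s <= 0)) stop("mesh_audit: ", sum(s <= 0), " non-positive elements")
  used <- unique(as.vector(mesh$elem))
  if (length(used) != nrow(mesh$nodes)) {
    stop("mesh_audit: ", nrow(mesh$nodes) - length(used), " orphan nodes")
  }
  key <- .row_keys(.elem_facets(mesh$elem))
  ext <- names(which(table(key) == 1))
  bkey <- .row_keys(mesh$bfacets)
  missing <- setdiff(ext, bkey)
  if (length(missing)) {
    stop("mesh_audit: ", length(missing), " exterior facets without a boundary tag")
  }
  if (mesh$coord == "axisym" && min(mesh$nodes[, 1]) < -1e-15) {
    stop("mesh_audit: axisymmetric mesh has r < 0")
  }
  invisible(TRUE)
}

# Merge a list of sub-meshes, deduplicating nodes on exact coordinate keys.
# Sub-meshes built from shared cut-line tables reproduce shared coordinates
# bit-for-bit, so exact matching is safe.
merge_meshes <- function(parts, coord) {
  key_of <- function(p) {
    if (ncol(p) == 2) sprintf("%.12e_%.12e", p[, 1], p[, 2])
    else sprintf("%.12e_%.12e_%.12e", p[, 1], p[, 2], p[, 3])
  }
  all_nodes <- do.call(rbind, lapply(parts, `[[`, "nodes"))
  keys <- key_of(all_nodes)
  uk <- !duplicated(keys)
  glob <- match(keys, keys[uk])
  nodes <- all_nodes[uk, , drop = FALSE]
  off <- 0L
  elem <- list(); sub <- list(); bf <- list(); bt <- list()
  for (p in parts) {
    n <- nrow(p$nodes)
    map <- glob[(off + 1L):(off + n)]
    elem[[length(elem) + 1L]] <- matrix(map[p$elem], ncol = ncol(p$elem))
    sub[[length(sub) + 1L]] <- p$subdomain
    if (!is.null(p$bfacets) && nrow(p$bfacets)) {
      bf[[length(bf) + 1L]] <- matrix(map[p$bfacets], ncol = ncol(p$bfacets))
      bt[[length(bt) + 1L]] <- p$btags
    }
    off <- off + n
  }
  m <- mp_mesh(nodes, do.call(rbind, elem), unlist(sub),
               do.call(rbind, bf), unlist(bt), coord = coord)
  # interior facets can be tagged from both sides (subdomain interfaces);
  # deduplicate identical tagged facets
  bkey <- paste(.row_keys(m$bfacets), m$btags)
  keep <- !duplicated(bkey)
  m$bfacets <- m$bfacets[keep, , drop = FALSE]
  m$btags <- m$btags[keep]
  orient_mesh(m)
}
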