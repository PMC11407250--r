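# Labeled tetrahedral meshes: construction, geometry, surface extraction.
# Coordinates are millimetres throughout; optical coefficients stay in cm^-1
# until finite-element assembly (see forward.R).

#' Tissue labels recognized by the phantom generator
#'
#' Seven labels cover the layered maternal wall (fat, merged muscle/uterus,
#' amniotic fluid) and the fetal head (scalp muscle, merged skull/spinal cord,
#' cerebrospinal fluid, brain). Skull and spinal cord, and muscle and uterus,
#' share optical properties and are merged into single labels.
#'
#' @return Character vector of the seven valid labels.
#' @export
tissue_labels <- function() {
  c("maternal_fat", "maternal_muscle_uterus", "amniotic_fluid",
    "fetal_muscle", "fetal_skull_spinal", "fetal_csf", "fetal_brain")
}

#' Construct a labeled tetrahedral mesh
#'
#' Validates connectivity, fixes element orientation (all volumes positive),
#' extracts the boundary surface and computes lumped nodal volumes.
#'
#' @param nodes numeric matrix (n x 3), coordinates in mm.
#' @param elements integer matrix (m x 4) of node indices.
#' @param labels character vector of length m; values from [tissue_labels()].
#' @param param optional (n x 3) matrix of unbent ("parametric") coordinates;
#'   equals `nodes` for flat geometries. Column 3 is depth beneath the scanned
#'   surface.
#' @param bend_radius cylinder radius (mm) used to curve the phantom, or
#'   `NULL` for flat.
#' @return An object of class `tet_mesh`: list with `nodes`, `elements`,
#'   `labels`, `volumes`, `node_volumes`, `surface_faces`, `surface_elem`,
#'   `param`, `bend_radius`.
#' @export
tet_mesh <- function(nodes, elements, labels, param = NULL, bend_radius = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(elements) != 4L) stop("elements must be an m x 4 matrix")
  n <- nrow(nodes); m <- nrow(elements)
  if (any(elements < 1L) || any(elements > n))
    stop("element node index out of range")
  labels <- as.character(labels)
  if (length(labels) != m) stop("one label per element required")
  bad <- setdiff(unique(labels), tissue_labels())
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))

  vol <- tet_volumes(nodes, elements)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- elements[flip, 3L]
    elements[flip, 3L] <- elements[flip, 4L]
    elements[flip, 4L] <- tmp
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 1e-12)) {
    stop("degenerate element(s) with near-zero volume: ",
         paste(utils::head(which(vol <= 1e-12), 5), collapse = ", "))
  }
  if (!all(tabulate(elements, n) > 0L))
    stop("every node must belong to at least one element")

  sf <- boundary_faces(elements)
  nodevol <- as.vector(rowsum(rep(vol / 4, 4L), as.vector(elements)))
  # rowsum sorts by group; all nodes appear because connectivity was checked
  if (is.null(param)) param <- nodes
  structure(list(
    nodes = nodes, elements = elements, labels = labels,
    volumes = vol, node_volumes = nodevol,
    surface_faces = sf$faces, surface_elem = sf$elem,
    param = as.matrix(param), bend_radius = bend_radius,
    env = new.env(parent = emptyenv())
  ), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d elements, %d surface faces\n",
              nrow(x$nodes), nrow(x$elements), nrow(x$surface_faces)))
  cat("labels:", paste(sprintf("%s (%d)", names(table(x$labels)),
                               as.integer(table(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

# Signed volumes (det/6) for each tetrahedron, vectorized.
tet_volumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  a <- nodes[elements[, 2L], , drop = FALSE] - p1
  b <- nodes[elements[, 3L], , drop = FALSE] - p1
  cc <- nodes[elements[, 4L], , drop = FALSE] - p1
  cx <- b[, 2] * cc[, 3] - b[, 3] * cc[, 2]
  cy <- b[, 3] * cc[, 1] - b[, 1] * cc[, 3]
  cz <- b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

# Boundary faces = faces belonging to exactly one element.
boundary_faces <- function(elements) {
  m <- nrow(elements)
  combos <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  f <- rbind(elements[, combos[1, ]], elements[, combos[2, ]],
             elements[, combos[3, ]], elements[, combos[4, ]])
  eid <- rep.int(seq_len(m), 4L)
  a <- f[, 1]; b <- f[, 2]; cc <- f[, 3]
  lo <- pmin(a, b, cc); hi <- pmax(a, b, cc); mid <- a + b + cc - lo - hi
  o <- order(lo, mid, hi)
  lo <- lo[o]; mid <- mid[o]; hi <- hi[o]
  same_next <- c(lo[-1] == lo[-length(lo)] & mid[-1] == mid[-length(mid)] &
                   hi[-1] == hi[-length(hi)], FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  keep <- o[!(same_next | same_prev)]
  list(faces = f[keep, , drop = FALSE], elem = eid[keep])
}

#' Structured tetrahedral box mesh
#'
#' Subdivides a regular hexahedral grid into six tetrahedra per cell
#' (Freudenthal/Kuhn triangulation, conforming across cells). Used both as a
#' test fixture and as the parametric backbone of [build_phantom()].
#'
#' @param lx,ly,lz box edge lengths in mm (x, y and depth z).
#' @param edge target edge length in mm; the grid uses `ceiling(l/edge)` cells
#'   per direction.
#' @param label tissue label applied to every element.
#' @return A [tet_mesh()].
#' @export
tet_box_mesh <- function(lx, ly, lz, edge, label = "maternal_muscle_uterus") {
  if (edge <= 0) stop("target edge length must be positive")
  g <- box_grid(lx, ly, lz, edge)
  tet_mesh(g$nodes, g$elements, rep(label, nrow(g$elements)))
}

# Raw structured grid (nodes + Kuhn tetrahedra), no labels/validation.
box_grid <- function(lx, ly, lz, edge) {
  nx <- max(1L, as.integer(ceiling(lx / edge)))
  ny <- max(1L, as.integer(ceiling(ly / edge)))
  nz <- max(1L, as.integer(ceiling(lz / edge)))
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)

  cell <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- cell$i; j <- cell$j; k <- cell$k
  # the 8 corner ids of every cell
  corner <- function(di, dj, dk) idx(i + di, j + dj, k + dk)
  v <- list(
    `000` = corner(0L, 0L, 0L), `100` = corner(1L, 0L, 0L),
    `010` = corner(0L, 1L, 0L), `110` = corner(1L, 1L, 0L),
    `001` = corner(0L, 0L, 1L), `101` = corner(1L, 0L, 1L),
    `011` = corner(0L, 1L, 1L), `111` = corner(1L, 1L, 1L))
  key <- function(di, dj, dk) paste0(di, dj, dk)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  ex <- diag(3L)
  els <- vector("list", 6L)
  for (p in seq_along(perms)) {
    s1 <- ex[perms[[p]][1L], ]
    s2 <- s1 + ex[perms[[p]][2L], ]
    els[[p]] <- cbind(v[["000"]],
                      v[[key(s1[1], s1[2], s1[3])]],
                      v[[key(s2[1], s2[2], s2[3])]],
                      v[["111"]])
  }
  elements <- do.call(rbind, els)
  list(nodes = nodes, elements = elements,
       dims = c(nx, ny, nz), spacing = c(lx / nx, ly / ny, lz / nz))
}

# Map unbent coordinates (u, v, w=depth) onto a cylinder of radius R curved
# along v; arclength at the surface (w = 0) is preserved and depth stays
# radial. vc is the v-coordinate of the apex line.
bend_coordinates <- function(param, R, vc) {
  th <- (param[, 2] - vc) / R
  cbind(param[, 1],
        vc + (R - param[, 3]) * sin(th),
        R - (R - param[, 3]) * cos(th))
}

#' Locate the element containing a point
#'
#' Brute-force search ordered by centroid distance; returns the element index
#' and the barycentric weights of the point within it.
#'
#' @param mesh a [tet_mesh()].
#' @param p length-3 numeric point (mm, physical coordinates).
#' @param tol barycentric tolerance for containment.
#' @return list(element, weights) with `weights` of length 4.
#' @export
locate_point <- function(mesh, p, tol = 1e-8) {
  cen <- element_centroids(mesh)
  d2 <- (cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 + (cen[, 3] - p[3])^2
  ord <- order(d2)
  n_try <- min(length(ord), 512L)
  for (e in ord[seq_len(n_try)]) {
    w <- bary_weights(mesh$nodes, mesh$elements[e, ], p)
    if (all(w >= -tol)) return(list(element = e, weights = pmax(w, 0)))
  }
  stop("point (", paste(signif(p, 6), collapse = ", "), ") not inside mesh")
}

element_centroids <- function(mesh) {
  env <- mesh$env
  if (is.null(env$centroids)) {
    el <- mesh$elements
    env$centroids <- (mesh$nodes[el[, 1], , drop = FALSE] +
                        mesh$nodes[el[, 2], , drop = FALSE] +
                        mesh$nodes[el[, 3], , drop = FALSE] +
                        mesh$nodes[el[, 4], , drop = FALSE]) / 4
  }
  env$centroids
}

bary_weights <- function(nodes, elem, p) {
  p1 <- nodes[elem[1L], ]
  E <- cbind(nodes[elem[2L], ] - p1, nodes[elem[3L], ] - p1, nodes[elem[4L], ] - p1)
  lam <- tryCatch(solve(E, p - p1), error = function(e) rep(NA_real_, 3))
  if (anyNA(lam)) return(rep(-Inf, 4))
  c(1 - sum(lam), lam)
}

# Per-element gradients of the four P1 basis functions and element volumes.
# Returns list(grads = m x 4 x 3 array, vol = m vector). Cached on the mesh.
element_gradients <- function(mesh) {
  env <- mesh$env
  if (!is.null(env$grads)) return(env$grads)
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1L], , drop = FALSE]
  a <- mesh$nodes[el[, 2L], , drop = FALSE] - p1
  b <- mesh$nodes[el[, 3L], , drop = FALSE] - p1
  cc <- mesh$nodes[el[, 4L], , drop = FALSE] - p1
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, cc); cxa <- cross(cc, a); axb <- cross(a, b)
  det <- rowSums(a * bxc)
  g2 <- bxc / det; g3 <- cxa / det; g4 <- axb / det
  g1 <- -(g2 + g3 + g4)
  m <- nrow(el)
  grads <- array(0, dim = c(m, 4L, 3L))
  grads[, 1L, ] <- g1; grads[, 2L, ] <- g2; grads[, 3L, ] <- g3; grads[, 4L, ] <- g4
  env$grads <- list(grads = grads, vol = det / 6)
  env$grads
}

# Sparse accumulator mapping per-(element, local node) values to nodes:
# out = acc %*% vals where vals is stacked column-major by local node.
node_accumulator <- function(mesh) {
  env <- mesh$env
  if (is.null(env$acc)) {
    m <- nrow(mesh$elements)
    env$acc <- Matrix::sparseMatrix(
      i = as.vector(mesh$elements),
      j = seq_len(4L * m),
      x = 1,
      dims = c(nrow(mesh$nodes), 4L * m))
  }
  env$acc
}

#' Surface nodes of a mesh
#'
#' @param mesh a [tet_mesh()].
#' @return Integer vector of unique node indices on the boundary surface.
#' @export
surface_nodes <- function(mesh) sort(unique(as.vector(mesh$surface_faces)))

# Faces on the scanned (top) surface: all three nodes at parametric depth ~0.
top_surface_faces <- function(mesh, tol = 1e-6) {
  w <- mesh$param[, 3]
  on_top <- matrix(w[mesh$surface_faces] < tol, ncol = 3L)
  which(rowSums(on_top) == 3L)
}

#' Minimum distance from the scanned surface to a tissue label
#'
#' Nearest-neighbour distance between top-surface nodes and the nodes of all
#' elements carrying `label`. Used to verify that a requested brain depth was
#' realized by the mesh generator.
#'
#' @param mesh a [tet_mesh()].
#' @param label one of [tissue_labels()].
#' @return Minimum Euclidean distance in mm.
#' @export
surface_to_label_distance <- function(mesh, label) {
  el <- mesh$elements[mesh$labels == label, , drop = FALSE]
  if (!nrow(el)) stop("no elements labeled '", label, "'")
  tgt <- mesh$nodes[unique(as.vector(el)), , drop = FALSE]
  top <- unique(as.vector(mesh$surface_faces[top_surface_faces(mesh), ]))
  src <- mesh$nodes[top, , drop = FALSE]
  # chunked to bound memory on large meshes
  best <- Inf
  step <- 2000L
  for (s in seq(1L, nrow(src), by = step)) {
    idx <- s:min(s + step - 1L, nrow(src))
    d2 <- outer(rowSums(src[idx, , drop = FALSE]^2), rowSums(tgt^2), `+`) -
      2 * src[idx, , drop = FALSE] %*% t(tgt)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
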