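# Continuous-wave diffusion-equation forward solver (P1 finite elements).
#
# Weak form of -div(kappa grad phi) + mua phi = q with the Robin boundary
# condition phi + 2 A kappa dphi/dn = 0:
#
#   K(kappa) + M(mua) + B(1/(2A))  , all assembled in mm units
#
# kappa is element-wise constant (from the element's mua, mus'); the
# absorption mass term uses a P1 nodal interpolation of mua so that the
# absorption Jacobian is an exact derivative of the discrete system.
# Properties arrive in cm^-1 and are converted here (mua: /10 per mm,
# kappa: x10 mm).

#' Internal-reflection boundary coefficient
#'
#' Groenhuis/Keijzer polynomial approximation of the effective reflection
#' coefficient for a tissue-air refractive index mismatch; `A = 1` recovers
#' the matched boundary.
#'
#' @param n tissue refractive index relative to air.
#' @return boundary coefficient A (>= 1 for n > 1).
#' @export
boundary_A <- function(n) {
  reff <- -1.4399 / n^2 + 0.7099 / n + 0.6681 + 0.0636 * n
  (1 + reff) / (1 - reff)
}

#' Assemble the diffusion finite-element system
#'
#' @param mesh a [tet_mesh()].
#' @param props a [property_field()] (cm^-1 units).
#' @param A_override optional constant boundary coefficient (e.g. `A = 1` for
#'   analytic comparisons); default derives A per boundary face from the
#'   adjacent element's refractive index.
#' @param mua_nodal optional nodal mu_a (cm^-1) overriding the element-to-node
#'   conversion; used by the finite-difference Jacobian oracle.
#' @return Object of class `fem_system`: sparse SPD matrix `A`, `mesh`,
#'   `props`, nodal mu_a, cached factorization slot.
#' @export
assemble_fem <- function(mesh, props, A_override = NULL, mua_nodal = NULL) {
  if (length(props$mua) != nrow(mesh$elements))
    stop("property field does not match mesh")
  geo <- element_gradients(mesh)
  vol <- geo$vol
  if (any(vol <= 1e-12))
    stop("degenerate element at assembly: ",
         paste(utils::head(which(vol <= 1e-12), 3), collapse = ", "))
  el <- mesh$elements
  m <- nrow(el)
  kappa_mm <- props$kappa * 10

  # stiffness: K_ab = kappa * V * (grad_a . grad_b); 16 triplet blocks
  ii <- jj <- xx <- vector("list", 16L)
  blk <- 1L
  for (a in 1:4) for (b in 1:4) {
    dot <- geo$grads[, a, 1] * geo$grads[, b, 1] +
      geo$grads[, a, 2] * geo$grads[, b, 2] +
      geo$grads[, a, 3] * geo$grads[, b, 3]
    ii[[blk]] <- el[, a]; jj[[blk]] <- el[, b]
    xx[[blk]] <- kappa_mm * vol * dot
    blk <- blk + 1L
  }

  # absorption mass from nodal mua (P1 interpolated):
  # M_ab = V*(mua_a + mua_b + S)/120 for a != b, V*(2*mua_a + S)/60 on diag
  if (is.null(mua_nodal)) mua_nodal <- nodal_mua(mesh, props)
  mu_mm <- mua_nodal / 10
  MU <- matrix(mu_mm[el], ncol = 4L)
  S <- rowSums(MU)
  im <- jm <- xm <- vector("list", 16L)
  blk <- 1L
  for (a in 1:4) for (b in 1:4) {
    im[[blk]] <- el[, a]; jm[[blk]] <- el[, b]
    xm[[blk]] <- if (a == b) vol * (2 * MU[, a] + S) / 60
    else vol * (MU[, a] + MU[, b] + S) / 120
    blk <- blk + 1L
  }

  # Robin boundary: (1/(2A)) * triangle mass (Area/12 * [2 1 1; 1 2 1; 1 1 2])
  sf <- mesh$surface_faces
  q1 <- mesh$nodes[sf[, 1], , drop = FALSE]
  e1 <- mesh$nodes[sf[, 2], , drop = FALSE] - q1
  e2 <- mesh$nodes[sf[, 3], , drop = FALSE] - q1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  Af <- if (is.null(A_override)) boundary_A(props$n[mesh$surface_elem])
  else rep_len(A_override, nrow(sf))
  cb <- area / (2 * Af) / 12
  ib <- jb <- xb <- vector("list", 9L)
  blk <- 1L
  for (a in 1:3) for (b in 1:3) {
    ib[[blk]] <- sf[, a]; jb[[blk]] <- sf[, b]
    xb[[blk]] <- cb * (if (a == b) 2 else 1)
    blk <- blk + 1L
  }

  n <- nrow(mesh$nodes)
  Amat <- Matrix::sparseMatrix(
    i = c(unlist(ii), unlist(im), unlist(ib)),
    j = c(unlist(jj), unlist(jm), unlist(jb)),
    x = c(unlist(xx), unlist(xm), unlist(xb)),
    dims = c(n, n), symmetric = FALSE)
  Amat <- Matrix::forceSymmetric((Amat + Matrix::t(Amat)) / 2)
  structure(list(A = Amat, mesh = mesh, props = props,
                 mua_nodal = mua_nodal, n_nodes = n,
                 cache = new.env(parent = emptyenv())),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("fem_system: %d nodes, lambda %s nm, phase %s\n",
              x$n_nodes, format(x$props$lambda), x$props$phase))
  invisible(x)
}

fem_factor <- function(system) {
  if (is.null(system$cache$chol))
    system$cache$chol <- Matrix::Cholesky(system$A, LDL = FALSE, perm = TRUE)
  system$cache$chol
}

# Solve A x = b with one step of iterative refinement.
fem_solve_vec <- function(system, b) {
  ch <- fem_factor(system)
  x <- as.vector(Matrix::solve(ch, b, system = "A"))
  r <- b - as.vector(system$A %*% x)
  x <- x + as.vector(Matrix::solve(ch, r, system = "A"))
  x
}

#' Define an isotropic point source beneath a surface anchor
#'
#' The source is placed one transport mean free path (1/mu_s', i.e.
#' 10/mu_s'[cm^-1] mm) beneath the surface anchor along the inward surface
#' normal (parametric depth axis), and distributed onto the nodes of the
#' enclosing element with barycentric weights; total power is 1.
#'
#' @param mesh a [tet_mesh()].
#' @param anchor_uv length-2 parametric surface position (u, v) in mm.
#' @param props property field used to look up the local mu_s'.
#' @param depth optional explicit placement depth in mm, overriding 1/mu_s'.
#' @return Object of class `source_spec`: `rhs` sparse weight info
#'   (`nodes`, `weights`), `anchor_uv`, `depth`, `position` (physical mm).
#' @export
make_source <- function(mesh, anchor_uv, props, depth = NULL) {
  if (is.null(depth)) {
    probe <- param_to_physical(mesh, c(anchor_uv, 0.25 * min_edge(mesh)))
    e0 <- locate_point(mesh, probe)$element
    depth <- 10 / props$musp[e0]
  }
  if (depth <= 0) stop("source depth must be positive")
  pos <- param_to_physical(mesh, c(anchor_uv, depth))
  loc <- locate_point(mesh, pos)
  structure(list(nodes = mesh$elements[loc$element, ],
                 weights = loc$weights, element = loc$element,
                 anchor_uv = anchor_uv, depth = depth, position = pos,
                 power = 1),
            class = "source_spec")
}

param_to_physical <- function(mesh, p_uvw) {
  p_uvw <- rbind(p_uvw)
  if (is.null(mesh$bend_radius)) return(as.vector(p_uvw))
  as.vector(bend_coordinates(p_uvw, mesh$bend_radius, vc = max(mesh$param[, 2]) / 2))
}

min_edge <- function(mesh) {
  el1 <- mesh$elements[1L, ]
  d <- stats::dist(mesh$nodes[el1, ])
  min(d)
}

#' Solve the CW diffusion forward problem
#'
#' Sparse Cholesky factorization (cached on the system, reused across
#' sources) plus one iterative-refinement step; the relative residual is
#' checked against `tol`.
#'
#' @param system a [assemble_fem()] result.
#' @param source a [make_source()] result, or a raw right-hand-side vector.
#' @param tol maximum admissible relative residual.
#' @return Object of class `fluence_solution` with nodal fluence rate `phi`
#'   (s^-1 mm^-2 per unit source power), `lambda`, `phase`, `residual`.
#' @export
solve_fluence <- function(system, source, tol = 1e-10) {
  b <- numeric(system$n_nodes)
  if (inherits(source, "source_spec")) {
    b[source$nodes] <- b[source$nodes] + source$power * source$weights
  } else {
    b <- as.numeric(source)
    if (length(b) != system$n_nodes) stop("rhs length mismatch")
  }
  phi <- fem_solve_vec(system, b)
  res <- sqrt(sum((b - as.vector(system$A %*% phi))^2)) / sqrt(sum(b^2))
  if (!is.finite(res) || res > tol)
    stop(sprintf("forward solve did not converge: relative residual %.3e", res))
  structure(list(phi = phi, lambda = system$props$lambda,
                 phase = system$props$phase, residual = res,
                 source = if (inherits(source, "source_spec")) source else NULL),
            class = "fluence_solution")
}

#' Large-detector patch on the scanned surface
#'
#' A square patch (default 10 x 10 mm) centred on the detector anchor in the
#' parametric surface frame, sampled on a uniform grid with spacings below
#' 0.5 mm. Surface nodal fluence is linearly interpolated onto the grid via
#' the surface triangles, and the quadrature weights fold in `dx*dy`, so the
#' patch fluence is `sum(w * phi)` in s^-1.
#'
#' @param mesh a [tet_mesh()].
#' @param anchor_uv parametric (u, v) centre of the patch.
#' @param side patch side length in mm.
#' @param dx,dy grid spacings in mm (must be < 0.5).
#' @param strict if `TRUE`, a patch extending beyond the meshed surface is an
#'   error; otherwise it is clipped with a warning.
#' @return Object of class `detector_patch`: `nodes`, `weights` (quadrature
#'   already applied), grid point count `m`, `anchor_uv`, `side`.
#' @export
detector_patch <- function(mesh, anchor_uv, side = 10, dx = 0.4, dy = 0.4,
                           strict = TRUE) {
  if (dx >= 0.5 || dy >= 0.5) stop("patch grid spacings must be < 0.5 mm")
  umax <- max(mesh$param[, 1]); vmax <- max(mesh$param[, 2])
  u0 <- anchor_uv[1] - side / 2; u1 <- anchor_uv[1] + side / 2
  v0 <- anchor_uv[2] - side / 2; v1 <- anchor_uv[2] + side / 2
  if (u0 < 0 || v0 < 0 || u1 > umax || v1 > vmax) {
    if (strict) stop("detector patch extends beyond the meshed surface")
    warning("detector patch clipped to the meshed surface")
    u0 <- max(u0, 0); v0 <- max(v0, 0); u1 <- min(u1, umax); v1 <- min(v1, vmax)
  }
  nxg <- ceiling((u1 - u0) / dx); nyg <- ceiling((v1 - v0) / dy)
  dxe <- (u1 - u0) / nxg; dye <- (v1 - v0) / nyg   # exact tiling of the patch
  gu <- u0 + (seq_len(nxg) - 0.5) * dxe
  gv <- v0 + (seq_len(nyg) - 0.5) * dye
  gp <- cbind(rep(gu, times = nyg), rep(gv, each = nxg))

  tf <- top_surface_faces(mesh)
  faces <- mesh$surface_faces[tf, , drop = FALSE]
  P <- mesh$param
  # restrict to faces overlapping the patch bounding box
  fu <- matrix(P[faces, 1], ncol = 3L); fv <- matrix(P[faces, 2], ncol = 3L)
  cand <- which(apply(fu, 1, max) >= u0 - 1e-9 & apply(fu, 1, min) <= u1 + 1e-9 &
                  apply(fv, 1, max) >= v0 - 1e-9 & apply(fv, 1, min) <= v1 + 1e-9)
  assigned <- rep(FALSE, nrow(gp))
  tri_node <- matrix(0L, nrow(gp), 3L)
  tri_w <- matrix(0, nrow(gp), 3L)
  for (f in cand) {
    if (all(assigned)) break
    tri <- faces[f, ]
    au <- P[tri[1], 1]; av <- P[tri[1], 2]
    bu <- P[tri[2], 1] - au; bv <- P[tri[2], 2] - av
    cu <- P[tri[3], 1] - au; cv <- P[tri[3], 2] - av
    det <- bu * cv - cu * bv
    if (abs(det) < 1e-12) next
    open <- which(!assigned)
    pu <- gp[open, 1] - au; pv <- gp[open, 2] - av
    l2 <- (pu * cv - pv * cu) / det
    l3 <- (bu * pv - bv * pu) / det
    l1 <- 1 - l2 - l3
    ok <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    hit <- open[ok]
    if (length(hit)) {
      tri_node[hit, ] <- matrix(tri, length(hit), 3L, byrow = TRUE)
      tri_w[hit, ] <- cbind(pmax(l1[ok], 0), pmax(l2[ok], 0), pmax(l3[ok], 0))
      assigned[hit] <- TRUE
    }
  }
  if (!all(assigned)) stop("patch grid points could not be located on the surface")
  idx <- as.vector(tri_node)
  w <- as.vector(tri_w) * dxe * dye
  agg <- rowsum(w, idx)
  structure(list(nodes = as.integer(rownames(agg)), weights = as.vector(agg),
                 m = nrow(gp), dx = dxe, dy = dye,
                 anchor_uv = anchor_uv, side = side),
            class = "detector_patch")
}

#' Integrated fluence at a large detector
#'
#' `Phi = dx*dy*sum_i phi_i` over the patch's interpolation grid.
#'
#' @param sol a [solve_fluence()] result (or bare nodal vector).
#' @param patch a [detector_patch()].
#' @return Fluence Phi in s^-1.
#' @export
detector_fluence <- function(sol, patch) {
  phi <- if (inherits(sol, "fluence_solution")) sol$phi else as.numeric(sol)
  sum(patch$weights * phi[patch$nodes])
}

#' Channel fluence for a source-detector pair
#'
#' Convenience wrapper: solve (or reuse) the forward field of the source and
#' integrate it over the detector patch.
#'
#' @param system a [assemble_fem()] result.
#' @param source a [make_source()] result.
#' @param patch a [detector_patch()] (or any object with `nodes`/`weights`).
#' @return Phi in s^-1.
#' @export
channel_fluence <- function(system, source, patch) {
  sol <- solve_fluence(system, source)
  detector_fluence(sol, patch)
}

# Detector functional as a plain weight vector (adjoint right-hand side).
detector_rhs <- function(n_nodes, patch) {
  b <- numeric(n_nodes)
  b[patch$nodes] <- b[patch$nodes] + patch$weights
  b
}
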