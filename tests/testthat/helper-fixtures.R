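# Shared fixtures, built once per test run and cached. Everything is
# generated in code; meshes are kept small (~1k nodes) so the full module
# suite stays fast.

.fix <- new.env()

# Tiny maternal-fetal phantom: brain at 22.5 mm, head radius 20 mm.
tiny_spec <- function(curved = FALSE, ...) {
  args <- list(fat_thickness = 6, muscle_thickness = 6, fluid_gap = 3,
               fetal_head_radius = 20, shell_thicknesses = c(2, 3, 2.5),
               abdomen_curvature_radius = if (curved) 150 else NULL,
               target_edge_length = 6, extent = c(72, 60), depth = 42)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

tiny_phantom <- function(curved = FALSE) {
  key <- paste0("phantom_", curved)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_phantom(tiny_spec(curved))
  .fix[[key]]
}

# Full forward/sensitivity setup on the tiny flat phantom at 780 nm.
tiny_setup <- function() {
  if (!is.null(.fix$setup)) return(.fix$setup)
  mesh <- tiny_phantom()
  layout <- build_probe_layout(mesh, c(4L, 4L), extent = c(48, 36))
  channels <- group_channels(select_channels(layout, dmin = 10, dmax = 60),
                             edges = seq(10, 60, by = 10))
  props <- assign_properties(mesh, 780, "diastole")
  fem <- assemble_fem(mesh, props)
  so <- layout$optodes[layout$optodes$role == "source", ]
  de <- layout$optodes[layout$optodes$role == "detector", ]
  sources <- stats::setNames(lapply(seq_len(nrow(so)), function(i)
    make_source(mesh, c(so$u[i], so$v[i]), props)), as.character(so$id))
  patches <- stats::setNames(lapply(seq_len(nrow(de)), function(i)
    detector_patch(mesh, c(de$u[i], de$v[i]))), as.character(de$id))
  .fix$setup <- list(mesh = mesh, layout = layout, channels = channels,
                     props = props, fem = fem, sources = sources,
                     patches = patches)
  .fix$setup
}

# Jacobian over a 6-channel subset of the tiny setup (shared by the
# sensitivity, flatfield and acceptance tests).
tiny_jacobian <- function() {
  if (!is.null(.fix$jac)) return(.fix$jac)
  s <- tiny_setup()
  sub <- s$channels[c(1:4, nrow(s$channels) - 1L, nrow(s$channels)), ]
  .fix$jac <- list(jac = compute_jacobian(s$fem, sub, s$sources, s$patches),
                   sub = sub)
  .fix$jac
}

# Independent oracle: exact distance from a point to a triangle in 3D.
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(sqrt(sum((a + v * ab - p)^2)))
  }
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(sqrt(sum((a + w * ac - p)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((b + w * (c - b) - p)^2)))
  }
  den <- 1 / (va + vb + vc)
  v <- vb * den; w <- vc * den
  sqrt(sum((a + ab * v + ac * w - p)^2))
}

point_surface_distance <- function(mesh, p) {
  sf <- mesh$surface_faces
  best <- Inf
  # prefilter by vertex distance to keep the oracle quick
  vd <- sqrt(colSums((t(mesh$nodes[sf[, 1], , drop = FALSE]) - p)^2))
  for (f in order(vd)[seq_len(min(60L, nrow(sf)))]) {
    d <- point_triangle_distance(p, mesh$nodes[sf[f, 1], ],
                                 mesh$nodes[sf[f, 2], ], mesh$nodes[sf[f, 3], ])
    best <- min(best, d)
  }
  best
}
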