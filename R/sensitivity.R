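# Adjoint absorption Jacobians, distance-group sensitivity maps and
# fetal-brain channel ranking.
#
# For the discrete CW system A(mua) phi = q and a channel functional
# Phi = w' phi, the derivative with respect to nodal mua is
#   dPhi/dmua_j = -u' (dA/dmua_j) phi,   A u = w (adjoint field),
# where dA/dmua_j is the P1 triple-product matrix of the absorption mass
# term. The per-element contraction has the closed form used below (exact
# integrals of products of three barycentric coordinates).

#' Adjoint absorption Jacobian for a set of channels
#'
#' Rows are channels, columns mesh nodes; entries are dPhi_i/dmua_j in
#' s^-1 per cm^-1 and are non-positive (raising absorption anywhere cannot
#' increase detected fluence). One forward solve per distinct source and one
#' adjoint solve per distinct detector are performed against the cached
#' factorization.
#'
#' @param system a [assemble_fem()] result (baseline optical state).
#' @param channels channel data frame ([select_channels()]).
#' @param sources named list of [make_source()] objects keyed by
#'   `source_id`.
#' @param patches named list of [detector_patch()] objects keyed by
#'   `detector_id`.
#' @return Object of class `jacobian_matrix`: dense matrix `J`
#'   (channels x nodes) with the channel table as attribute, plus the
#'   per-channel fluences `Phi` (s^-1) that fall out of the same solves.
#' @export
compute_jacobian <- function(system, channels, sources, patches) {
  mesh <- system$mesh
  sid <- as.character(channels$source_id)
  did <- as.character(channels$detector_id)
  if (!all(sid %in% names(sources))) stop("channel references unknown source")
  if (!all(did %in% names(patches))) stop("channel references unknown detector")

  phi_s <- lapply(sources[unique(sid)], function(s) solve_fluence(system, s)$phi)
  adj_d <- lapply(patches[unique(did)], function(p)
    fem_solve_vec(system, detector_rhs(system$n_nodes, p)))

  geo <- element_gradients(mesh)
  vol <- geo$vol
  acc <- node_accumulator(mesh)
  el <- mesh$elements
  nch <- nrow(channels)
  J <- matrix(0, nch, system$n_nodes)
  Phi <- numeric(nch)
  for (i in seq_len(nch)) {
    phi <- phi_s[[sid[i]]]
    u <- adj_d[[did[i]]]
    Phi[i] <- sum(detector_rhs(system$n_nodes, patches[[did[i]]]) * phi)
    U <- matrix(u[el], ncol = 4L); P <- matrix(phi[el], ncol = 4L)
    Su <- rowSums(U); Sp <- rowSums(P); D <- rowSums(U * P)
    vals <- vector("list", 4L)
    for (j in 1:4) {
      uj <- U[, j]; pj <- P[, j]
      vals[[j]] <- vol * (uj * pj / 20 +
                            (uj * (Sp - pj) + pj * (Su - uj) + (D - uj * pj)) / 60 +
                            ((Su - uj) * (Sp - pj) - (D - uj * pj)) / 120)
    }
    # derivative wrt mua in mm^-1; /10 converts to per cm^-1
    J[i, ] <- as.vector(acc %*% unlist(vals, use.names = FALSE)) / -10
  }
  structure(list(J = J, channels = channels, Phi = Phi,
                 lambda = system$props$lambda, phase = system$props$phase),
            class = "jacobian_matrix")
}

#' @export
print.jacobian_matrix <- function(x, ...) {
  cat(sprintf("jacobian_matrix: %d channels x %d nodes (lambda %s nm)\n",
              nrow(x$J), ncol(x$J), format(x$lambda)))
  invisible(x)
}

#' Total normalized sensitivity map for a channel group
#'
#' Sums Jacobian rows over the member channels of one source-detector
#' distance group and normalizes by the maximum absolute value of the sum,
#' giving a per-node map in [-1, 1] with max |value| = 1 (readable as
#' percent of peak sensitivity).
#'
#' @param jac a [compute_jacobian()] result.
#' @param members integer indices (rows of `jac$J`) in the group, or a group
#'   label present in `jac$channels$group`.
#' @return list of class `group_sensitivity_map`: `map` (per node),
#'   `scale` (the normalizing max |sum|), `members`.
#' @export
total_normalized_jacobian <- function(jac, members) {
  if (is.character(members)) {
    members <- which(jac$channels$group == members)
  }
  if (!length(members)) stop("empty channel group")
  s <- colSums(jac$J[members, , drop = FALSE])
  scale <- max(abs(s))
  if (scale == 0) stop("group sensitivity is identically zero")
  structure(list(map = s / scale, scale = scale, members = members),
            class = "group_sensitivity_map")
}

#' Nodes belonging to elements with a given label
#'
#' @param mesh a [tet_mesh()].
#' @param label tissue label, default `"fetal_brain"`.
#' @return sorted integer node indices.
#' @export
label_nodes <- function(mesh, label = "fetal_brain") {
  el <- mesh$elements[mesh$labels == label, , drop = FALSE]
  if (!nrow(el)) stop("no elements labeled '", label, "'")
  sort(unique(as.vector(el)))
}

#' Per-channel fetal-brain sensitivity scores
#'
#' Default score of channel i = sum over brain nodes of |J_{i,j}|, divided
#' by the channel's own peak |J_{i,j}| over all nodes — i.e. the brain mass
#' of the channel's normalized sensitivity map. The normalization removes
#' the overall channel transmission (short channels have hugely larger raw
#' |J| everywhere simply because they detect more light), so scores are
#' comparable across distances and phantoms; the raw row mass is available
#' with `normalize = FALSE` and gives the same ordering within one distance
#' group.
#'
#' @param jac a [compute_jacobian()] result.
#' @param brain_nodes integer node indices (see [label_nodes()]).
#' @param normalize divide each row's brain mass by the row's peak |J|.
#' @return numeric vector, one non-negative score per channel.
#' @export
brain_sensitivity_scores <- function(jac, brain_nodes, normalize = TRUE) {
  if (!length(brain_nodes)) stop("empty brain node set")
  s <- rowSums(abs(jac$J[, brain_nodes, drop = FALSE]))
  if (normalize) s <- s / apply(abs(jac$J), 1L, max)
  s
}

#' Top-k channels of a group by brain sensitivity
#'
#' Descending score order; ties broken deterministically by shorter distance,
#' then lower channel id. Returns `min(k, group size)` rows.
#'
#' @param scores per-channel scores ([brain_sensitivity_scores()]).
#' @param channels the grouped channel table the scores refer to.
#' @param group group label (or `NULL` for all channels pooled).
#' @param k number of channels to keep.
#' @return data frame: `rank`, `channel`, `source_id`, `detector_id`,
#'   `distance`, `group`, `score`.
#' @export
rank_top_channels <- function(scores, channels, group = NULL, k = 10) {
  if (k <= 0) stop("k must be positive")
  idx <- if (is.null(group)) seq_len(nrow(channels))
  else which(channels$group == group)
  if (!length(idx)) stop("empty channel group '", group, "'")
  o <- idx[order(-scores[idx], channels$distance[idx], channels$channel[idx])]
  o <- o[seq_len(min(k, length(o)))]
  data.frame(rank = seq_along(o),
             channel = channels$channel[o],
             source_id = channels$source_id[o],
             detector_id = channels$detector_id[o],
             distance = channels$distance[o],
             group = if (is.null(channels$group)) NA_character_ else channels$group[o],
             score = scores[o])
}

#' Oriented segment records for ranked channels
#'
#' For plotting/export: the physical endpoints of each ranked channel, its
#' midpoint, and the brain node where its |J| peaks (the brain-surface region
#' the channel is most sensitive to).
#'
#' @param ranking a [rank_top_channels()] result.
#' @param layout the probe layout.
#' @param jac the Jacobian the ranking came from.
#' @param mesh the mesh (for brain node lookup).
#' @return data frame, one row per ranked channel.
#' @export
channel_orientation_map <- function(ranking, layout, jac, mesh) {
  brain <- label_nodes(mesh, "fetal_brain")
  opt <- layout$optodes
  rows <- lapply(seq_len(nrow(ranking)), function(r) {
    ch <- ranking$channel[r]
    i <- which(jac$channels$channel == ch)
    s <- opt[opt$id == ranking$source_id[r], ]
    d <- opt[opt$id == ranking$detector_id[r], ]
    jrow <- abs(jac$J[i, brain])
    peak <- brain[which.max(jrow)]
    data.frame(rank = ranking$rank[r], channel = ch,
               group = ranking$group[r], score = ranking$score[r],
               distance = ranking$distance[r],
               sx = s$x, sy = s$y, sz = s$z, dx = d$x, dy = d$y, dz = d$z,
               mx = (s$x + d$x) / 2, my = (s$y + d$y) / 2, mz = (s$z + d$z) / 2,
               peak_node = peak,
               px = mesh$nodes[peak, 1], py = mesh$nodes[peak, 2],
               pz = mesh$nodes[peak, 3])
  })
  do.call(rbind, rows)
}
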