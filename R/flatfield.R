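# Flat-field imaging sensitivity: uniform 1% absorption perturbation,
# (optionally noisy) difference data, and Moore-Penrose reconstruction with
# spatially variant regularization.

#' Uniformly perturb the absorption of a property field
#'
#' Scales mu_a by `1 + fraction` in every element; mu_s' and n are untouched
#' (the diffusion coefficient is recomputed from the perturbed mu_a).
#'
#' @param props a [property_field()].
#' @param fraction fractional mu_a increase (> 0), default 1%.
#' @return A new `property_field`.
#' @export
perturb_field <- function(props, fraction = 0.01) {
  if (fraction <= 0) stop("perturbation fraction must be positive")
  out <- props
  out$mua <- props$mua * (1 + fraction)
  out$kappa <- 1 / (3 * (out$mua + out$musp))
  out
}

#' Channel difference data from baseline and perturbed fluences
#'
#' `dPhi = Phi(baseline) - Phi(perturbed)` per channel, with independent
#' multiplicative Gaussian noise (standard deviation `k(r)` from the distance
#' dependent noise model) applied to each state before differencing, or
#' noiseless when `noise = NULL`.
#'
#' @param baseline,perturbed numeric vectors of channel fluences (same
#'   channel order).
#' @param distances channel source-detector distances in mm (needed with
#'   noise).
#' @param noise a [noise_model()] or `NULL`.
#' @return numeric vector dPhi.
#' @export
difference_data <- function(baseline, perturbed, distances = NULL, noise = NULL) {
  if (length(baseline) != length(perturbed))
    stop("baseline and perturbed channel sets differ")
  if (is.null(noise)) return(baseline - perturbed)
  if (is.null(distances) || length(distances) != length(baseline))
    stop("channel distances required to draw distance-dependent noise")
  k <- noise_std(distances, noise)
  nb <- baseline * (1 + stats::rnorm(length(baseline), 0, k))
  np <- perturbed * (1 + stats::rnorm(length(perturbed), 0, k))
  nb - np
}

#' Moore-Penrose flat-field reconstruction with spatially variant regularization
#'
#' Implements the regularized minimum-norm inversion
#' `dmua = D^{ -1/2 } Jt' (Jt Jt' + I)^{-1} dPhi_t` where
#' `D = diag(J'J) + alpha`, `alpha = 1e-2 max(diag(J'J))`,
#' `Jhat = J D^{-1/2}`, and the channel-space scaling
#' `E = diag(Jhat Jhat') + beta`, `beta = 1e-2 max(diag(Jhat Jhat'))`,
#' `Jt = E^{-1/2} Jhat`, `dPhi_t = E^{-1/2} dPhi`. The diagonal
#' inverse-square-root operators are applied consistently on both sides,
#' which is the standard measurement/sensitivity normalization that keeps
#' the final system well conditioned.
#'
#' @param J Jacobian matrix (channels x nodes) or a `jacobian_matrix`.
#' @param dphi channel difference data (length = rows of J).
#' @return Object of class `reconstruction_result`: `dmua` per node (cm^-1),
#'   `alpha`, `beta`, diagonal scalings `Linv`, `Minv`.
#' @export
reconstruct_flatfield <- function(J, dphi) {
  if (inherits(J, "jacobian_matrix")) J <- J$J
  J <- as.matrix(J)
  if (nrow(J) != length(dphi)) stop("J and dPhi are dimensionally inconsistent")
  cs <- colSums(J^2)
  rs0 <- rowSums(J^2)
  if (any(cs == 0) || any(rs0 == 0))
    stop("all-zero Jacobian row or column: scaling is singular")
  alpha <- 1e-2 * max(cs)
  Linv <- 1 / sqrt(cs + alpha)
  Jhat <- sweep(J, 2L, Linv, `*`)
  rs <- rowSums(Jhat^2)
  beta <- 1e-2 * max(rs)
  Minv <- 1 / sqrt(rs + beta)
  Jt <- Jhat * Minv             # row scaling
  dpt <- dphi * Minv
  G <- Matrix::tcrossprod(Jt)
  diag(G) <- diag(G) + 1
  z <- solve(G, dpt)
  dmua <- Linv * as.vector(crossprod(Jt, z))
  structure(list(dmua = dmua, alpha = alpha, beta = beta,
                 Linv = Linv, Minv = Minv),
            class = "reconstruction_result")
}

#' Summed, normalized flat-field map for a channel group
#'
#' Reconstructs each member channel individually (J restricted to one row),
#' sums the per-channel images and normalizes to max |value| = 1.
#'
#' @param jac a [compute_jacobian()] result.
#' @param dphi per-channel difference data aligned with `jac$channels`.
#' @param members row indices or group label selecting the member channels.
#' @return list of class `group_flatfield_map`: `map` (per node, in [-1,1]),
#'   `scale`, `members`.
#' @export
grouped_flatfield_map <- function(jac, dphi, members) {
  if (is.character(members)) members <- which(jac$channels$group == members)
  if (!length(members)) stop("empty channel group")
  total <- numeric(ncol(jac$J))
  for (i in members) {
    rec <- reconstruct_flatfield(jac$J[i, , drop = FALSE], dphi[i])
    total <- total + rec$dmua
  }
  scale <- max(abs(total))
  if (scale == 0) stop("flat-field map is identically zero")
  structure(list(map = total / scale, scale = scale, members = members),
            class = "group_flatfield_map")
}

#' Rule-of-thumb feasibility classification
#'
#' A tissue region is considered measurable when the normalized Jacobian
#' there exceeds `jac_threshold` (default 1%) and reconstructable when the
#' normalized flat-field value reaches `ff_range[1]` (nominally 1-10%).
#'
#' @param jac_map a [total_normalized_jacobian()] map (or bare vector).
#' @param ff_map a [grouped_flatfield_map()] map (or bare vector).
#' @param brain_nodes node indices of the region of interest.
#' @param jac_threshold normalized Jacobian threshold.
#' @param ff_range nominal flat-field band; values at or above the lower
#'   edge count as feasible.
#' @return list: `jac_max_brain`, `ff_max_brain`, `jac_feasible`,
#'   `ff_feasible`, `feasible`, `note`.
#' @export
classify_feasibility <- function(jac_map, ff_map, brain_nodes,
                                 jac_threshold = 0.01, ff_range = c(0.01, 0.10)) {
  jm <- if (is.list(jac_map)) jac_map$map else jac_map
  fm <- if (is.list(ff_map)) ff_map$map else ff_map
  jmax <- max(abs(jm[brain_nodes]))
  fmax <- max(abs(fm[brain_nodes]))
  jac_ok <- jmax > jac_threshold
  ff_ok <- fmax >= ff_range[1]
  list(jac_max_brain = jmax, ff_max_brain = fmax,
       jac_feasible = jac_ok, ff_feasible = ff_ok,
       feasible = jac_ok && ff_ok,
       note = sprintf(paste0("normalized Jacobian at brain %.3g (threshold %g); ",
                             "normalized flat field %.3g (band %g-%g)"),
                      jmax, jac_threshold, fmax, ff_range[1], ff_range[2]))
}
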