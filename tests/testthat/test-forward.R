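# Finite-element forward solver: assembly, solving, detector integration.

test_that("assembled system is symmetric positive definite", {
  mesh <- tet_box_mesh(18, 18, 18, 6)   # 4^3 = 64 nodes
  props <- uniform_properties(mesh, mua = 0.1, musp = 8)
  sys <- assemble_fem(mesh, props)
  A <- as.matrix(sys$A)
  expect_equal(A, t(A), tolerance = 1e-14)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("degenerate elements are rejected by name", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  good <- rbind(c(1L, 2L, 3L, 4L))
  flat <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 3L))  # zero-volume second
  expect_silent(tet_mesh(nodes[1:4, ], good, "fetal_brain"))
  expect_error(tet_mesh(nodes[1:4, ], flat, rep("fetal_brain", 2)),
               "degenerate element")
})

test_that("solution is linear in source power and monotone in absorption", {
  mesh <- tet_box_mesh(36, 36, 30, 6)
  props <- uniform_properties(mesh, mua = 0.1, musp = 8)
  sys <- assemble_fem(mesh, props)
  src <- make_source(mesh, c(18, 18), props)
  sol1 <- solve_fluence(sys, src)
  expect_true(all(is.finite(sol1$phi)))
  expect_lt(sol1$residual, 1e-10)
  src2 <- src; src2$power <- 2
  sol2 <- solve_fluence(sys, src2)
  expect_equal(sol2$phi, 2 * sol1$phi, tolerance = 1e-12)

  darker <- assemble_fem(mesh, uniform_properties(mesh, mua = 0.4, musp = 8))
  sol3 <- solve_fluence(darker, src)
  # restrict to the well-resolved region: the P1 point-source field
  # oscillates at ~1e-3 of peak near the singularity on this coarse fixture
  sig <- sol1$phi > 1e-2 * max(sol1$phi)
  expect_gt(sum(sig), 20)
  expect_true(all(sol3$phi[sig] < sol1$phi[sig]))

  # monotone decay along the surface away from the source
  ray <- which(abs(mesh$nodes[, 2] - 18) < 1e-9 & mesh$nodes[, 3] == 0 &
                 mesh$nodes[, 1] >= 18)
  ray <- ray[order(mesh$nodes[ray, 1])]
  expect_true(all(diff(sol1$phi[ray]) < 0))
})

test_that("source-detector exchange is symmetric for matched functionals", {
  mesh <- tet_box_mesh(40, 40, 30, 5)
  props <- uniform_properties(mesh, mua = 0.1, musp = 10)
  sys <- assemble_fem(mesh, props)
  sa <- make_source(mesh, c(12, 20), props)
  sb <- make_source(mesh, c(28, 20), props)
  rhs <- function(s) {
    b <- numeric(nrow(mesh$nodes)); b[s$nodes] <- s$weights; b
  }
  phi_ab <- sum(rhs(sb) * solve_fluence(sys, sa)$phi)
  phi_ba <- sum(rhs(sa) * solve_fluence(sys, sb)$phi)
  expect_lt(abs(phi_ab - phi_ba) / phi_ab, 1e-3 * 1e-3)  # far below 0.1%
})

test_that("detector patch quadrature is exact for constants and convergent", {
  mesh <- tiny_phantom()
  anchor <- c(36, 30)
  patch <- detector_patch(mesh, anchor)
  expect_equal(sum(patch$weights), 100, tolerance = 1e-9)   # 10 x 10 mm area
  expect_lt(patch$dx, 0.5)
  # constant field integrates to c * area
  expect_equal(detector_fluence(rep(3.5, nrow(mesh$nodes)), patch), 350,
               tolerance = 1e-9)
  # refinement oracle on a genuine solved field
  s <- tiny_setup()
  sol <- solve_fluence(s$fem, s$sources[[1]])
  fine <- detector_patch(mesh, anchor, dx = 0.1, dy = 0.1)
  expect_equal(detector_fluence(sol, patch), detector_fluence(sol, fine),
               tolerance = 0.01)
  expect_error(detector_patch(mesh, c(1, 1)), "beyond")
  expect_warning(p2 <- detector_patch(mesh, c(1, 30), strict = FALSE), "clipped")
  expect_lt(sum(p2$weights), 100)
  expect_error(detector_patch(mesh, anchor, dx = 0.6), "0.5")
})

test_that("boundary coefficient reduces to ~1 for matched media", {
  expect_equal(boundary_A(1), 1, tolerance = 5e-3)
  expect_gt(boundary_A(1.4), 2)   # strong internal reflection for tissue-air
})
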