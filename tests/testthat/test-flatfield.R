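# Flat-field perturbation, difference data and regularized reconstruction.

test_that("perturbation scales absorption only", {
  mesh <- tiny_phantom()
  pf <- assign_properties(mesh, 790)
  up <- perturb_field(pf, 0.01)
  expect_equal(up$mua, pf$mua * 1.01)
  expect_identical(up$musp, pf$musp)
  expect_identical(up$n, pf$n)
  twice <- perturb_field(perturb_field(pf, 0.01), 0.01)
  once <- perturb_field(pf, 1.01^2 - 1)
  expect_equal(twice$mua, once$mua, tolerance = 1e-12)
  expect_error(perturb_field(pf, 0), "positive")
})

test_that("difference data: null case, sign, determinism", {
  expect_equal(difference_data(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(difference_data(1:3, 1:2), "differ")
  base <- c(1e-6, 2e-7); pert <- base * 0.99
  expect_true(all(difference_data(base, pert) > 0))
  nm <- noise_model()
  set.seed(5); a <- difference_data(base, pert, c(30, 80), nm)
  set.seed(5); b <- difference_data(base, pert, c(30, 80), nm)
  expect_identical(a, b)
  expect_error(difference_data(base, pert, NULL, nm), "distances")
})

test_that("reconstruction equals a dense transcription of the equations", {
  jac <- tiny_jacobian()$jac
  J <- jac$J
  set.seed(3)
  dphi <- abs(rnorm(nrow(J), sd = 1e-8))
  rec <- reconstruct_flatfield(J, dphi)

  # independent dense oracle, written straight from the update equations
  D <- diag(t(J) %*% J)
  alpha <- 1e-2 * max(D)
  Linv <- diag(1 / sqrt(D + alpha))
  Jhat <- J %*% Linv
  E <- diag(Jhat %*% t(Jhat))
  beta <- 1e-2 * max(E)
  Minv <- diag(1 / sqrt(E + beta))
  Jt <- Minv %*% Jhat
  dpt <- Minv %*% dphi
  z <- solve(Jt %*% t(Jt) + diag(nrow(J)), dpt)
  oracle <- as.vector(Linv %*% t(Jt) %*% z)
  expect_equal(rec$dmua, oracle, tolerance = 1e-10)

  # exact linearity and the zero map
  rec2 <- reconstruct_flatfield(J, 3 * dphi)
  expect_equal(rec2$dmua, 3 * rec$dmua, tolerance = 1e-12)
  expect_equal(reconstruct_flatfield(J, rep(0, nrow(J)))$dmua,
               rep(0, ncol(J)))
  expect_true(all(rec$Linv > 0) && all(rec$Minv > 0))
  expect_error(reconstruct_flatfield(rbind(J, 0), c(dphi, 0)), "all-zero")
  expect_error(reconstruct_flatfield(J, dphi[-1]), "inconsistent")
})

test_that("grouped flat-field maps are normalized sums of member images", {
  jac <- tiny_jacobian()$jac
  set.seed(9)
  dphi <- abs(rnorm(nrow(jac$J), sd = 1e-8))
  gm <- grouped_flatfield_map(jac, dphi, 1:4)
  expect_equal(max(abs(gm$map)), 1)
  single <- grouped_flatfield_map(jac, dphi, 2L)
  rec <- reconstruct_flatfield(jac$J[2, , drop = FALSE], dphi[2])
  expect_equal(single$map, rec$dmua / max(abs(rec$dmua)), tolerance = 1e-12)
  expect_error(grouped_flatfield_map(jac, dphi, integer(0)), "empty")
})

test_that("feasibility classification follows the rule-of-thumb thresholds", {
  nodes <- 1:5
  lo <- rep(0.0005, 10); hi <- rep(0.02, 10)
  r1 <- classify_feasibility(lo, lo, nodes)
  expect_false(r1$feasible)
  r2 <- classify_feasibility(hi, hi, nodes)
  expect_true(r2$jac_feasible && r2$ff_feasible && r2$feasible)
  r3 <- classify_feasibility(hi, lo, nodes, jac_threshold = 0.01,
                             ff_range = c(0.0001, 0.1))
  expect_true(r3$ff_feasible)
})
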