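# Adjoint Jacobian, group normalization and channel ranking.

test_that("adjoint Jacobian matches central finite differences", {
  s <- tiny_setup()
  tj <- tiny_jacobian()
  jac <- tj$jac; sub <- tj$sub
  i <- 1L
  src <- s$sources[[as.character(sub$source_id[i])]]
  pat <- s$patches[[as.character(sub$detector_id[i])]]
  mu0 <- nodal_mua(s$mesh, s$props)
  jmax <- max(abs(jac$J[i, ]))
  nodes <- order(-abs(jac$J[i, ]))[c(1, 3, 10, 100, 400)]
  nodes <- nodes[abs(jac$J[i, nodes]) > 1e-6 * jmax]
  delta <- 1e-4
  for (j in nodes) {
    up <- mu0; up[j] <- mu0[j] + delta
    dn <- mu0; dn[j] <- mu0[j] - delta
    fd <- (channel_fluence(assemble_fem(s$mesh, s$props, mua_nodal = up), src, pat) -
             channel_fluence(assemble_fem(s$mesh, s$props, mua_nodal = dn), src, pat)) /
      (2 * delta)
    expect_lt(abs(jac$J[i, j] - fd) / abs(fd), 0.005)
  }
})

test_that("Jacobian entries are non-positive up to numerical leakage", {
  # P1 fields carry no discrete maximum principle, so tiny positive entries
  # (~1e-4 of the row peak on this coarse fixture) can appear; the bulk of
  # every row must be non-positive
  jac <- tiny_jacobian()$jac
  for (i in seq_len(nrow(jac$J)))
    expect_lt(max(jac$J[i, ]), 1e-3 * max(abs(jac$J[i, ])))
  neg_mass <- rowSums(abs(pmin(jac$J, 0))) / rowSums(abs(jac$J))
  expect_true(all(neg_mass > 0.999))
  expect_true(all(is.finite(jac$J)))
  # a short channel carries negligible sensitivity at depth
  s <- tiny_setup()
  short <- which.min(tiny_jacobian()$sub$distance)
  deep <- s$mesh$param[, 3] > 30
  row <- abs(jac$J[short, ])
  expect_lt(sum(row[deep]) / sum(row), 0.01)
})

test_that("total normalized Jacobian: unit peak, N=1 reduction, duplication", {
  jac <- tiny_jacobian()$jac
  m <- total_normalized_jacobian(jac, 1:4)
  expect_equal(max(abs(m$map)), 1)
  one <- total_normalized_jacobian(jac, 2L)
  expect_equal(one$map, jac$J[2, ] / max(abs(jac$J[2, ])))
  dup <- total_normalized_jacobian(jac, c(1:4, 1:4))
  expect_equal(dup$map, m$map, tolerance = 1e-12)
  expect_error(total_normalized_jacobian(jac, integer(0)), "empty")
})

test_that("brain scores agree with an explicit per-node summation", {
  s <- tiny_setup()
  jac <- tiny_jacobian()$jac
  brain <- label_nodes(s$mesh, "fetal_brain")
  sc_raw <- brain_sensitivity_scores(jac, brain, normalize = FALSE)
  sc <- brain_sensitivity_scores(jac, brain)
  # oracle: plain double loop, then per-row peak division
  sc2 <- peak <- numeric(nrow(jac$J))
  for (i in seq_len(nrow(jac$J))) {
    for (j in brain) sc2[i] <- sc2[i] + abs(jac$J[i, j])
    peak[i] <- max(abs(jac$J[i, ]))
  }
  expect_equal(sc_raw, sc2)
  expect_equal(sc, sc2 / peak)
  expect_true(all(sc >= 0))
  expect_error(brain_sensitivity_scores(jac, integer(0)), "empty")
  box <- tet_box_mesh(12, 12, 12, 6)
  expect_error(label_nodes(box, "fetal_brain"), "no elements")
})

test_that("ranking matches a full sort and breaks ties deterministically", {
  sub <- tiny_jacobian()$sub
  set.seed(11)
  sc <- runif(nrow(sub))
  rk <- rank_top_channels(sc, sub, group = NULL, k = 3)
  expect_equal(rk$channel, sub$channel[order(-sc)][1:3])
  # clamp: k beyond the group size returns everything sorted
  all_rk <- rank_top_channels(sc, sub, group = NULL, k = 100)
  expect_equal(nrow(all_rk), nrow(sub))
  expect_true(all(diff(all_rk$score) <= 0))
  # ties: equal scores resolved by shorter distance then lower channel id
  tied <- rep(1, nrow(sub))
  rt <- rank_top_channels(tied, sub, group = NULL, k = nrow(sub))
  expect_equal(rt$channel, sub$channel[order(sub$distance, sub$channel)])
  expect_error(rank_top_channels(sc, sub, k = 0), "positive")
  expect_error(rank_top_channels(sc, sub, group = "999-1000"), "empty")
})

test_that("orientation map exports one oriented segment per ranked channel", {
  s <- tiny_setup()
  jac <- tiny_jacobian()$jac
  sub <- tiny_jacobian()$sub
  brain <- label_nodes(s$mesh, "fetal_brain")
  sc <- brain_sensitivity_scores(jac, brain)
  rk <- rank_top_channels(sc, sub, group = NULL, k = 4)
  om <- channel_orientation_map(rk, s$layout, jac, s$mesh)
  expect_equal(nrow(om), nrow(rk))
  expect_true(all(om$peak_node %in% brain))
  # the best channel's midpoint sits above the fetal head
  ctr <- c(36, 30)
  expect_lt(sqrt(sum((c(om$mx[1], om$my[1]) - ctr)^2)),
            1.5 * tiny_spec()$fetal_head_radius)
})
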