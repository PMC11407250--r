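# Phantom generator, probe layout and channel grouping.

test_that("phantom_spec validates its geometry", {
  expect_error(tiny_spec(fat_thickness = 0), "positive")
  expect_error(phantom_spec(fetal_head_radius = 5,
                            shell_thicknesses = c(2, 3, 2.5)), "exceed")
  expect_error(phantom_spec(target_edge_length = -1), "positive")
  expect_error(phantom_spec(brain_depth = 99), "inconsistent")
  # consistency: derived brain depth is the sum of the layers above the brain
  sp <- tiny_spec()
  expect_equal(sp$brain_depth,
               sp$fat_thickness + sp$muscle_thickness + sp$fluid_gap +
                 sum(sp$shell_thicknesses))
})

test_that("build_phantom realizes the requested brain depth", {
  # oracle: nearest-neighbour distance from top-surface nodes to brain nodes
  mesh <- tiny_phantom()
  d <- surface_to_label_distance(mesh, "fetal_brain")
  expect_lt(abs(d - tiny_spec()$brain_depth), tiny_spec()$target_edge_length)

  # deepening the fluid gap by 15 mm moves the brain 15 mm down
  deep <- build_phantom(tiny_spec(fluid_gap = 18, depth = 56))
  d2 <- surface_to_label_distance(deep, "fetal_brain")
  expect_lt(abs(d2 - (tiny_spec()$brain_depth + 15)),
            tiny_spec()$target_edge_length)
})

test_that("phantom meshes are valid and deterministic", {
  mesh <- tiny_phantom()
  expect_true(all(mesh$volumes > 0))
  expect_true(all(tabulate(mesh$elements, nrow(mesh$nodes)) > 0))
  expect_setequal(unique(mesh$labels), tissue_labels())
  # node volumes partition the total volume
  expect_equal(sum(mesh$node_volumes), sum(mesh$volumes))
  # byte-identical rebuild
  again <- build_phantom(tiny_spec())
  expect_identical(mesh$nodes, again$nodes)
  expect_identical(mesh$elements, again$elements)
  expect_identical(mesh$labels, again$labels)
})

test_that("curved phantoms preserve surface arclength and positive volumes", {
  mesh <- tiny_phantom(curved = TRUE)
  expect_true(all(mesh$volumes > 0))
  # surface nodes sit on the bending cylinder
  top <- mesh$param[, 3] < 1e-9
  R <- mesh$bend_radius
  vc <- max(mesh$param[, 2]) / 2
  rad <- sqrt((mesh$nodes[top, 2] - vc)^2 + (R - mesh$nodes[top, 3])^2)
  expect_lt(max(abs(rad - R)), 1e-9)
})

test_that("checkerboard probe layout yields the canonical optode split", {
  big <- phantom_spec(target_edge_length = 8)   # coarse but full extent
  mesh <- build_phantom(big)
  layout <- build_probe_layout(mesh, c(6L, 6L), extent = c(100, 70))
  expect_equal(sum(layout$optodes$role == "source"), 18L)
  expect_equal(sum(layout$optodes$role == "detector"), 18L)
  all_pairs <- select_channels(layout, dmin = 1e-9, dmax = Inf)
  expect_equal(nrow(all_pairs), 324L)
  # every optode lies on the (curved) surface: point-to-triangle oracle
  ds <- vapply(sample(nrow(layout$optodes), 8), function(i)
    point_surface_distance(mesh, as.numeric(layout$optodes[i, c("x", "y", "z")])),
    numeric(1))
  expect_lt(max(ds), 0.5)

  small <- build_probe_layout(mesh, c(2L, 2L), extent = c(30, 30))
  expect_equal(sum(small$optodes$role == "source"), 2L)
  expect_equal(nrow(select_channels(small, 1e-9, Inf)), 4L)
  expect_error(build_probe_layout(mesh, c(6L, 6L), extent = c(1000, 70)),
               "exceeds")
})

test_that("channel selection matches a brute-force distance filter", {
  mesh <- tiny_phantom()
  layout <- build_probe_layout(mesh, c(4L, 4L), extent = c(60, 42))
  sel <- select_channels(layout, dmin = 20, dmax = 45)
  # oracle: enumerate every source-detector pair directly
  opt <- layout$optodes
  src <- opt[opt$role == "source", ]; det <- opt[opt$role == "detector", ]
  cnt <- 0L
  for (i in seq_len(nrow(src))) for (j in seq_len(nrow(det))) {
    d <- sqrt(sum((as.numeric(src[i, c("x", "y", "z")]) -
                     as.numeric(det[j, c("x", "y", "z")]))^2))
    if (d >= 20 && d <= 45) cnt <- cnt + 1L
  }
  expect_equal(nrow(sel), cnt)
  expect_true(all(sel$distance >= 20 & sel$distance <= 45))
  expect_error(select_channels(layout, dmin = 50, dmax = 50), "smaller")
})

test_that("distance grouping partitions channels with half-open bins", {
  ch <- data.frame(channel = 1:5, source_id = 1:5, detector_id = 1:5,
                   distance = c(20, 40, 59.9, 120, 100))
  g <- group_channels(ch, edges = seq(20, 120, by = 20))
  expect_equal(g$group, c("20-40", "40-60", "40-60", "100-120", "100-120"))
  gr <- attr(g, "groups")
  expect_equal(sum(gr$NM), nrow(ch))
  expect_error(group_channels(data.frame(channel = 1, source_id = 1,
                                         detector_id = 1, distance = 10),
                              edges = seq(20, 120, 20)), "outside")
  # partition property on a real channel set
  s <- tiny_setup()
  gr2 <- attr(s$channels, "groups")
  expect_equal(sum(gr2$NM), nrow(s$channels))
  expect_false(any(duplicated(s$channels$channel)))
})
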