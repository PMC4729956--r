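test_that("the default honeycomb has the published unit cell and chirality", {
  net <- hc33_net()
  uc <- estimate_unit_cell(tibble::tibble(x = net$faces$cx, y = net$faces$cy))
  expect_equal(uc$a, 5.5, tolerance = 1e-6)
  expect_equal(uc$b, 5.5, tolerance = 1e-6)
  expect_equal(uc$gamma, 120, tolerance = 1e-6)
  expect_equal(chirality_angle(net), 6, tolerance = 1e-6)
})

test_that("every interior vertex joins three walls, 120 degrees apart", {
  net <- hc33_net()
  deg <- table(c(net$edges$v1, net$edges$v2))
  interior <- as.integer(names(deg)[deg == 3L])
  expect_gt(length(interior), 0L)
  for (v in interior[1:min(5, length(interior))]) {
    inc <- net$edges[net$edges$v1 == v | net$edges$v2 == v, ]
    other <- ifelse(inc$v1 == v, inc$v2, inc$v1)
    ang <- sort(atan2(net$vertices$y[other] - net$vertices$y[v],
                      net$vertices$x[other] - net$vertices$x[v]) * 180 / pi)
    expect_equal(diff(ang), c(120, 120), tolerance = 1e-6)
  }
})

test_that("the vertex graph satisfies the Euler formula", {
  net <- hc33_net()
  n_faces <- sum(ring_statistics(as_pore_graph(net)))
  V <- nrow(net$vertices); E <- nrow(net$edges)
  expect_equal(V - E + (n_faces + 1L), 2L)  # +1 for the outer face
})

test_that("hexagon pore area follows the across-flats closed form", {
  expect_equal(pore_area_hexagon(2.3), sqrt(3) / 2 * 2.3^2)
  expect_equal(pore_area_hexagon(2.0), 3.46, tolerance = 1e-2)
  expect_equal(pore_area_hexagon(0), 0)
  expect_error(pore_area_hexagon(-1), ">= 0")
})

test_that("chirality flips sign under reflection and vanishes for achiral builds", {
  net <- hc33_net()
  expect_equal(chirality_angle(mirror_network(net)), -6, tolerance = 1e-6)
  net0 <- build_honeycomb(cells = c(3, 3), chirality = 0)
  expect_equal(chirality_angle(net0), 0, tolerance = 1e-9)
  netm <- build_honeycomb(cells = c(3, 3), chirality = -6)
  expect_equal(chirality_angle(netm),
               -chirality_angle(net), tolerance = 1e-9)
})

test_that("builder preconditions are enforced", {
  expect_error(build_honeycomb(cells = c(2, 2), a = 2), "too small")
  expect_error(build_honeycomb(cells = c(2, 2), chirality = 31), "below 30")
})

test_that("a distance defect makes the two wall peptides individually resolvable", {
  net <- insert_defect(hc33_net(), "distance", widen = 0.5)
  e <- net$defects$where[1]
  b <- net$beads[net$beads$edge == e, ]
  ba <- b[b$peptide == "a", c("x", "y")]
  bb <- b[b$peptide == "b", c("x", "y")]
  ref <- hc33_net()$beads
  ra <- ref[ref$edge == e & ref$peptide == "a", c("x", "y")]
  rb <- ref[ref$edge == e & ref$peptide == "b", c("x", "y")]
  gap_now <- min(sqrt(outer(ba$x, bb$x, "-")^2 + outer(ba$y, bb$y, "-")^2))
  gap_ref <- min(sqrt(outer(ra$x, rb$x, "-")^2 + outer(ra$y, rb$y, "-")^2))
  expect_equal(gap_now - gap_ref, 0.5, tolerance = 1e-6)
  expect_error(insert_defect(hc33_net(), "distance", where = 999L),
               "not in network")
})

test_that("a vertex rotation twists the three incident walls", {
  net0 <- hc33_net()
  net <- insert_defect(net0, "vertex_rotation", twist = 12)
  v <- net$defects$where[1]
  inc <- net$edges$edge[net$edges$v1 == v | net$edges$v2 == v]
  expect_length(inc, 3L)
  expect_equal(net$edges$angle[net$edges$edge %in% inc],
               net0$edges$angle[net0$edges$edge %in% inc] + 12)
  expect_error(insert_defect(net0, "vertex_rotation", where = -1L), "interior")
})
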