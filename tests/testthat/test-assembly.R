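test_that("the octapeptide dimer realises exactly the three polar contacts", {
  d <- at2_dimer()
  motifs <- sort(paste(d$motifs$a, d$motifs$b, sep = "-"))
  expect_equal(motifs, sort(c("Arg2-His6'", "Tyr4-Tyr4'", "His6-Arg2'")))
  expect_equal(d$gap, d$gap_requested)  # linear dimer needs no widening
})

test_that("dimers are C2 symmetric about their centre", {
  for (d in list(at2_dimer(), at1_dimer())) {
    b <- assembly_beads(d)
    rx <- 2 * d$center[1] - b$x
    ry <- 2 * d$center[2] - b$y
    # the 180-degree rotation maps the bead set onto itself
    dmat <- sqrt(outer(b$x, rx, "-")^2 + outer(b$y, ry, "-")^2)
    expect_lt(max(apply(dmat, 1, min)), 1e-9)
  }
})

test_that("the L-shape denies the inner polar contacts of the decapeptide dimer", {
  d <- at1_dimer()
  expect_gt(d$gap, d$gap_requested)  # clash resolution widened the gap
  pairs <- paste(d$motifs$a, d$motifs$b)
  expect_false(any(grepl("Tyr4.*Tyr4|Tyr4.*His6|His6.*Tyr4", pairs)))
  # the dimer's only surviving end motif: C terminal against Arg2
  expect_true(any(grepl("C-term", pairs) & grepl("Arg2", pairs)))
})

test_that("dimer construction rejects impossible gaps", {
  p <- build_backbone(angiotensin_II(), "linear")
  expect_error(build_dimer(p, gap = 0.3), "steric")
})

test_that("the decapeptide dimer footprint is about 2.7 x 2.3 nm", {
  fp <- dimer_footprint(at1_dimer())
  expect_equal(unname(fp["length"]), 2.7, tolerance = 0.4 / 2.7)
  expect_equal(unname(fp["width"]), 2.3, tolerance = 0.4 / 2.3)
})

test_that("chains of staggered dimers keep their annotations and identity case", {
  d <- at1_dimer()
  c1 <- build_chain_A(d, 1)
  expect_equal(nrow(c1$beads), 2 * nrow(d$peptide_a$beads))
  expect_equal(bead_dists(c1$beads), bead_dists(assembly_beads(d)),
               tolerance = 1e-9)
  c3 <- build_chain_A(d, 3)
  expect_equal(length(c3$dimers), 3L)
  expect_true(any(grepl("His9-His9", c3$annotations)))
  c0 <- build_chain_A(d, 2, stagger = 0)
  expect_true(any(grepl("ladder", c0$annotations)))
})

test_that("stacked rows alternate N-N and C-C interfaces", {
  p <- build_backbone(angiotensin_I(), "L")
  r4 <- build_rows_B(p, n_rows = 4, per_row = 3)
  expect_equal(row_interfaces(r4), c("N-N", "C-C", "N-N"))
  r1 <- build_rows_B(p, n_rows = 1, per_row = 3)
  expect_equal(row_interfaces(r1), character())
  r2 <- build_rows_B(p, n_rows = 2, per_row = 3)
  expect_equal(r2$unit_cell$a, c(3, 0))
})

test_that("the substrate is a triangular lattice at the bulk-derived spacing", {
  s <- make_substrate(2)
  expect_equal(nrow(s$points), 4L)
  expect_equal(s$spacing, 0.2884)
  d <- as.matrix(dist(s$points[, c("x", "y")]))
  expect_equal(min(d[d > 0]), 0.2884, tolerance = 1e-9)
  s2 <- make_substrate(c(3, 2), spacing = 0.3)
  d2 <- as.matrix(dist(s2$points[, c("x", "y")]))
  expect_equal(min(d2[d2 > 0]), 0.3, tolerance = 1e-9)
})
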