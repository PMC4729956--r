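test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(5)
  pts <- cbind(runif(12), runif(12))
  tris <- delaunay(pts)
  # brute-force oracle: no point strictly inside any circumcircle
  cc <- pepnet:::circumcenters(pts, tris)
  for (t in seq_len(nrow(tris))) {
    r <- sqrt(sum((pts[tris[t, 1], ] - cc[t, ])^2))
    d <- sqrt((pts[, 1] - cc[t, 1])^2 + (pts[, 2] - cc[t, 2])^2)
    inside <- which(d < r - 1e-9)
    expect_true(all(inside %in% tris[t, ]))
  }
})

test_that("interior points of a triangular lattice are six-coordinated", {
  g <- expand.grid(i = 0:6, j = 0:6)
  pts <- cbind(g$i + g$j / 2, g$j * sqrt(3) / 2)
  tris <- delaunay(pts)
  cnt <- tabulate(as.vector(tris), nbins = nrow(pts))
  interior <- g$i >= 1 & g$i <= 5 & g$j >= 1 & g$j <= 5
  expect_true(all(cnt[interior] == 6L))
})

test_that("pristine honeycomb graphs are all six-membered rings", {
  rs <- ring_statistics(as_pore_graph(hc33_net()))
  expect_equal(names(rs), "6")
  expect_equal(unname(rs), 9L)
})

test_that("a single hexagon traverses as one six-ring", {
  v <- tibble::tibble(x = cos(seq(0, 300, 60) * pi / 180),
                      y = sin(seq(0, 300, 60) * pi / 180))
  g <- pore_graph(v, tibble::tibble(v1 = 1:6, v2 = c(2:6, 1)))
  expect_equal(ring_statistics(g), c("6" = 1L))
})

test_that("inserting one 5-7 pair changes the histogram by exactly {5:+1, 7:+1, 6:-2}", {
  g <- as_pore_graph(build_honeycomb(cells = c(4, 4)))
  before <- ring_statistics(g)
  after <- ring_statistics(insert_ring_pair(g))
  expect_equal(unname(after["5"]), 1L)
  expect_equal(unname(after["7"]), 1L)
  expect_equal(unname(after["6"]), unname(before["6"]) - 2L)
  expect_equal(sum(after), sum(before))
})

test_that("pore graphs reject malformed input", {
  v <- tibble::tibble(x = c(0, 1), y = c(0, 0))
  expect_error(pore_graph(v, tibble::tibble(v1 = 1, v2 = 1)), "self-loops")
  expect_error(pore_graph(v, tibble::tibble(v1 = c(1, 2), v2 = c(2, 1))),
               "duplicate")
})

test_that("a small-angle seam keeps the network all-hexagon", {
  for (th in c(0, 1)) {
    td <- gen_two_domain(th, seed = 1)
    rs <- ring_statistics(td$graph)
    expect_equal(names(rs), "6", info = paste("theta", th))
  }
})

test_that("large-angle boundaries carry equal numbers of 5- and 7-rings", {
  for (th in c(16, 18, 20)) {
    rs <- ring_statistics(gen_two_domain(th, seed = 1)$graph)
    expect_gt(unname(rs["5"]), 0L)
    expect_equal(unname(rs["5"]), unname(rs["7"]), info = paste("theta", th))
  }
})

test_that("two-domain generation is deterministic under a fixed seed", {
  a <- gen_two_domain(20, seed = 3)
  b <- gen_two_domain(20, seed = 3)
  expect_identical(a$centres, b$centres)
  expect_identical(ring_statistics(a$graph), ring_statistics(b$graph))
  expect_error(gen_two_domain(30), "0, 30")
})
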