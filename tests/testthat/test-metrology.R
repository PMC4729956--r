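test_that("pore centres are recovered to sub-pixel accuracy", {
  img <- hc33_image()
  net <- hc33_net()
  ctr <- detect_pores(img)
  expect_equal(nrow(ctr), 9L)
  err <- vapply(seq_len(nrow(ctr)), function(i)
    min(sqrt((net$faces$cx - ctr$x[i])^2 + (net$faces$cy - ctr$y[i])^2)),
    numeric(1))
  expect_lt(max(err), img$pixel_size)
  expect_error(detect_pores(new_img <- structure(
    list(pixels = matrix(0, 50, 50), pixel_size = 0.05, origin = c(0, 0),
         mode = "constant_density_topograph", isovalue = NA, substrate_z = 0),
    class = "stm_image")), "blank image")
})

test_that("pore detection survives 10% Gaussian noise", {
  img <- add_scan_noise(hc33_image(), sigma = 0.1, seed = 4)
  net <- hc33_net()
  ctr <- detect_pores(img)
  expect_equal(nrow(ctr), 9L)
  err <- vapply(seq_len(nrow(ctr)), function(i)
    min(sqrt((net$faces$cx - ctr$x[i])^2 + (net$faces$cy - ctr$y[i])^2)),
    numeric(1))
  expect_lt(max(err), 2 * img$pixel_size)
})

test_that("lattice fitting handles hexagonal, square and scaled inputs", {
  g <- expand.grid(i = 0:3, j = 0:3)
  sq <- tibble::tibble(x = 4 * g$i, y = 4 * g$j)
  uc <- estimate_unit_cell(sq)
  expect_equal(uc$a, 4, tolerance = 1e-9)
  expect_equal(uc$b, 4, tolerance = 1e-9)
  expect_equal(uc$gamma, 90, tolerance = 1e-9)
  net <- hc33_net()
  hexc <- tibble::tibble(x = net$faces$cx, y = net$faces$cy)
  uc2 <- estimate_unit_cell(hexc)
  uc3 <- estimate_unit_cell(dplyr::mutate(hexc, x = 2 * x, y = 2 * y))
  expect_equal(uc3$a, 2 * uc2$a, tolerance = 1e-9)
  expect_equal(uc3$gamma, uc2$gamma, tolerance = 1e-9)
  expect_error(estimate_unit_cell(tibble::tibble(x = 1:8, y = 0)), "degenerate")
  expect_error(estimate_unit_cell(sq[1:4, ]), "at least 7")
})

test_that("measured angles rotate with the sample and lengths do not", {
  net <- hc33_net()
  hexc <- tibble::tibble(x = net$faces$cx, y = net$faces$cy)
  rot <- function(df, th) {
    t <- th * pi / 180
    tibble::tibble(x = cos(t) * df$x - sin(t) * df$y,
                   y = sin(t) * df$x + cos(t) * df$y)
  }
  uc0 <- estimate_unit_cell(hexc)
  uc7 <- estimate_unit_cell(rot(hexc, 7))
  expect_equal(uc7$a, uc0$a, tolerance = 1e-9)
  expect_equal(uc7$gamma, uc0$gamma, tolerance = 1e-9)
  d0 <- pepnet:::principal_direction(uc0)
  d7 <- pepnet:::principal_direction(uc7)
  expect_equal((d7 - d0) %% 60, 7, tolerance = 1e-6)
})

test_that("build parameters are recovered across the (a, chirality) plane", {
  for (a in c(4, 6, 8)) for (chi in c(-10, 0, 10)) {
    net <- build_honeycomb(cells = c(3, 3), a = a, chirality = chi)
    uc <- estimate_unit_cell(tibble::tibble(x = net$faces$cx, y = net$faces$cy))
    expect_equal(uc$a, a, tolerance = 0.02)
    expect_equal(chirality_angle(net), chi, tolerance = 0.5)
  }
})

test_that("image-based chirality agrees with the build value", {
  expect_equal(chirality_angle(hc33_image()), 6, tolerance = 0.5)
})

test_that("pore geometry reports the published inner diameter and area", {
  pg <- pore_geometry(hc33_net())
  expect_equal(attr(pg, "d_mean"), 2.3, tolerance = 0.1 / 2.3)
  expect_equal(attr(pg, "area_mean"), pore_area_hexagon(attr(pg, "d_mean")),
               tolerance = 0.01)
  broken <- hc33_net()
  broken$faces$edges[[1]] <- broken$faces$edges[[1]][1:3]
  expect_error(pore_geometry(broken), "open pore")
})

test_that("domain misorientation is recovered and single domains stay single", {
  r1 <- domain_misorientation(gen_two_domain(1, seed = 2))
  expect_equal(r1$misorientation$theta, 1, tolerance = 0.2)
  r20 <- domain_misorientation(gen_two_domain(20, seed = 1))
  expect_gte(r20$misorientation$theta, 16)
  expect_lte(r20$misorientation$theta, 25)
  r0 <- domain_misorientation(gen_two_domain(0, seed = 1))
  expect_equal(nrow(r0$misorientation), 0L)
  expect_equal(nrow(r0$domains), 1L)
})

test_that("row spacing recovers the build value and scales with the image", {
  img <- rows_image()
  expect_equal(row_spacing(img), 3.0, tolerance = 0.05)
  expect_equal(row_spacing(scale_image(img, 2)), 6.0, tolerance = 0.05)
  set.seed(3)
  wn <- structure(list(pixels = matrix(rnorm(10000), 100, 100),
                       pixel_size = 0.05, origin = c(0, 0),
                       mode = "constant_density_topograph",
                       isovalue = NA, substrate_z = 0), class = "stm_image")
  expect_error(row_spacing(wn), "no significant periodicity")
})

test_that("the metrology umbrella produces tidy and glance summaries", {
  m <- measure_honeycomb(hc33_net(), img = hc33_image())
  g <- generics::glance(m)
  expect_equal(g$a, 5.5, tolerance = 0.02)
  expect_equal(g$gamma, 120, tolerance = 1)
  expect_equal(g$chirality, 6, tolerance = 0.5)
  expect_equal(g$pore_d, 2.3, tolerance = 0.1)
  t <- generics::tidy(m)
  expect_equal(nrow(t), 9L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_metrology(m, f)
  expect_true(file.exists(f))
  rec <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(rec$pore_d, g$pore_d, tolerance = 1e-9)
})

test_that("autoplot methods return ggplot objects", {
  expect_s3_class(ggplot2::autoplot(hc33_image()), "ggplot")
  expect_s3_class(ggplot2::autoplot(hc33_net()), "ggplot")
  expect_s3_class(ggplot2::autoplot(at2_dimer()), "ggplot")
  expect_s3_class(ggplot2::autoplot(gen_two_domain(20, seed = 1)$graph),
                  "ggplot")
})
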