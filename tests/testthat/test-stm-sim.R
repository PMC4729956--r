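test_that("cube files round-trip losslessly in both unit dialects", {
  g <- make_grid(c(0.1, 0.2, 0), c(0.08, 0.09, 0.1), c(4, 3, 2))
  arr <- array(c(1.1, -0.25, pi, exp(1), 0.5, 2^-20, 1e3, 7,
                 rnorm(16)), c(4, 3, 2))
  fb <- withr::local_tempfile(fileext = ".cube")
  fa <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, arr, fb, units = "bohr")
  write_cube(g, arr, fa, units = "angstrom")
  rb <- read_cube(fb); ra <- read_cube(fa)
  expect_identical(rb$values, arr)
  expect_identical(ra$values, arr)
  expect_equal(rb$units, "bohr")
  expect_equal(ra$units, "angstrom")
  expect_equal(rb$grid$spacing, ra$grid$spacing, tolerance = 1e-7)
  expect_equal(rb$grid$origin, ra$grid$origin, tolerance = 1e-7)
})

test_that("truncated cube data is reported with expected vs found counts", {
  g <- make_grid(c(0, 0, 0), 0.08, c(3, 3, 3))
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, array(1, c(3, 3, 3)), f)
  ln <- readLines(f)
  writeLines(ln[-length(ln)], f)
  expect_error(read_cube(f), "expected 27")
})

test_that("the energy window keeps occupied orbitals within 2 eV of the HOMO", {
  g <- make_grid(c(0, 0, 0), 0.1, c(4, 4, 4))
  mk <- function(v) array(v, c(4, 4, 4))
  orbs <- orbital_set(g, c(-5, -6.5, -7.5), list(mk(1), mk(2), mk(3)))
  expect_equal(select_window(orbs, 2)$energies, c(-5, -6.5))
  expect_equal(select_window(orbs, 0)$energies, -5)        # HOMO only
  orbs_b <- orbital_set(g, c(-5, -7), list(mk(1), mk(2)))
  expect_equal(select_window(orbs_b, 2)$energies, c(-5, -7))  # boundary inclusive
  expect_error(orbital_set(g, -5, list(mk(1)), occupied = FALSE), "occupied")
})

test_that("window selection grows monotonically with the window", {
  g <- make_grid(c(0, 0, 0), 0.1, c(2, 2, 2))
  set.seed(21)
  en <- sort(runif(12, -9, -4), decreasing = TRUE)
  orbs <- orbital_set(g, en, lapply(en, function(e) array(e, c(2, 2, 2))))
  prev <- -1L
  for (w in c(0, 0.5, 1, 2, 4, 10)) {
    n <- length(select_window(orbs, w)$energies)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("summed squares behave like a density", {
  g <- make_grid(c(0, 0, 0), 0.05, c(30, 30, 30))
  lob <- tibble::tibble(x = 0.4, y = 0.4, z = 0.7, amplitude = 1, sigma = 0.1)
  psi <- gaussian_orbital(g, lob)
  rho1 <- sum_squares(orbital_set(g, -5, list(psi)))
  rho2 <- sum_squares(orbital_set(g, c(-5, -5.5), list(psi, psi)))
  expect_equal(rho2$values, 2 * rho1$values)
  expect_true(all(rho1$values >= 0))
  # disjoint lobes add with disjoint supports
  lob2 <- tibble::tibble(x = 1.1, y = 1.1, z = 0.7, amplitude = 1, sigma = 0.1)
  psi2 <- gaussian_orbital(g, lob2)
  expect_equal(sum(psi * psi2), 0)
  # grid mismatch is refused
  g2 <- make_grid(c(0, 0, 0), 0.05, c(10, 10, 10))
  expect_error(orbital_set(g2, -5, list(psi)), "does not match")
})

test_that("the topograph matches the closed-form Gaussian isosurface height", {
  g <- make_grid(c(0, 0, 0), 0.02, c(60, 60, 60))
  s <- 0.12
  lob <- tibble::tibble(x = 0.6, y = 0.6, z = 0.5, amplitude = 1, sigma = s)
  rho <- sum_squares(orbital_set(g, -5, list(gaussian_orbital(g, lob))))
  iso <- 0.01 * max(rho$values)
  img <- topograph(rho, iso)
  ax <- grid_axes(g)
  for (ix in seq(10, 50, 8)) for (iy in seq(10, 50, 8)) {
    r2 <- (ax$x[ix] - 0.6)^2 + (ax$y[iy] - 0.6)^2
    # rho = exp(-r^2 / s^2) (squared orbital); solve rho(z) = iso for z
    arg <- -log(iso / max(rho$values)) * s^2 - r2
    z_true <- if (arg > 0) 0.5 + sqrt(arg) else 0
    expect_lt(abs(img$pixels[ix, iy] - z_true), g$spacing[3])
  }
})

test_that("higher lobes are brighter and isovalue behaves monotonically", {
  g <- make_grid(c(0, 0, 0), 0.04, c(50, 50, 40))
  two <- function(h2) tibble::tibble(x = c(0.5, 1.5), y = 1, z = c(0.5, h2),
                                     amplitude = 1, sigma = 0.12)
  rho <- sum_squares(orbital_set(g, -5, list(gaussian_orbital(g, two(0.9)))))
  img <- topograph(rho, 0.01 * max(rho$values))
  peak_lo <- max(img$pixels[1:25, ])
  peak_hi <- max(img$pixels[26:50, ])
  expect_gt(peak_hi, peak_lo)
  # raising the lobe raises its pixels, never lowers them
  rho2 <- sum_squares(orbital_set(g, -5, list(gaussian_orbital(g, two(1.1)))))
  img2 <- topograph(rho2, img$isovalue)
  expect_true(all(img2$pixels[26:50, ] - img$pixels[26:50, ] > -1e-9))
  # lowering the isovalue never shrinks the bright region
  img3 <- topograph(rho, 0.001 * max(rho$values))
  expect_true(all((img$pixels > 0) <= (img3$pixels > 0)))
  expect_warning(big <- topograph(rho, 2 * max(rho$values)), "empty")
  expect_true(all(big$pixels == 0))
})

test_that("constant-height maps slice the density linearly", {
  g <- make_grid(c(0, 0, 0), 0.04, c(40, 40, 40))
  lob <- tibble::tibble(x = 0.8, y = 0.8, z = 0.6, amplitude = 1, sigma = 0.12)
  rho <- sum_squares(orbital_set(g, -5, list(gaussian_orbital(g, lob))))
  img <- constant_height_map(rho, 0.6)
  pk <- which(img$pixels == max(img$pixels), arr.ind = TRUE)[1, ]
  ax <- grid_axes(g)
  expect_equal(ax$x[pk[1]], 0.8, tolerance = 0.05)
  expect_equal(ax$y[pk[2]], 0.8, tolerance = 0.05)
  rho2 <- rho; rho2$values <- 2 * rho2$values
  expect_equal(constant_height_map(rho2, 0.6)$pixels, 2 * img$pixels)
  hi <- constant_height_map(rho, 0.04 * 39)
  expect_lt(max(hi$pixels), 1e-6)
  expect_error(constant_height_map(rho, 5), "outside")
})

test_that("assembly images reproduce the published contrast ordering", {
  img <- hc33_image()
  net <- hc33_net()
  px_at <- function(x, y) {
    ix <- round((x - img$origin[1]) / img$pixel_size) + 1
    iy <- round((y - img$origin[2]) / img$pixel_size) + 1
    img$pixels[ix, iy]
  }
  # backbone ridge bright, pore centre dark
  bb <- dplyr::filter(net$beads, kind == "backbone", code %in% c("Y", "H"))
  ridge <- mean(mapply(px_at, bb$x[1:50], bb$y[1:50]))
  pore <- px_at(net$faces$cx[5], net$faces$cy[5])
  expect_gt(ridge, pore + 0.2)
  # Tyr4 brighter than Asp1 within one peptide
  b1 <- dplyr::filter(net$beads, edge == 1, peptide == "a", kind == "side")
  expect_gt(px_at(b1$x[b1$code == "Y"], b1$y[b1$code == "Y"]),
            px_at(b1$x[b1$code == "D"], b1$y[b1$code == "D"]))
})

test_that("zero-amplitude assemblies image as empty", {
  p <- build_backbone("G", "linear")
  stm <- stm_params(amplitudes = list(backbone = 0, nterm = 0, cterm = 0,
                                      backbone_scale = numeric(),
                                      side = numeric(), side_default = 0))
  img <- simulate_assembly_image(build_dimer(p, gap = 0.9), stm)
  expect_true(all(img$pixels == 0))
})

test_that("images round-trip through PGM and TSV with their sidecars", {
  img <- hc33_image()
  fp <- withr::local_tempfile(fileext = ".pgm")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_stm_pgm(img, fp)
  write_stm_tsv(img, ft)
  rp <- read_stm_image(fp)
  rt <- read_stm_image(ft)
  expect_equal(rp$pixel_size, img$pixel_size)
  expect_equal(rt$pixels, img$pixels, tolerance = 1e-9)
  expect_equal(rp$pixels, img$pixels, tolerance = diff(range(img$pixels)) / 65535 * 2)
})

test_that("scan noise is reproducible and seed-sensitive", {
  img <- hc33_image()
  n1 <- add_scan_noise(img, sigma = 0.1, scanline = 0.02, seed = 9)
  n2 <- add_scan_noise(img, sigma = 0.1, scanline = 0.02, seed = 9)
  n3 <- add_scan_noise(img, sigma = 0.1, scanline = 0.02, seed = 10)
  expect_identical(n1$pixels, n2$pixels)
  expect_false(identical(n1$pixels, n3$pixels))
})
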