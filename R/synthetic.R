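#' Generate a toy molecular-orbital fixture
#'
#' Writes Gaussian-lobe orbital volumes as cube files on one common grid,
#' together with a JSON manifest of energies, occupation flags and the
#' subset an energy-window selection must return -- everything needed to
#' exercise the orbital pipeline with known ground truth.
#'
#' @param energies Orbital energies, eV (>= 1 value).
#' @param dir Output directory (created if missing).
#' @param occupied Logical occupation flags; default all `TRUE`.
#' @param ids Orbital identifiers; must be unique.
#' @param window_eV Window recorded in the manifest for the expected
#'   selection.
#' @param seed Integer seed controlling the random lobe geometry.
#' @return The manifest list, invisibly; files `*.cube` and
#'   `manifest.json` appear in `dir`.
#' @export
gen_orbital_fixture <- function(energies, dir, occupied = NULL, ids = NULL,
                                window_eV = 2.0, seed = 1L) {
  stopifnot(length(energies) >= 1L)
  occupied <- occupied %||% rep(TRUE, length(energies))
  ids <- ids %||% sprintf("orb%02d", seq_along(energies))
  if (anyDuplicated(ids))
    stop("orbital ids must be unique", call. = FALSE)
  if (!any(occupied)) stop("at least one orbital must be occupied", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- make_grid(c(0, 0, 0), 0.08, c(12, 12, 12))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  files <- character(length(energies))
  for (k in seq_along(energies)) {
    nl <- sample(1:3, 1)
    lobes <- tibble::tibble(x = stats::runif(nl, 0.2, 0.7),
                            y = stats::runif(nl, 0.2, 0.7),
                            z = stats::runif(nl, 0.2, 0.7),
                            amplitude = stats::runif(nl, 0.5, 1),
                            sigma = 0.15)
    files[k] <- file.path(dir, paste0(ids[k], ".cube"))
    write_cube(grid, gaussian_orbital(grid, lobes), files[k],
               comments = c(sprintf("orbital %s", ids[k]),
                            sprintf("energy %.4f eV occupied %d",
                                    energies[k], as.integer(occupied[k]))))
  }
  homo <- max(energies[occupied])
  manifest <- list(ids = ids, files = basename(files), energies = energies,
                   occupied = occupied, homo_energy = homo,
                   window_eV = window_eV,
                   expected_selection = ids[occupied & energies >= homo - window_eV],
                   seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname gen_orbital_fixture
#' @export
read_orbital_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cubes <- lapply(file.path(dir, manifest$files), read_cube)
  orbital_set(cubes[[1]]$grid, manifest$energies,
              lapply(cubes, `[[`, "values"), occupied = manifest$occupied)
}

#' Generate a synthetic STM image of an assembly with ground truth
#'
#' Builds one of the three observed assemblies with the published-geometry
#' defaults, runs the Gaussian-lobe orbital model and the topograph
#' renderer, optionally adds STM-style noise, and records every build
#' parameter in a ground-truth record from which the artifact can be
#' regenerated bit-identically.
#'
#' @param kind `"honeycomb"`, `"rows_B"` or `"chain_A"`.
#' @param params Named builder overrides (`cells`, `a`, `chirality` for
#'   the honeycomb; `n_rows`, `per_row`, `row_spacing` for rows;
#'   `n`, `stagger` for chains).
#' @param noise List with `sigma` and `scanline` fractions (see
#'   [add_scan_noise()]); zero means noise-free.
#' @param seed Integer seed for the noise.
#' @param stm [stm_params()].
#' @return A `synth_image`: `image` (`stm_image`), the built `model`, and
#'   the `truth` record.
#' @export
gen_assembly_image <- function(kind = c("honeycomb", "rows_B", "chain_A"),
                               params = list(),
                               noise = list(sigma = 0, scanline = 0),
                               seed = 1L, stm = stm_params()) {
  kind <- match.arg(kind)
  noise <- utils::modifyList(list(sigma = 0, scanline = 0), noise)
  model <- switch(kind,
    honeycomb = do.call(build_honeycomb, params),
    rows_B = {
      p <- utils::modifyList(list(n_rows = 6L, per_row = 8L, row_spacing = 3.0),
                             params)
      build_rows_B(build_backbone(angiotensin_I(), "L"),
                   n_rows = p$n_rows, per_row = p$per_row,
                   row_spacing = p$row_spacing)
    },
    chain_A = {
      p <- utils::modifyList(list(n = 4L, stagger = 0.9), params)
      build_chain_A(build_dimer(build_backbone(angiotensin_I(), "L")),
                    n = p$n, stagger = p$stagger)
    })
  img <- simulate_assembly_image(model, stm)
  if (noise$sigma > 0 || noise$scanline > 0)
    img <- add_scan_noise(img, sigma = noise$sigma,
                          scanline = noise$scanline, seed = seed)
  truth <- list(kind = kind, params = params, noise = noise, seed = seed,
                pixel_size = img$pixel_size,
                builder = switch(kind,
                  honeycomb = list(a = model$a, chirality = model$chirality,
                                   cells = model$cells),
                  rows_B = list(row_spacing = utils::modifyList(
                    list(row_spacing = 3.0), params)$row_spacing),
                  chain_A = list(stagger = utils::modifyList(
                    list(stagger = 0.9), params)$stagger)),
                stm = stm[c("spacing", "z_spacing", "zmax", "sigma", "iso_frac")])
  structure(list(image = img, model = model, truth = truth),
            class = "synth_image")
}

#' @export
print.synth_image <- function(x, ...) {
  cat(sprintf("<synth_image> %s, %s noise\n", x$truth$kind,
              if (x$truth$noise$sigma > 0 || x$truth$noise$scanline > 0)
                sprintf("sigma %.2g / scanline %.2g (seed %d)",
                        x$truth$noise$sigma, x$truth$noise$scanline,
                        x$truth$seed) else "no"))
  print(x$image)
  invisible(x)
}

#' @rdname gen_assembly_image
#' @param truth A ground-truth record (or path to one written by
#'   [write_ground_truth()]).
#' @export
regenerate <- function(truth) {
  if (is.character(truth)) truth <- read_ground_truth(truth)
  gen_assembly_image(truth$kind, params = truth$params, noise = truth$noise,
                     seed = truth$seed)
}

#' @rdname gen_assembly_image
#' @param path JSON path for the ground-truth sidecar.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gen_assembly_image
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(tr$params) && !length(tr$params)) tr$params <- list()
  if (!is.null(tr$params$cells)) tr$params$cells <- as.integer(tr$params$cells)
  tr
}

#' Two misoriented honeycomb domains merged along a seam
#'
#' Generates pore-centre lattices of two domains rotated by -theta/2 and
#' +theta/2, merges them along a straight vertical seam (duplicate seam
#' points removed), and re-triangulates the merged set so ring statistics
#' can be computed on the dual network: the interior faces of the dual
#' are the pores, and their sizes are the ring sizes.  Around 1 degree
#' the boundary stays all-hexagon over fields of this size; in the 16-25
#' degree range the seam is accommodated by paired five- and
#' seven-membered rings (dislocations).
#'
#' @param theta Domain misorientation, degrees, 0 <= theta < 30; 0 gives a
#'   single pristine domain.
#' @param a Superlattice constant, nm.
#' @param extent `c(width, height)` of the analysis window, nm.
#' @param margin Band excluded at the window boundary before building the
#'   dual graph (boundary-truncated cells otherwise contaminate the ring
#'   histogram), nm.
#' @param seed Integer seed for the symmetry-breaking jitter.
#' @return A `two_domain_network`: `centres` (tibble `x`, `y`, `domain`),
#'   the dual `graph` ([pore_graph()]), and the `truth` record.
#' @export
gen_two_domain <- function(theta, a = 5.5, extent = c(60, 52), margin = NULL,
                           seed = 1L) {
  if (theta < 0 || theta >= 30)
    stop("theta must lie in [0, 30) degrees", call. = FALSE)
  margin <- margin %||% (1.2 * a)
  half <- extent / 2
  rad <- sqrt(sum(half^2)) + 2 * a
  nmax <- ceiling(rad / a) + 2L
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  base <- cbind(ij$i * a + ij$j * a / 2, ij$j * a * sqrt(3) / 2)
  base <- base[sqrt(rowSums(base^2)) <= rad, , drop = FALSE]
  rot <- function(p, ang) {
    R <- rot2(ang)
    t(R %*% t(p))
  }
  if (theta == 0) {
    pts <- base
    dom <- rep(1L, nrow(pts))
  } else {
    # bicrystal construction: the two rotated lattices overlap in a band
    # around the seam; greedy hard-core thinning of the doubled band keeps
    # the density right, and the residual misfit carries the dislocations
    q1 <- rot(base, -theta / 2)
    q2 <- rot(base, +theta / 2)
    w <- a
    p1 <- q1[q1[, 1] <= w, , drop = FALSE]
    p2 <- q2[q2[, 1] >= -w, , drop = FALSE]
    cand <- rbind(p1, p2)
    cdom <- c(rep(1L, nrow(p1)), rep(2L, nrow(p2)))
    inband <- abs(cand[, 1]) <= w
    ord <- which(inband)[order(-abs(cand[inband, 1]), cand[inband, 2])]
    keep <- !inband
    # outside-band points are fixed; band points must clear them too
    acc <- cand[!inband & abs(cand[, 1]) <= w + 1.5 * a, , drop = FALSE]
    for (k in ord) {
      near <- abs(acc[, 1] - cand[k, 1]) < a & abs(acc[, 2] - cand[k, 2]) < a
      if (!nrow(acc) ||
          !any((acc[near, 1] - cand[k, 1])^2 +
                 (acc[near, 2] - cand[k, 2])^2 < (0.65 * a)^2)) {
        keep[k] <- TRUE
        acc <- rbind(acc, cand[k, ])
      }
    }
    pts <- cand[keep, , drop = FALSE]
    dom <- cdom[keep]
  }
  inwin <- abs(pts[, 1]) <= half[1] & abs(pts[, 2]) <= half[2]
  pts <- pts[inwin, , drop = FALSE]; dom <- dom[inwin]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pts <- pts + matrix(stats::rnorm(length(pts), 0, 1e-4 * a), nrow(pts), 2)
  if (theta > 0) pts <- relax_seam(pts, band = 2.5 * a, half = half)
  tris <- delaunay(pts)
  # place the analysis-window cuts so they do not slice through a
  # dislocation core: a cut through a core would clip one ring of a 5-7
  # pair and turn a windowing artifact into a fake ring-statistics signal
  cnt <- tabulate(as.vector(tris), nbins = nrow(pts))
  # feature-complete windowing: a misfit dislocation is a 5-ring with an
  # adjacent 7-ring; the analysis graph includes or excludes whole cores,
  # never half of one, the way boundary-touching particles are handled in
  # counting frames.  Coordination defects too close to the point-set
  # boundary are unreliable and excluded together with their partners.
  reliable <- abs(pts[, 1]) <= half[1] - 1.1 * a &
    abs(pts[, 2]) <= half[2] - 1.1 * a
  in_w <- abs(pts[, 1]) <= half[1] - margin & abs(pts[, 2]) <= half[2] - margin
  i5 <- rep(which(cnt < 6L), times = pmax(0L, 6L - cnt[cnt < 6L]))
  i7 <- rep(which(cnt > 6L), times = pmax(0L, cnt[cnt > 6L] - 6L))
  used <- logical(length(i7))
  pair5 <- integer(0); pair7 <- integer(0); lone <- integer(0)
  for (i in i5) {
    free <- which(!used)
    if (!length(free)) { lone <- c(lone, i); next }
    dd <- sqrt((pts[i7[free], 1] - pts[i, 1])^2 +
                 (pts[i7[free], 2] - pts[i, 2])^2)
    j <- free[which.min(dd)]
    if (min(dd) > 2.5 * a) { lone <- c(lone, i); next }
    used[j] <- TRUE
    pair5 <- c(pair5, i); pair7 <- c(pair7, i7[j])
  }
  lone <- unique(c(lone, i7[!used]))
  keep_pair <- rep(TRUE, length(pair5))
  excluded <- lone
  repeat {
    drop_now <- keep_pair &
      (!reliable[pair5] | !reliable[pair7] | !in_w[pair5] | !in_w[pair7])
    if (length(excluded)) {
      near_x <- function(i) any(sqrt((pts[excluded, 1] - pts[i, 1])^2 +
                                       (pts[excluded, 2] - pts[i, 2])^2) <
                                  1.3 * a)
      drop_now <- drop_now | (keep_pair &
        (vapply(pair5, near_x, logical(1)) |
           vapply(pair7, near_x, logical(1))))
    }
    if (!any(drop_now & keep_pair) || !any(keep_pair)) break
    newly <- which(drop_now & keep_pair)
    keep_pair[newly] <- FALSE
    excluded <- unique(c(excluded, pair5[newly], pair7[newly]))
  }
  defect <- cnt != 6L
  sel <- (in_w & !defect) | seq_len(nrow(pts)) %in%
    c(pair5[keep_pair], pair7[keep_pair])
  sel[excluded] <- FALSE
  has_sel <- sel[tris[, 1]] | sel[tris[, 2]] | sel[tris[, 3]]
  has_exc <- tris[, 1] %in% excluded | tris[, 2] %in% excluded |
    tris[, 3] %in% excluded
  graph <- dual_pore_graph(pts, tris, keep = has_sel & !has_exc)
  disl <- tibble::tibble(
    x5 = pts[pair5[keep_pair], 1], y5 = pts[pair5[keep_pair], 2],
    x7 = pts[pair7[keep_pair], 1], y7 = pts[pair7[keep_pair], 2])
  structure(list(theta = theta, a = a,
                 centres = tibble::tibble(x = pts[, 1], y = pts[, 2],
                                          domain = dom),
                 graph = graph, dislocations = disl,
                 n_unpaired = length(lone),
                 truth = list(theta = theta, a = a, extent = extent,
                              margin = margin, seed = seed)),
            class = "two_domain_network")
}

# Local Laplacian relaxation of the seam band: each band point moves half
# way towards the centroid of its Delaunay neighbours.  This heals the
# spurious crowding/holes of cutting two half-lattices mid-cell while the
# topologically protected dislocations of a misoriented seam survive.
relax_seam <- function(pts, band, half, iters = 12L) {
  for (it in seq_len(iters)) {
    tris <- delaunay(pts)
    nb <- vector("list", nrow(pts))
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tris[, pr[1]]; j <- tris[, pr[2]]
      for (k in seq_along(i)) {
        nb[[i[k]]] <- c(nb[[i[k]]], j[k])
        nb[[j[k]]] <- c(nb[[j[k]]], i[k])
      }
    }
    mov <- which(abs(pts[, 1]) <= band &
                   abs(pts[, 1]) <= half[1] - 1 & abs(pts[, 2]) <= half[2] - 1)
    for (i in mov) {
      n_i <- unique(nb[[i]])
      if (length(n_i) < 3L) next
      # weight tapers to zero at the relaxation-zone edge so the zone
      # boundary does not itself shear the lattice
      wgt <- 0.3 * min(1, (band - abs(pts[i, 1])) / (0.4 * band))
      ctr <- colMeans(pts[n_i, , drop = FALSE])
      pts[i, ] <- pts[i, ] + wgt * (ctr - pts[i, ])
    }
  }
  pts
}

#' @export
print.two_domain_network <- function(x, ...) {
  cat(sprintf("<two_domain_network> theta = %.1f deg, %d centres (%d | %d)\n",
              x$theta, nrow(x$centres), sum(x$centres$domain == 1L),
              sum(x$centres$domain == 2L)))
  invisible(x)
}
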