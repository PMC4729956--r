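#' Molecular orbital sets on a common grid
#'
#' Bundles volumetric orbital amplitudes (or densities) with their
#' energies and occupation flags.  The HOMO energy is the maximum energy
#' among occupied orbitals; occupation is metadata, never inferred.
#'
#' @param grid A [make_grid()] grid shared by all orbitals.
#' @param energies Numeric vector, eV.
#' @param values List of arrays matching `grid$shape`.
#' @param occupied Logical vector (default all occupied).
#' @param is_density If `TRUE` the arrays are already |psi|^2 and are
#'   summed without squaring.
#' @return An `orbital_set`.
#' @export
orbital_set <- function(grid, energies, values, occupied = NULL,
                        is_density = FALSE) {
  occupied <- occupied %||% rep(TRUE, length(energies))
  stopifnot(length(energies) == length(values),
            length(occupied) == length(energies))
  for (v in values)
    if (!all(dim(v) == grid$shape))
      stop("orbital volume does not match the grid", call. = FALSE)
  if (!any(occupied)) stop("at least one orbital must be occupied", call. = FALSE)
  structure(list(grid = grid, energies = as.numeric(energies),
                 occupied = occupied, values = values,
                 is_density = is_density,
                 homo_energy = max(energies[occupied])),
            class = "orbital_set")
}

#' @export
print.orbital_set <- function(x, ...) {
  cat(sprintf("<orbital_set> %d orbital(s) on %s grid, HOMO %.2f eV, %d occupied\n",
              length(x$energies), paste(x$grid$shape, collapse = "x"),
              x$homo_energy, sum(x$occupied)))
  invisible(x)
}

#' Select occupied orbitals within an energy window below the HOMO
#'
#' Returns the occupied orbitals with energy >= HOMO - `window_eV`,
#' boundary inclusive.  The 2 eV default is the window used when summing
#' squared occupied orbitals for STM simulation.
#'
#' @param orbs An [orbital_set()].
#' @param window_eV Window depth below the HOMO, eV (>= 0).
#' @return An `orbital_set` containing the selected subset.
#' @export
select_window <- function(orbs, window_eV = 2.0) {
  stopifnot(inherits(orbs, "orbital_set"), window_eV >= 0)
  keep <- orbs$occupied & orbs$energies >= orbs$homo_energy - window_eV
  orbital_set(orbs$grid, orbs$energies[keep], orbs$values[keep],
              occupied = rep(TRUE, sum(keep)), is_density = orbs$is_density)
}

#' Sum of squared orbitals (LDOS proxy)
#'
#' `rho(r) = sum_i |psi_i(r)|^2` over the orbitals of the set; inputs
#' flagged as densities are summed without squaring.
#'
#' @param orbs An [orbital_set()] whose members share one grid.
#' @return An `ldos_grid`: the grid plus the non-negative scalar field.
#' @export
sum_squares <- function(orbs) {
  stopifnot(inherits(orbs, "orbital_set"), length(orbs$values) >= 1L)
  rho <- array(0, dim = orbs$grid$shape)
  for (v in orbs$values) rho <- rho + if (orbs$is_density) v else v^2
  structure(list(grid = orbs$grid, values = rho), class = "ldos_grid")
}

#' @export
print.ldos_grid <- function(x, ...) {
  cat(sprintf("<ldos_grid> %s voxels, max %.3g\n",
              paste(x$grid$shape, collapse = "x"), max(x$values)))
  invisible(x)
}

#' Gaussian-lobe volumetric amplitude
#'
#' Builds one orbital amplitude as a sum of isotropic Gaussian lobes;
#' lobes are truncated at four standard deviations.
#'
#' @param grid A [make_grid()] grid.
#' @param lobes Tibble/data frame with columns `x`, `y`, `z`, `amplitude`,
#'   `sigma` (nm).
#' @return An array of shape `grid$shape`.
#' @export
gaussian_orbital <- function(grid, lobes) {
  ax <- grid_axes(grid)
  psi <- array(0, dim = grid$shape)
  for (k in seq_len(nrow(lobes))) {
    s <- lobes$sigma[k]; a <- lobes$amplitude[k]
    if (a == 0) next
    ix <- which(abs(ax$x - lobes$x[k]) <= 4 * s)
    iy <- which(abs(ax$y - lobes$y[k]) <= 4 * s)
    iz <- which(abs(ax$z - lobes$z[k]) <= 4 * s)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax$x[ix] - lobes$x[k])^2 / (2 * s^2))
    gy <- exp(-(ax$y[iy] - lobes$y[k])^2 / (2 * s^2))
    gz <- exp(-(ax$z[iz] - lobes$z[k])^2 / (2 * s^2))
    psi[ix, iy, iz] <- psi[ix, iy, iz] + a * (gx %o% gy %o% gz)
  }
  psi
}
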