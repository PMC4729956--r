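#' Regular 3D grids
#'
#' Axis-aligned regular volumetric grids in nm; voxel centres sit at
#' `origin + (i - 1) * spacing`.
#'
#' @param origin Length-3 numeric, nm.
#' @param spacing Length-3 (or scalar) voxel step, nm.
#' @param shape Length-3 integer voxel counts.
#' @return A `grid3d` object.
#' @export
make_grid <- function(origin, spacing, shape) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  stopifnot(length(origin) == 3L, length(shape) == 3L, all(spacing > 0),
            all(shape >= 1))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = as.integer(shape)), class = "grid3d")
}

#' @rdname make_grid
#' @param grid A `grid3d`.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) && all(abs(a$spacing - b$spacing) < tol) &&
    all(a$shape == b$shape)
}

bohr_nm <- 0.0529177210903

#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and grid origin;
#' three axis records (voxel count and step vector); the atom block; then
#' volumetric data with z fastest.  Native units are Bohr; following the
#' Gaussian convention a negative voxel count flags Angstrom steps, and a
#' negative atom count flags the extra orbital-id record after the atoms.
#' All geometry is converted to nm.
#'
#' @param path Cube file path.
#' @return List with `grid` ([make_grid()]), `values` array (x, y, z),
#'   `atoms` tibble, `comments`, `dset_ids`, and the detected `units`.
#' @export
read_cube <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 7L) stop("malformed cube file: too short", call. = FALSE)
  comments <- ln[1:2]
  num <- function(s) scan(text = s, quiet = TRUE)
  hd <- num(ln[3])
  natom <- as.integer(hd[1])
  origin_raw <- hd[2:4]
  ax <- lapply(4:6, function(i) num(ln[i]))
  nvox <- vapply(ax, function(a) a[1], numeric(1))
  units <- if (any(nvox < 0)) "angstrom" else "bohr"
  conv <- if (units == "angstrom") 0.1 else bohr_nm
  shape <- as.integer(abs(nvox))
  steps <- lapply(ax, function(a) a[2:4] * conv)
  if (any(vapply(1:3, function(i) any(abs(steps[[i]][-i]) > 1e-12), logical(1))))
    stop("only axis-aligned cube grids are supported", call. = FALSE)
  spacing <- vapply(1:3, function(i) steps[[i]][i], numeric(1))
  origin <- origin_raw * conv

  at_lines <- ln[seq_len(abs(natom)) + 6L]
  atoms <- if (abs(natom) > 0) {
    m <- do.call(rbind, lapply(at_lines, num))
    tibble::tibble(number = as.integer(m[, 1]), charge = m[, 2],
                   x = m[, 3] * conv, y = m[, 4] * conv, z = m[, 5] * conv)
  } else tibble::tibble(number = integer(), charge = numeric(),
                        x = numeric(), y = numeric(), z = numeric())

  cursor <- 6L + abs(natom)
  dset_ids <- NULL
  if (natom < 0) {
    cursor <- cursor + 1L
    ids <- num(ln[cursor])
    dset_ids <- as.integer(ids[-1])
  }
  vals <- scan(text = paste(ln[(cursor + 1L):length(ln)], collapse = "\n"),
               quiet = TRUE)
  expected <- prod(shape)
  if (length(vals) != expected)
    stop(sprintf("cube data block has %d values, expected %d",
                 length(vals), expected), call. = FALSE)
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  list(grid = make_grid(origin, spacing, shape), values = arr, atoms = atoms,
       comments = comments, dset_ids = dset_ids, units = units)
}

#' Write a Gaussian cube file
#'
#' Inverse of [read_cube()]; geometry given in nm is written in Bohr
#' (default) or, with `units = "angstrom"`, with negated voxel counts per
#' the sign convention.
#'
#' @param grid A [make_grid()] grid (nm).
#' @param values Array matching `grid$shape` (x, y, z order).
#' @param path Output path.
#' @param atoms Optional tibble like the one [read_cube()] returns.
#' @param comments Two header lines.
#' @param units `"bohr"` or `"angstrom"`.
#' @export
write_cube <- function(grid, values, path, atoms = NULL,
                       comments = c("pepnet cube", "synthetic orbital volume"),
                       units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  stopifnot(all(dim(values) == grid$shape))
  conv <- if (units == "angstrom") 0.1 else bohr_nm
  sgn <- if (units == "angstrom") -1 else 1
  natom <- if (is.null(atoms)) 0L else nrow(atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments[1:2], con)
  fmt <- function(n, v) sprintf("%5d %15.9f %15.9f %15.9f", n, v[1], v[2], v[3])
  writeLines(fmt(natom, grid$origin / conv), con)
  for (i in 1:3) {
    step <- c(0, 0, 0); step[i] <- grid$spacing[i] / conv
    writeLines(fmt(sgn * grid$shape[i], step), con)
  }
  if (natom > 0) {
    for (k in seq_len(natom))
      writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$number[k],
                         atoms$charge[k], atoms$x[k] / conv, atoms$y[k] / conv,
                         atoms$z[k] / conv), con)
  }
  v <- aperm(values, c(3, 2, 1))  # z fastest in file order
  flat <- as.vector(v)
  nper <- 6L
  idx <- split(flat, (seq_along(flat) - 1L) %/% nper)
  # full double precision so volumes survive a write/read cycle losslessly
  writeLines(vapply(idx, function(row) paste(sprintf("%.16E", row),
                                             collapse = " "), character(1)), con)
  invisible(path)
}
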