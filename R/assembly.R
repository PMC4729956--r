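#' Build an antiparallel peptide dimer
#'
#' The dimer is the repeat unit of every observed assembly: a second copy
#' of the peptide rotated 180 degrees in plane, its backbone offset by
#' `gap`, and shifted longitudinally by `registry_shift` along the
#' backbone.  At the default shift of minus one rise the three polar
#' contacts of the linear octapeptide dimer (Arg2-His6', Tyr4-Tyr4',
#' His6-Arg2') align exactly; for the L-shaped decapeptide the short
#' C-terminal arm pokes into the gap, the steric-clash resolution widens
#' the gap, and the inner Tyr4/His6 beads end up beyond the contact
#' cutoff -- the geometric expression of why that dimer is held together
#' only at its ends (C-terminal against Arg2).
#'
#' Contacts between polar beads of the two peptides closer than
#' `params$contact_cutoff` are annotated as motifs.  The construction is
#' C2-symmetric about the dimer centre by construction.
#'
#' @param p A `peptide2d` in its build frame (backbone along x).
#' @param gap Requested backbone-to-backbone separation, nm; must exceed
#'   twice the bead offset, and is widened automatically until no two
#'   beads of different peptides are closer than `params$hardcore`.
#' @param params [pepnet_params()].
#' @return A `dimer` object with `peptide_a`, `peptide_b`, the effective
#'   `gap`, the `motifs` tibble and the C2 `center`.
#' @examples
#' d <- build_dimer(build_backbone(angiotensin_II(), "linear"))
#' d$motifs
#' @export
build_dimer <- function(p, gap = NULL, params = pepnet_params()) {
  stopifnot(inherits(p, "peptide2d"))
  gap <- gap %||% params$gap
  if (gap <= 2 * params$bead_offset)
    stop("gap must exceed twice the bead offset (steric clash)", call. = FALSE)

  n <- length(p$sequence$residues)
  r <- p$params$rise
  cx <- (n * r + params$registry_shift) / 2

  make_pair <- function(g) {
    a <- place_peptide(p, y = g / 2)
    b <- place_peptide(a, theta = 180, about = c(cx, 0))
    list(a = a, b = b)
  }
  g <- gap
  pair <- make_pair(g)
  while (min_cross_dist(bead_matrix(pair$a), bead_matrix(pair$b)) <
         params$hardcore) {
    g <- g + 0.025
    if (g > gap + 5) stop("could not resolve steric clash", call. = FALSE)
    pair <- make_pair(g)
  }

  motifs <- annotate_contacts(pair$a, pair$b, params$contact_cutoff)
  structure(list(peptide_a = pair$a, peptide_b = pair$b,
                 arrangement = "antiparallel",
                 gap = g, gap_requested = gap,
                 motifs = motifs, center = c(cx, 0), params = params),
            class = "dimer")
}

# polar bead contacts between two placed peptides; partner labels primed
annotate_contacts <- function(a, b, cutoff) {
  pa <- dplyr::filter(a$beads, .data$polarity == "polar", .data$kind != "backbone")
  pb <- dplyr::filter(b$beads, .data$polarity == "polar", .data$kind != "backbone")
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    return(tibble::tibble(a = character(), b = character(), dist = numeric()))
  d <- sqrt(outer(pa$x, pb$x, "-")^2 + outer(pa$y, pb$y, "-")^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  tibble::tibble(a = pa$label[hit[, 1]],
                 b = paste0(pb$label[hit[, 2]], "'"),
                 dist = d[hit]) |>
    dplyr::arrange(.data$dist)
}

#' @export
print.dimer <- function(x, ...) {
  cat(sprintf("<dimer> %s, %s, gap %.2f nm (requested %.2f), %d motif contact(s)\n",
              x$peptide_a$sequence$name, x$arrangement, x$gap, x$gap_requested,
              nrow(x$motifs)))
  if (nrow(x$motifs))
    cat("  ", paste(sprintf("%s-%s", x$motifs$a, x$motifs$b), collapse = ", "), "\n")
  invisible(x)
}

#' All beads of a dimer or assembly as one table
#' @param x A `dimer` or `assembly_model`.
#' @return A tibble of beads with a `peptide` identifier column.
#' @export
assembly_beads <- function(x) UseMethod("assembly_beads")

#' @export
assembly_beads.dimer <- function(x) {
  dplyr::bind_rows(dplyr::mutate(x$peptide_a$beads, peptide = "a"),
                   dplyr::mutate(x$peptide_b$beads, peptide = "b"))
}

#' @export
assembly_beads.assembly_model <- function(x) x$beads

#' Footprint of a dimer
#'
#' Bounding box of the residue and backbone beads inflated by a
#' van-der-Waals envelope radius; the terminal groups are excluded
#' because they carry no appreciable imaging signal.  The default
#' decapeptide dimer measures about 2.7 x 2.1 nm, bracketing the
#' apparent 2.7 x 2.3 nm footprint.
#'
#' @param d A `dimer`.
#' @param r_vdw Envelope radius added on every side, nm.
#' @return Named vector `c(length=, width=)`, length being the larger span.
#' @export
dimer_footprint <- function(d, r_vdw = 0.2) {
  b <- dplyr::filter(assembly_beads(d), .data$kind != "terminus")
  spans <- c(diff(range(b$x)), diff(range(b$y))) + 2 * r_vdw
  c(length = max(spans), width = min(spans))
}

place_dimer <- function(d, x = 0, y = 0, theta = 0) {
  about <- d$center
  d$peptide_a <- place_peptide(d$peptide_a, x, y, theta, about)
  d$peptide_b <- place_peptide(d$peptide_b, x, y, theta, about)
  d$center <- d$center + c(x, y)
  d
}

new_assembly <- function(kind, dimers = NULL, peptides = NULL, unit_cell = NULL,
                         annotations = character(), params = pepnet_params()) {
  if (!is.null(dimers)) {
    beads <- purrr::imap_dfr(dimers, function(d, i)
      dplyr::mutate(assembly_beads(d), peptide = paste0(i, .data$peptide),
                    dimer = i))
  } else {
    beads <- purrr::imap_dfr(peptides, function(p, i)
      dplyr::mutate(p$beads, peptide = as.character(i)))
  }
  structure(list(kind = kind, dimers = dimers, peptides = peptides,
                 beads = beads, unit_cell = unit_cell,
                 annotations = annotations, params = params),
            class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model> %s: %d peptide(s), %d beads\n", x$kind,
              length(x$dimers %||% list()) * 2 + length(x$peptides %||% list()),
              nrow(x$beads)))
  if (length(x$annotations)) cat("  ", paste(x$annotations, collapse = "; "), "\n")
  invisible(x)
}

#' Structure A: staggered chains of decapeptide dimers
#'
#' Dimers are stacked along their long (cross-backbone) axis with a
#' lateral stagger between successive dimers, reproducing the ~2.3 nm
#' wide, ~2.7 nm long repeat observed for the decapeptide.  End motifs
#' (C-terminal against Arg2, and the diagonal His9-His9' link between
#' adjacent dimers) are carried as annotations.
#'
#' @param d Template [build_dimer()] (decapeptide, L-shaped).
#' @param n Number of dimers, >= 1.
#' @param stagger Lateral offset between successive dimers, nm; 0 gives an
#'   unstaggered ladder, flagged as non-published geometry.
#' @param period Along-chain repeat, nm; defaults to the dimer footprint
#'   length.
#' @return An `assembly_model` of kind `"chain_A"`.
#' @export
build_chain_A <- function(d, n, stagger = 0.9, period = NULL) {
  stopifnot(inherits(d, "dimer"), n >= 1)
  period <- period %||% unname(dimer_footprint(d)["length"])
  dimers <- lapply(seq_len(n) - 1L, function(k)
    place_dimer(d, x = k * stagger, y = k * period))
  if (n > 1) {
    for (k in seq_len(n - 1L)) {
      if (min_cross_dist(bead_matrix(dimers[[k]]$peptide_a),
                         bead_matrix(dimers[[k + 1]]$peptide_b)) <
          d$params$hardcore)
        stop("adjacent dimers clash; increase period", call. = FALSE)
    }
  }
  ann <- c("end motif: C-terminal/Arg2", "end motif: His9-His9' diagonal",
           sprintf("chain period %.2f nm, stagger %.2f nm", period, stagger))
  if (stagger == 0) ann <- c(ann, "unstaggered ladder (non-published geometry)")
  new_assembly("chain_A", dimers = dimers,
               unit_cell = list(a = c(stagger, period), b = NULL, gamma = NA),
               annotations = ann, params = d$params)
}

#' Structure B: stacked antiparallel rows
#'
#' Peptides stack parallel along their long side into rows; adjacent rows
#' are rotated by 180 degrees so that row interfaces alternate between
#' N-terminal/N-terminal and C-terminal/C-terminal contacts.  The default
#' centre-to-centre row spacing is the observed 3.0 nm row width.
#'
#' @param p A `peptide2d` template.
#' @param n_rows,per_row Number of rows and peptides per row, >= 1.
#' @param row_spacing Centre-to-centre row distance, nm.
#' @param stack_spacing In-row stacking period, nm.
#' @return An `assembly_model` of kind `"rows_B"` whose `annotations`
#'   include the interface sequence (e.g. `N-N, C-C, N-N` for four rows).
#' @export
build_rows_B <- function(p, n_rows, per_row = 6, row_spacing = 3.0,
                         stack_spacing = 0.475) {
  stopifnot(inherits(p, "peptide2d"), n_rows >= 1, per_row >= 1)
  mid <- c(diff(range(p$beads$x)) / 2 + min(p$beads$x), 0)
  peptides <- list()
  for (k in seq_len(n_rows)) {
    flipped <- k %% 2L == 1L  # odd rows rotated so the first interface is N-N
    for (j in seq_len(per_row)) {
      q <- p
      if (flipped) q <- place_peptide(q, theta = 180, about = mid)
      peptides[[length(peptides) + 1L]] <-
        place_peptide(q, x = (k - 1L) * row_spacing, y = (j - 1L) * stack_spacing)
    }
  }
  interfaces <- if (n_rows > 1)
    ifelse(seq_len(n_rows - 1L) %% 2L == 1L, "N-N", "C-C") else character()
  new_assembly("rows_B", peptides = peptides,
               unit_cell = list(a = c(row_spacing, 0), b = c(0, stack_spacing),
                                gamma = 90),
               annotations = c(sprintf("row spacing %.2f nm", row_spacing),
                               if (length(interfaces))
                                 paste("interfaces:", paste(interfaces, collapse = ", "))),
               params = p$params)
}

#' Interface sequence of a rows assembly
#' @param asm An `assembly_model` of kind `"rows_B"`.
#' @return Character vector like `c("N-N","C-C","N-N")`.
#' @export
row_interfaces <- function(asm) {
  stopifnot(asm$kind == "rows_B")
  ann <- grep("^interfaces:", asm$annotations, value = TRUE)
  if (!length(ann)) return(character())
  strsplit(sub("^interfaces: ", "", ann), ", ")[[1]]
}

#' Triangular Au(111) reference lattice
#'
#' A visualization / height reference for the substrate.  The default
#' nearest-neighbour spacing 0.2884 nm is bulk Au a0 = 0.4078 nm over
#' sqrt(2) -- a modelling choice, the assemblies are not registered to it.
#'
#' @param n_cells Either one integer (n x n) or `c(nx, ny)` cells, >= 1.
#' @param spacing Nearest-neighbour distance, nm.
#' @param z0 Substrate plane height, nm.
#' @return A `substrate_lattice`: tibble of lattice points plus metadata.
#' @export
make_substrate <- function(n_cells, spacing = 0.2884, z0 = 0) {
  n_cells <- rep(as.integer(n_cells), length.out = 2L)
  stopifnot(all(n_cells >= 1L))
  g <- expand.grid(i = seq_len(n_cells[1]) - 1L, j = seq_len(n_cells[2]) - 1L)
  pts <- tibble::tibble(x = g$i * spacing + g$j * spacing / 2,
                        y = g$j * spacing * sqrt(3) / 2, z = z0)
  structure(list(points = pts, spacing = spacing, z0 = z0,
                 surface = "Au(111)"),
            class = "substrate_lattice")
}

#' @export
print.substrate_lattice <- function(x, ...) {
  cat(sprintf("<substrate_lattice> %s, %d sites, spacing %.4f nm, z0 = %.2f nm\n",
              x$surface, nrow(x$points), x$spacing, x$z0))
  invisible(x)
}
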