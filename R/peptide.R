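#' Build a planar peptide model
#'
#' Lays an amino-acid sequence out in the surface plane as a rigid 2D
#' building block: per-residue backbone anchors at a fixed rise, side-chain
#' beads alternating left/right of the backbone with residue parity, and
#' (optionally) two polar terminal beads.  The decapeptide adopts an
#' L-shape with the two C-terminal residues on a short perpendicular arm,
#' which bends towards the polar side; the octapeptide is linear.
#'
#' @param seq A [peptide_sequence()] or string.
#' @param shape `"linear"` or `"L"`.
#' @param params Parameter list from [pepnet_params()]; `rise`,
#'   `bead_offset`, `bend_after`, `bend_angle`, `include_termini`,
#'   `terminal_offset` and the bead heights are used.
#' @return A `peptide2d` object: the sequence, the backbone polyline
#'   (`anchors`), a `beads` tibble (columns `kind` in backbone/side/terminus,
#'   `index`, `code`, `label`, `polarity`, `side`, `x`, `y`, `z`), and the
#'   accumulated rigid-body `placement`.
#' @examples
#' p <- build_backbone(angiotensin_II(), "linear")
#' dplyr::count(residue_beads(p), polarity, side)
#' @export
build_backbone <- function(seq, shape = c("linear", "L"), params = pepnet_params()) {
  seq <- peptide_sequence(seq)
  shape <- match.arg(shape)
  n <- length(seq$residues)
  r <- params$rise
  cls <- classify_residues(seq)

  if (shape == "L") {
    b <- as.integer(params$bend_after)
    if (b <= 1L || b >= n)
      stop(sprintf("bend_after must lie strictly inside the chain (1, %d)", n),
           call. = FALSE)
  } else {
    b <- n  # no bend
  }

  d1 <- c(1, 0)
  d2 <- as.numeric(rot2(-params$bend_angle) %*% d1)  # arm turns to polar side
  t_bend <- b * r
  along <- function(t) {
    if (t <= t_bend) rbind(t * d1) else rbind(t_bend * d1 + (t - t_bend) * d2)
  }
  tt <- (seq_len(n) - 0.5) * r
  anchors_xy <- do.call(rbind, lapply(tt, along))
  dir_i <- lapply(seq_len(n), function(i) if (i <= b) d1 else d2)

  side <- ifelse(cls$index %% 2L == 1L, 1L, -1L)
  normal <- t(vapply(dir_i, function(d) c(-d[2], d[1]), numeric(2)))
  bead_xy <- anchors_xy + side * params$bead_offset * normal

  anchors <- tibble::tibble(index = cls$index,
                            x = anchors_xy[, 1], y = anchors_xy[, 2],
                            z = params$backbone_z)

  beads <- dplyr::bind_rows(
    tibble::tibble(kind = "backbone", index = cls$index, code = cls$code,
                   label = cls$label, polarity = cls$polarity, side = 0L,
                   x = anchors_xy[, 1], y = anchors_xy[, 2],
                   z = params$backbone_z),
    tibble::tibble(kind = "side", index = cls$index, code = cls$code,
                   label = cls$label, polarity = cls$polarity, side = side,
                   x = bead_xy[, 1], y = bead_xy[, 2], z = params$side_z)
  )

  if (isTRUE(params$include_termini)) {
    start <- c(0, 0) - params$terminal_offset * d1
    d_end <- dir_i[[n]]
    endp <- as.numeric(along(n * r)) + params$terminal_offset * d_end
    beads <- dplyr::bind_rows(
      beads,
      tibble::tibble(kind = "terminus", index = c(0L, n + 1L),
                     code = c("Nt", "Ct"), label = c("N-term", "C-term"),
                     polarity = "polar", side = 0L,
                     x = c(start[1], endp[1]), y = c(start[2], endp[2]),
                     z = params$terminal_z)
    )
  }

  structure(list(sequence = seq, shape = shape, params = params,
                 anchors = anchors, beads = beads,
                 placement = list(x = 0, y = 0, theta = 0),
                 orientation = "N->C"),
            class = "peptide2d")
}

#' @export
print.peptide2d <- function(x, ...) {
  cat(sprintf("<peptide2d> %s (%s), %d residues, %d beads; placed at (%.2f, %.2f) nm, %.1f deg\n",
              x$sequence$name, x$shape, length(x$sequence$residues),
              nrow(x$beads), x$placement$x, x$placement$y, x$placement$theta))
  invisible(x)
}

#' Residue (side-chain) beads of a peptide model
#'
#' @param p A `peptide2d`.
#' @return The `beads` rows with `kind == "side"`, one per residue.
#' @export
residue_beads <- function(p) dplyr::filter(p$beads, .data$kind == "side")

#' Rigid-body placement of a peptide
#'
#' Rotates the peptide by `theta` degrees about the origin of its current
#' frame and translates it by `(x, y)`; all intra-peptide distances are
#' preserved exactly.
#'
#' @param p A `peptide2d`.
#' @param x,y Translation in nm.
#' @param theta Anticlockwise in-plane rotation in degrees.
#' @param about Rotation centre (length-2, nm) in the current frame.
#' @return The transformed `peptide2d`.
#' @export
place_peptide <- function(p, x = 0, y = 0, theta = 0, about = c(0, 0)) {
  tr <- function(df) {
    rot <- rotate_xy(df$x, df$y, theta, about[1], about[2])
    df$x <- rot$x + x
    df$y <- rot$y + y
    df
  }
  p$anchors <- tr(p$anchors)
  p$beads <- tr(p$beads)
  p$placement <- list(x = p$placement$x + x, y = p$placement$y + y,
                      theta = p$placement$theta + theta)
  p
}

#' Mirror a peptide about the x axis
#'
#' Used to build the mirror image of chiral assemblies; flips the handedness
#' (left/right side assignments are relabelled accordingly).
#' @param p A `peptide2d`.
#' @return The reflected `peptide2d`.
#' @export
mirror_peptide <- function(p) {
  p$anchors$y <- -p$anchors$y
  p$beads$y <- -p$beads$y
  p$beads$side <- -p$beads$side
  p$placement$theta <- -p$placement$theta
  p
}

bead_matrix <- function(p) as.matrix(p$beads[, c("x", "y")])
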