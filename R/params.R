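#' Model parameters
#'
#' One flat list of the tunable geometric parameters, overridable per call
#' or from a YAML configuration file.  Lengths in nm, angles in degrees.
#'
#' * `rise` 0.2875 - backbone rise per residue; calibrated so 8 residues
#'   span 2.3 nm.
#' * `bead_offset` 0.25 - lateral offset of side-chain beads from the
#'   backbone line.
#' * `bend_after` 8, `bend_angle` 90 - position and angle of the L-shape
#'   bend of the decapeptide (short arm His9-Leu10).
#' * `include_termini` TRUE - model the N-terminal amine and C-terminal
#'   carboxyl as two extra polar beads at the chain ends.
#' * `terminal_offset` 0.15 - how far the terminal beads sit beyond the
#'   backbone ends.
#' * `backbone_z` 0.25, `side_z` 0.32, `terminal_z` 0.28 - bead heights
#'   above the substrate plane, used by the STM simulator.
#' * `gap` 0.9 - antiparallel dimer backbone-to-backbone separation.
#' * `registry_shift` -0.2875 - longitudinal shift of the antiparallel
#'   partner; at -1 rise the three polar dimer contacts
#'   (Arg2-His6', Tyr4-Tyr4', His6-Arg2') align exactly.
#' * `hardcore` 0.25 - minimum allowed bead-bead distance between
#'   different peptides; dimer construction widens the gap until satisfied.
#' * `contact_cutoff` 0.5 - bead-bead distance below which a polar contact
#'   is annotated as a binding motif.
#' * `wall_reach` 1.585 - effective half-thickness of a dimer wall, from
#'   its centreline to the apparent inner pore face; calibrated jointly
#'   with a = 5.5 nm and chi = +6 deg so the default honeycomb reports a
#'   2.30 nm across-flats inner pore diameter.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
pepnet_params <- function(...) {
  p <- list(
    rise = 0.2875,
    bead_offset = 0.25,
    bend_after = 8L,
    bend_angle = 90,
    include_termini = TRUE,
    terminal_offset = 0.15,
    backbone_z = 0.25,
    side_z = 0.32,
    terminal_z = 0.28,
    gap = 0.9,
    registry_shift = -0.2875,
    hardcore = 0.25,
    contact_cutoff = 0.5,
    wall_reach = 1.585
  )
  utils::modifyList(p, list(...))
}

#' @rdname pepnet_params
#' @param path YAML file whose top-level keys (optionally nested under a
#'   `geometry:` section) override the defaults.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$geometry)) cfg <- utils::modifyList(cfg, cfg$geometry)
  cfg$geometry <- NULL
  do.call(pepnet_params, cfg)
}
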