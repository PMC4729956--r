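Package: pepnet
Title: Sequence-Controlled 2D Peptide Self-Assembly on Au(111): Models,
    Simulated STM Images and Lattice Metrology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric building-block models for angiotensin peptides
    confined to a metal surface, constructors for their observed
    two-dimensional assemblies (staggered dimer chains, stacked antiparallel
    rows and a chiral double-walled honeycomb network with distance, vertex
    and grain-boundary defects), a molecular-orbital scanning-tunnelling
    topograph simulator (occupied orbitals within an energy window are
    squared, summed, and the constant-density isosurface is rendered as
    height above the substrate), and image/graph metrology that recovers
    lattice constants, chirality angles, pore geometry, stripe periods,
    ring statistics and domain misorientations from synthetic images with
    known ground truth.  Includes electrospray ion-beam deposition dose
    bookkeeping and Gaussian cube file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
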