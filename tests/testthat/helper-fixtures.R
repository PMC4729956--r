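# Lazily built shared fixtures; the image renders are the expensive part,
# so each is computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

hc33_net <- function() fixture("hc33_net", function() build_honeycomb(cells = c(3, 3)))

hc33_image <- function() fixture("hc33_image", function()
  gen_assembly_image("honeycomb", params = list(cells = c(3, 3)))$image)

rows_image <- function() fixture("rows_image", function()
  gen_assembly_image("rows_B", params = list(n_rows = 6, per_row = 8))$image)

at1_dimer <- function() fixture("at1_dimer", function()
  build_dimer(build_backbone(angiotensin_I(), "L")))

at2_dimer <- function() fixture("at2_dimer", function()
  build_dimer(build_backbone(angiotensin_II(), "linear")))

# pairwise distances of a bead table, sorted (rigid-body fingerprints)
bead_dists <- function(beads) {
  m <- as.matrix(beads[, c("x", "y")])
  sort(as.vector(stats::dist(m)))
}
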