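test_that("polarity classification matches the published residue assignment", {
  cls <- classify_residues("DRVYIHPF")
  expect_equal(cls$polarity,
               c("polar", "polar", "nonpolar", "polar", "nonpolar", "polar",
                 "nonpolar", "nonpolar"))
  cls10 <- classify_residues("DRVYIHPFHL")
  expect_equal(cls10$polarity[1:8], cls$polarity)
  expect_equal(cls10$polarity[9:10], c("polar", "nonpolar"))  # His9, Leu10
  expect_equal(cls10$label[c(4, 9)], c("Tyr4", "His9"))
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(peptide_sequence(""), "at least one residue")
  expect_error(classify_residues("DRX"), "'X' at position 3")
})

test_that("average masses reproduce standard residue chemistry", {
  # glycine: residue mass plus one water
  expect_equal(average_mass("G"), 75.07, tolerance = 1e-4)
  # independent oracle: seqinr's protein molecular weight
  skip_if_not_installed("seqinr")
  for (s in c("DRVYIHPFHL", "DRVYIHPF", "ACDEFGHIKLMNPQRSTVWY")) {
    expect_equal(average_mass(s),
                 seqinr::pmw(strsplit(s, "")[[1]]),
                 tolerance = 0.5)
  }
})

test_that("contour length is residues times rise", {
  expect_equal(contour_length(angiotensin_II()), 2.3, tolerance = 1e-9)
  expect_equal(contour_length(angiotensin_I()), 2.875, tolerance = 1e-9)
  expect_error(contour_length("AG", 0), "positive")
  expect_error(contour_length("", 0.2875), "at least one residue")
})

test_that("C-terminal truncation turns the decapeptide into the octapeptide", {
  expect_equal(as.character(truncate_cterm(angiotensin_I(), 2)), "DRVYIHPF")
  expect_equal(as.character(truncate_cterm("AG", 1)), "A")
  expect_error(truncate_cterm("AG", 2))
  expect_error(truncate_cterm("AG", 0), "allow_identity")
  expect_equal(as.character(truncate_cterm("AG", 0, allow_identity = TRUE)), "AG")
})

test_that("linear backbones alternate side beads and segregate polarity", {
  p <- build_backbone(angiotensin_II(), "linear")
  rb <- residue_beads(p)
  expect_equal(nrow(rb), 8L)
  expect_equal(rb$side, rep(c(1L, -1L), 4))
  nonpolar_side <- rb$side[rb$label %in% c("Val3", "Ile5", "Pro7")]
  polar_side <- rb$side[rb$label %in% c("Arg2", "Tyr4", "His6")]
  expect_length(unique(nonpolar_side), 1L)
  expect_length(unique(polar_side), 1L)
  expect_false(unique(nonpolar_side) == unique(polar_side))
})

test_that("L-shaped backbones put the two C-terminal residues on a short arm", {
  p <- build_backbone(angiotensin_I(), "L")
  a <- p$anchors
  expect_equal(diff(a$x[1:8]), rep(0.2875, 7), tolerance = 1e-9)
  expect_equal(a$x[9], a$x[10], tolerance = 1e-9)       # arm runs perpendicular
  expect_lt(a$y[10], a$y[9])
  expect_error(build_backbone("DRVYIHPFHL", "L",
                              pepnet_params(bend_after = 10)),
               "strictly inside")
  p1 <- build_backbone("G", "linear")
  expect_equal(nrow(p1$anchors), 1L)
})

test_that("rigid-body placement preserves all pairwise bead distances", {
  p <- build_backbone(angiotensin_I(), "L")
  ref <- bead_dists(p$beads)
  set.seed(11)
  for (k in 1:8) {
    q <- place_peptide(p, x = runif(1, -9, 9), y = runif(1, -9, 9),
                       theta = runif(1, 0, 360),
                       about = runif(2, -2, 2))
    expect_equal(bead_dists(q$beads), ref, tolerance = 1e-9)
  }
  expect_equal(bead_dists(mirror_peptide(p)$beads), ref, tolerance = 1e-9)
})

test_that("FASTA reading preserves names and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">At-I native", "DRVYIHPFHL", ">At-II", "DRVYIHPF"), f)
  tab <- read_peptide_fasta(f)
  expect_equal(tab$name, c("At-I native", "At-II"))
  expect_equal(tab$sequence, c("DRVYIHPFHL", "DRVYIHPF"))
  expect_s3_class(tab$peptide[[1]], "peptide_sequence")
})

test_that("parameters can be loaded from a YAML config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("geometry:", "  rise: 0.3", "  bead_offset: 0.3"), f)
  p <- read_params(f)
  expect_equal(p$rise, 0.3)
  expect_equal(p$bead_offset, 0.3)
  expect_equal(p$bend_after, 8L)  # untouched default
})
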