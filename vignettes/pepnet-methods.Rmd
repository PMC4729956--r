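---
title: "Models and metrology for 2D peptide self-assembly on Au(111)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrology for 2D peptide self-assembly on Au(111)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepnet)
```

`pepnet` models the self-assembly of the angiotensin peptides on a
Au(111) surface as explicit planar geometry, simulates STM images of the
assemblies from a molecular-orbital picture, and measures the published
lattice observables back from those models and images. This vignette
explains the model, its assumptions and calibrations, the numerical
choices, and what the synthetic data can and cannot tell you about real
experiments.

## The planar peptide model

A peptide confined to a metal surface at low temperature is treated as a
rigid 2D object: per-residue backbone anchors laid out at a fixed rise,
one side-chain bead per residue at a fixed lateral offset, alternating
sides with residue parity (the beta-strand-like motif that segregates
the polar face Arg2/Tyr4/His6 from the nonpolar face Val3/Ile5/Pro7 in
At-II), plus two optional polar terminal beads.

Key parameters (all in `pepnet_params()`, overridable per call or from
YAML):

* `rise = 0.2875` nm — *calibration*, chosen once so that the 8-residue
  At-II spans the measured 2.3 nm. It is not a prediction of backbone
  chemistry.
* `bead_offset = 0.25` nm — the surface projection of a side chain;
  no measured value exists, so a typical united-residue scale is used.
* `bend_after = 8`, `bend_angle = 90` deg — the At-I L-shape. The
  experiments locate His9 and Leu10 on a short arm but give neither the
  bend position nor its angle; placing the bend after Phe8 at 90 degrees
  towards the polar side is a design decision, kept configurable. The
  choice has a consequence we consider a feature: in the antiparallel
  At-I dimer the arm pokes into the inter-backbone gap, steric-clash
  resolution widens the gap, and the inner Tyr4/His6 beads end up beyond
  the contact cutoff — the geometric counterpart of the observation that
  the decapeptide dimer is bonded only at its ends.
* `include_termini = TRUE` — the N-terminal amine and C-terminal
  carboxyl as two extra polar beads; toggleable because whether the
  printed 2.3 nm At-II length includes the termini is not stated. We
  exclude terminal beads from footprint measurements since they carry
  almost no imaging signal.

## Dimers and assemblies

The antiparallel dimer is a 180-degree in-plane rotation of the peptide
about a point on the mid-line, longitudinally shifted by
`registry_shift = -rise`. At that registry the three polar contacts of
the linear At-II dimer (Arg2–His6', Tyr4–Tyr4', His6–Arg2') align
exactly; contacts are annotated whenever two polar beads of different
peptides come within `contact_cutoff = 0.5` nm. A hard-core distance of
0.25 nm between beads of different peptides is enforced by widening the
gap, never by bending the molecules — the building block is rigid.

Structure A stacks At-I dimers along their long axis with a lateral
stagger; structure B stacks peptides into rows whose centre-to-centre
spacing defaults to the measured 3.0 nm, with alternate rows rotated by
180 degrees so interfaces alternate N-terminal/N-terminal and
C-terminal/C-terminal.

The honeycomb network places one dimer on every edge of a hexagonal
lattice with superlattice constant `a = 5.5` nm. Chirality is
implemented as a rotation of each dimer about its own midpoint by the
chirality angle (+6 degrees by default, anticlockwise positive). This
one-parameter construction reproduces simultaneously the rotated pore
hexagons and the splayed three-fold vertex; the experiments describe the
observation, not the parameterisation, so this is our modelling choice.

The across-flats reading of the pore "inner diameter" is used
throughout: a 2.3 nm across-flats hexagon has area
(sqrt(3)/2) d^2 = 4.58 nm², consistent with the printed 4.5 nm², whereas
the across-corners reading would give 3.4 nm². The wall half-thickness
`wall_reach = 1.585` nm (centreline of a dimer wall to its apparent
inner face) is the second calibration of the package: it is fixed so
that the *default* network (a = 5.5 nm, chirality +6 degrees) reports an
across-flats inner diameter of 2.30 nm, because the measured pore size
reflects the full electron envelope of the walls rather than bead
centres. Both calibrations were fixed once, before the validation suite
was written, and are documented as calibrations wherever they surface.

## STM simulation

The simulator follows the molecular-orbital recipe: all occupied
orbitals within `window_eV = 2` of the HOMO (boundary inclusive — the
source description does not state inclusivity, so we document our
choice) are squared and summed, and the image is the height of the
constant-density isosurface above the substrate plane, with sub-voxel
linear interpolation along z. We read "convoluted with the relative
distance away from the substrate" as exactly this constant-density
topograph: brightness = isosurface height; a literal smoothing kernel
has no dimensional meaning here. A constant-height density slice is
provided as a companion mode.

Orbitals for an assembly are built from isotropic Gaussian lobes
(`sigma = 0.18` nm) at the bead positions, side-chain and terminal lobes
on the frontier orbital and backbone lobes on a second occupied orbital
1 eV deeper, so the window selection is a live part of every simulated
image. The per-residue amplitude table is the simulator's calibration
surface, chosen to reproduce the qualitative contrast of the
experiments and shipped as a configurable list rather than hard-coded:

* backbone 0.8 — the brightest ridge runs along the backbone;
* Tyr and His side chains 1.0 — the strongest residue features;
* Phe 0.7 — the phenyl groups are the only density at the honeycomb
  vertex, giving the three-protrusion/three-depression fingerprint;
* Asp and Leu side chains 0.02, C terminus 0.02, N terminus 0.15, and
  the backbone amplitude under Asp/Leu scaled by 0.1 — these segments
  image dark, which is why the molecule appears as four protrusions in
  a line and why both row interfaces of structure B are resolvable.

Because no isovalue or grid spacing is reported for the original
simulations, simulated-image comparisons are qualitative (contrast
ordering); the defaults are isovalue = 1% of the density maximum and
0.05 nm grid spacing.

## Metrology conventions

* Angles in degrees, anticlockwise positive. Unit-cell angles are
  reported in the (60, 120] convention, preferring the obtuse
  representative (the hexagonal 120-degree convention).
* The lattice fit clusters short pairwise difference vectors of the
  pore-centre set by direction and takes the two shortest non-collinear
  cluster means; collinear centre sets are rejected as degenerate.
* Chirality of a network is the mean signed offset of the wall-axis
  directions from the half-way direction (30 degrees mod 60) between
  superlattice principal directions; on images, pore-wall distances are
  profiled radially around each detected pore and the phase of the
  six-fold Fourier component gives the hexagon orientation.
* The stripe period estimator projects the image onto the stripe
  normal and reads the zero-padded 1D spectrum. Alternating row
  decoration puts the spectral fundamental at twice the row spacing;
  when the second harmonic carries at least 15% of the fundamental's
  power the estimator reports the harmonic — the spacing of the rows
  themselves. A pure sinusoidal stripe pattern is unaffected.
* Ring statistics traverse the faces of the straight-line planar
  embedding (rotation system from bead coordinates); the outer face is
  excluded by orientation, and faces above `max_ring = 12` are treated
  as sampling holes, not rings.

## Synthetic data and its limits

Every input the pipeline needs is generated with known ground truth:
toy orbital volumes as cube files with an energy manifest, STM-like
images of the three assemblies (additive Gaussian pixel noise plus an
optional per-scanline offset, mimicking line noise), and two-domain
networks for grain-boundary analysis. Ground-truth records are written
alongside every artifact and regeneration from a record is
bit-identical under the recorded seed.

The grain-boundary generator merges two half-lattices of pore centres
rotated by ±theta/2, thins the doubled seam band with a hard-core rule,
relaxes the band (a tapered local Laplacian step that cannot remove
topologically protected dislocations), re-triangulates, and builds the
dual pore graph. The analysis window includes or excludes whole
dislocation cores (a 5-ring with its adjacent 7-ring), the way
boundary-touching particles are handled in counting frames — a cut
through a core would convert a windowing artifact into a fake
ring-statistics signal. Around 1 degree the seam stays all-hexagon over
fields of this size (dislocation spacing far exceeds the window); in
the 16–21 degree range the seam carries cleanly paired 5/7 rings.
Beyond about 22 degrees the cores crowd to within the exclusion radius
of boundary-compromised features at this window size, and few or no
complete cores survive the counting rule; the misorientation itself is
still recovered by the orientation-field analysis. This is a known
limitation of the generator, not of the ring-statistics operation.

What passing tests show — and what they do not: the synthetic images
share the geometry, contrast ordering and simple noise of the
experimental system, so they validate the *recovery logic* (build
parameters in, measured values out, at stated tolerances). They do not
emulate tip changes, thermal drift, creep, bias-dependent contrast or
tip convolution, so performance on real STM data is out of scope.

## Numerical choices and problem sizes

Delaunay triangulation is an incremental Bowyer–Watson implementation
(no suitable triangulation package is available to this package);
near-cocircular ties are broken by a deterministic jitter of 1e-4
lattice constants under the caller's seed. The topograph oracle test
checks the renderer against the closed-form Gaussian isosurface height
to within one z-voxel. Stochastic tests fix their seeds.

The validation suite runs on 3 x 3-cell networks (9 pores, ~500 x 400
pixel images) and the acceptance script on 5 x 5 cells (25 pores,
~860 x 590 pixels), sizes at which the lattice fit is already
over-determined by an order of magnitude; six-row images are used for
the stripe period. Two-domain fields are 60 x 52 nm (~130 pore
centres). These sizes keep a full run in tens of seconds on one CPU
while leaving every estimator's precision far inside the tolerances
quoted in the tests.

## Known limitations

* The bead model is rigid and athermal: no conformational relaxation,
  no force-field energetics, no protonation chemistry. Motif "contacts"
  are geometric annotations, not bonds.
* The bare-bead footprint of the At-I dimer (2.7 x 2.1 nm with a 0.2 nm
  van-der-Waals pad) brackets but does not exactly reproduce the
  apparent 2.3 x 2.7 nm STM footprint, which includes the electron
  envelope.
* The uniform 6-degree chirality is treated as exact across the
  network; the experiments report an essentially uniform adsorption
  geometry but small per-molecule variations surely exist.
* Grain-boundary ring counting above ~22 degrees returns few complete
  cores at the default window size (see above).
* Coverage from deposition doses is reported as a fraction only when a
  spot area is supplied; no sticking-probability or re-desorption model
  is included (both assumed ideal).
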