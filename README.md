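# pepnet

Sequence-controlled 2D peptide self-assembly on Au(111): geometric
building-block models, simulated scanning-tunnelling-microscopy (STM)
images, and lattice metrology, in one tidyverse-style R package.

## The problem

Angiotensin I (At-I, `DRVYIHPFHL`, 1,296 g/mol) and its truncation
angiotensin II (At-II, `DRVYIHPF`, 1,046 g/mol) self-assemble on a
Au(111) surface into strikingly different 2D structures: the decapeptide
forms small staggered-dimer chains (structure A, ~2.3 x 2.7 nm dimers)
and stacked antiparallel rows of 3 nm width (structure B), while removing
His9 and Leu10 straightens the backbone and unlocks a long-range-ordered
chiral honeycomb network — unit cell a = b = 5.5 nm at 120 degrees, pore
inner diameter 2.3 nm (4.5 nm² pore area), with the pore hexagons rotated
anticlockwise by 6 degrees relative to the superlattice. `pepnet` is for
researchers who want a quantitative, testable model chain for this kind
of system: from a one-letter sequence to a planar bead model, to the
assembled network, to a simulated STM image, and back to measured
lattice observables with known ground truth.

## What it computes

* **Peptide model** — residue polarity classification (polar Asp, Arg,
  Tyr, His versus nonpolar Val, Ile, Pro, Phe, Leu), average masses,
  contour lengths (`n` residues x 0.2875 nm rise, calibrated so At-II
  spans 2.3 nm), and planar backbones: linear for At-II, L-shaped for
  At-I with His9/Leu10 on a short perpendicular arm. Side-chain beads
  alternate sides with residue parity, segregating the polar and
  nonpolar faces.
* **Assemblies** — antiparallel dimers (for linear At-II, the three
  polar contacts Arg2–His6', Tyr4–Tyr4', His6–Arg2' align exactly; for
  L-shaped At-I the arm forces the backbones apart and only the
  C-terminal/Arg2 end motif survives), staggered chains, 180°-alternating
  stacked rows, and the chiral double-walled honeycomb, where each
  hexagon edge hosts one dimer rotated by the chirality angle about its
  own midpoint. Defects: dimer distance defects, vertex twists, and
  two-domain grain boundaries re-triangulated along the seam
  (~1 degree boundaries stay all-hexagon, 16–25 degree boundaries carry
  paired 5- and 7-membered rings).
* **STM simulation** — the molecular-orbital recipe: occupied orbitals
  within 2 eV of the HOMO are squared and summed, and the constant-density
  isosurface of the sum is rendered as height above the substrate
  (`rho(x,y,z) >= iso`, brightness = z). Gaussian cube I/O, a
  Gaussian-lobe orbital model with a per-residue amplitude table
  (backbone ridge bright; Tyr/His brightest; Asp1, Leu10 and the
  C terminus dark), constant-height companion mode, and STM-style noise.
* **Metrology** — pore-centre detection, Bravais-lattice fitting
  (autocorrelation of the centre set), signed chirality, across-flats
  pore diameter and area, stripe-period recovery, planar-graph ring
  statistics, and domain-misorientation mapping.
* **Deposition bookkeeping** — electrospray ion-beam deposition dose to
  molecule count: `N = Q[pAh] * 3.6e-9 / (z * e)`.

## Worked example

```r
library(pepnet)

at1 <- angiotensin_I()
at2 <- truncate_cterm(at1, 2, name = "At-II")
average_mass(at1)        # 1296 g/mol
average_mass(at2)        # 1046 g/mol
contour_length(at2)      # 2.30 nm

d <- build_dimer(build_backbone(at2, "linear"))
d
#> <dimer> At-II, antiparallel, gap 0.90 nm (requested 0.90), 3 motif contact(s)
#>    Arg2-His6', Tyr4-Tyr4', His6-Arg2'

net <- build_honeycomb(cells = c(3, 3))   # a = 5.5 nm, chirality +6 deg
glance(measure_honeycomb(net))
#> # A tibble: 1 x 8
#>       a     b gamma chirality pore_d pore_area n_pores n_centres
#>   <dbl> <dbl> <dbl>     <dbl>  <dbl>     <dbl>   <int>     <int>
#> 1   5.5   5.5   120      6.00   2.30      4.58       9         9

molecules_from_dose(dose_record(43, 2))   # 4.83e11 molecules
```

The recovered unit cell (5.5 nm, 120 degrees), chirality (+6 degrees),
pore diameter (2.30 nm) and area (4.58 nm², printed as 4.5 nm² in the
source experiments) are measured back from the built model, not read
from its inputs. `autoplot()` works on peptides, dimers, networks, pore
graphs and images; `tidy()`/`glance()` work on dimers, lattice fits and
metrology results.

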