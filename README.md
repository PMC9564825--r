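# mtlattice

Quantitative geometry of microtubule lattices and their inner proteins
(MIPs), for structural biologists working on cilia, flagella and other
microtubule-based machines.

Cryo-EM structures of axonemal doublet microtubules and of sperm singlet
microtubules show MIPs bound to the lumenal wall in characteristic
patterns — striation arcs across a few interprotofilament interfaces,
noncontinuous spirals that skip the lattice seam, and filaments running
along protofilaments. Asking whether such a decoration remodels the
tubulin lattice, and describing the decoration itself, comes down to a
small set of geometric descriptors. `mtlattice` computes them from atomic
models (PDB/mmCIF), generates synthetic lattices with known ground truth so
every estimator is testable, and realigns cryo-EM particle orientation
tables to a common seam register.

## Descriptors

For a microtubule of N protofilaments with tubulin dimers of rise d:

* **Longitudinal dimer spacing** — distances between mass centers of
  consecutive dimers along a protofilament (n dimers → n−1 values; a 48-nm
  column of 6 dimers yields 5).
* **Interprotofilament angle** θ — the rotation angle
  `acos((tr(R) − 1)/2)` of the least-squares (Kabsch) superposition R
  mapping a dimer onto its lateral neighbor; θ = 360°/N for an ideal tube.
* **MIP tilt angle** τ — the angle between a MIP's principal long axis and
  the least-squares plane of the two tubulin dimers it bridges, in
  [0°, 90°].
* **Buried interface area** — the PISA convention
  `A = (SASA(A) + SASA(B) − SASA(A∪B)) / 2` over Shrake–Rupley
  solvent-accessible areas (probe 1.4 Å).
* **Decoration periodicity, handedness, copies per repeat** — the axial
  repeat of a MIP class (median of per-column spacings, in nm), the sign
  of its rise around the tube viewed from the plus end, and the copy count
  of one spiral/striation unit.
* **Pairwise MIP RMSD** — after superposing each copy's associated
  alpha-tubulin, the conformational spread of a MIP class across lattice
  positions.
* **Seam detection** — the unique lateral interface whose nearest
  monomer-monomer contacts are heterotypic (alpha against beta).
* **Seam-register realignment** — removes per-class pseudo-helical offsets
  (k·360/N rotations about the helical axis, m·d/2 monomer shifts) from
  STAR-format particle orientation tables (Euler ZYZ:
  `R = Rz(rot)·Ry(tilt)·Rz(psi)`).

## Worked example

Build the default synthetic TAILS-like lattice — a closed 13-protofilament
singlet with an 8-nm dimer rise, one seam, and a MIP rod on every non-seam
lateral interface at every dimer repeat — then annotate it from
coordinates alone and measure everything:

```r
library(mtlattice)

template <- build_dimer_template(seed = 1)
lat <- build_singlet(lattice_params(), template)
lat <- decorate_mips(lat, mip_decoration("SPACA9"))

ann <- annotate_lattice(lat$model)
ann
#> lattice_annotation: 228 chains; axis ~ ( 0.000, -0.000, 1.000 )
#>   tubule S: 13 pf, closed, seam interface 12, numbering from chain labels

analyze_model(lat$model, annotation = ann)
#> geometry_report
#>   tubule S: 13 pf (closed), seam interface 12
#>   dimer spacing: mean 80.000 A over 65 measurements
#>   interprotofilament angle (non-seam): mean 27.692 deg
#>   MIP SPACA9: 72 copies, 12 per repeat, periodicity 8.0 nm, left-handed
#>     tilt: 51.5-51.5 deg (mean 51.5)
#>     interface area: mean 95 A^2
#>     pairwise RMSD: 0.00-0.00 A
```

Reading the output: the annotation recovered the 13 protofilaments and
located the seam at the last interface; dimer spacing reproduces the 80 Å
(8 nm) rise; the interprotofilament angle is 360/13 = 27.692°; the
decoration forms a left-handed spiral of 12 copies per 8-nm repeat
(the seam interface stays empty), each copy tilted 51.5° against its
protofilament pair; and all copies are exact lattice images of one
another, hence zero pairwise RMSD.

Deposited atomic models are analyzed the same way —
`analyze_model("model.cif", chain_map = "chains.json")` — with the chain
map naming each chain's role (alpha/beta/MIP class) when author chain
subdivisions do not match the size-based default.

A command-line pipeline wrapping these functions (subcommands `simulate`,
`analyze`, `compare`, `realign`) ships as
`system.file("scripts", "mtlattice-cli.R", package = "mtlattice")`.

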