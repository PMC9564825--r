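---
title: "Microtubule lattice geometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microtubule lattice geometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cilia and flagella are built from microtubules whose lumens are lined with
microtubule inner proteins (MIPs). Recent cryo-EM structures of axonemal
doublets and of the singlet microtubules of the distal sperm flagellum show
MIPs bound in characteristic geometric patterns: striation arcs bridging a
few interprotofilament interfaces, noncontinuous spirals that occupy every
lateral interface except the seam, and filaments running longitudinally
along single protofilaments. Whether such a decoration stabilizes, bends or
leaves the tubulin lattice unchanged is a quantitative question about
lattice geometry: longitudinal dimer spacing, interprotofilament rotation
angles, MIP tilt relative to the wall, buried interface area, decoration
periodicity and handedness.

`mtlattice` implements those descriptors as a reusable toolkit, together
with a synthetic-lattice generator that makes every estimator testable
against known ground truth, and a seam-register utility that removes the
pseudo-helical alignment ambiguities of microtubule particle orientation
tables.

## The lattice model

An idealized microtubule is parameterized by `lattice_params()`:

* `n_pf` — protofilament count (default 13, the canonical singlet/A-tubule).
* `dimer_rise` — longitudinal rise per tubulin dimer along the axis, in
  Angstrom. Default 80 (the 8-nm tubulin repeat at the precision the field
  reports it); 82 mirrors the 8.2-nm extraction rise used in helical
  particle picking and can be set explicitly.
* `monomer_len` — axial monomer length, default `dimer_rise / 2` (4 nm,
  the alpha/beta monomer spacing).
* `stagger` — axial offset per lateral interface. Default
  `3 * monomer_len / n_pf`: the 3-start B lattice, in which the stagger
  accumulated around the tube equals three monomer lengths. Because three
  is odd, the closure interface puts alpha monomers against beta monomers —
  the seam — and the constructor enforces an integer total monomer offset
  so that exactly one seam exists for any `n_pf`.
* `radius` — protofilament circle radius, default 105 Angstrom (a 25-nm
  microtubule).
* `seam_index` — which lateral interface carries the closure break.
* `polarity` — `plus_up` places alpha below beta along +z.
* `handedness_sign` — the sign of the azimuthal step per protofilament.
  The default −1 makes a decoration that follows the lateral stagger rise
  clockwise when viewed from the plus end, which the handedness estimator
  reports as a left-handed spiral. The sign is a package convention chosen
  to reproduce the left-handed geometry of lumenal spirals without
  committing to any particular EM display convention; flipping it mirrors
  the lattice and flips the reported handedness, which is covered by a
  test.

Tubulin monomers are emulated by anisotropic ellipsoidal clouds of carbon
pseudo-atoms (`build_dimer_template()`). The three cloud standard
deviations are distinct (9, 6, and ~11 Angstrom) so that after placement
the radial, tangential and longitudinal principal directions of a dimer
are all well separated — the plane fits below depend on that. The template
is rotated exactly into its principal frame, so its long axis is along z
by construction, and each pseudo-atom is its own residue so residue counts
track atom counts.

What the generator deliberately does **not** emulate: chemically realistic
tubulin coordinates, the inner/outer junction architecture of the doublet
(the B tubule is a partial arc of a tangent cylinder carrying only labels,
rise and stagger), lattice accommodation or flexibility, and density-space
features. Tests passing on synthetic lattices therefore demonstrate that
the estimators recover the geometry they are defined on; they do not
demonstrate robustness to conformational heterogeneity of real models,
which is why the annotation accepts an explicit chain map for deposited
structures.

## MIP decorations

`mip_decoration()` describes a MIP class: a lateral-interface mode (rods
bridging two adjacent protofilaments, the striation/spiral geometry) and a
longitudinal-filament mode (rods running along single protofilaments, the
SAXO-like geometry). Key parameters:

* `periodicity` — axial repeat, an integer multiple of the dimer rise
  (default one rise, 8 nm).
* `tilt` — angle between the rod axis and the plane of the two flanking
  dimers, default 51.5 degrees, the midpoint of the 50–53 degree range
  reported for SPACA9-class MIPs.
* `length` (45 Angstrom) and `n_atoms` (24) — rod marker geometry. Eight
  of the atoms form a thin symmetric sheath so the rod is non-collinear
  without moving its centroid or principal axis; the sheath basis is
  anchored to the lattice frame so that all copies are exact lattice images
  of each other.
* `inset` — radial inward displacement of the anchor from the flanking
  dimer midpoint (default 15 Angstrom, which leaves the rod nestled
  against the lumenal wall).

The generator refuses to decorate the seam: a lateral-interface MIP
recognizes the homotypic alpha–alpha / beta–beta lateral contacts, which do
not occur there. `pf_span = "all_non_seam"` on a closed 13-protofilament
tube therefore yields 12 copies per repeat, and an arc over protofilaments
B02–B05 yields 3 — the two copy-count invariants the test suite pins down.

Placement defines ground truth *in terms of the same plane definition the
estimator uses* (below): the rod is placed at the requested tilt relative
to the least-squares plane of the actual flanking pseudo-atom clouds, so
parameter recovery is exact rather than approximate, and any later change
to either side of the definition will break the round-trip test.

## Annotation

`annotate_lattice()` reconstructs the lattice bookkeeping from coordinates
alone:

1. **Classification.** Chains with at least `min_tubulin_res` residues
   (default 300; real tubulins have ~440) are tubulin, smaller chains are
   MIPs grouped by residue name. An explicit JSON chain map overrides this
   for deposited models.
2. **Axis.** The principal direction of tubulin chain centers, refined by
   nearest-neighbor bond directions. The refinement matters: because the
   seam's stagger sawtooth correlates axial offset with azimuth, the raw
   principal direction of a short lattice is biased by several degrees,
   while nearest-neighbor bonds (which are longitudinal, 4 nm, shorter
   than any lateral spacing) are exactly axial.
3. **Protofilament clustering.** Chains are clustered by azimuth about the
   axis using a circular gap statistic. The cluster count is chosen at the
   *first* large drop (ratio > 8) in the sorted circular gaps rather than
   the largest drop: the alpha and beta clouds of a pseudo-dimer sit at
   slightly different azimuths, and the largest-drop rule would split each
   protofilament into its two monomer columns.
4. **Indices and classes.** Within each protofilament, monomers are sorted
   axially; dimers pair each monomer of the leading class with the next
   monomer toward the plus end. Numbering follows chain labels when they
   encode it; otherwise it starts just after the seam and increases with
   azimuth, and the printed annotation states which origin was used —
   protofilament numbering conventions differ between publications, so the
   report always says what it did.
5. **Seam.** For each adjacent-protofilament interface, each monomer's
   nearest lateral neighbor is classified homotypic or heterotypic; the
   unique predominantly heterotypic interface is the seam. The threshold is
   an inclusive 50% because the last monomer of a short protofilament has
   no lateral partner toward the plus end, halving the census; a tube with
   zero or several heterotypic interfaces is reported (with the
   per-interface fractions) rather than silently assigned.

## Estimators

* `dimer_spacings()` — Euclidean distances between mass centers of
  consecutive dimers in a protofilament; n dimers give n−1 measurements.
  Mass centers use standard atomic masses; on all-carbon synthetic clouds
  mass and geometric weighting coincide exactly.
* `interprotofilament_angle()` — the rotation angle
  `acos((tr(R) − 1)/2)` of the Kabsch superposition mapping a dimer onto
  its lateral neighbor at the matched axial level, atoms paired by residue
  correspondence (CA atoms when present, all atoms otherwise — the atom
  choice the original descriptor leaves open). On an ideal closed
  N-protofilament tube this equals 360/N at every interface including the
  seam, which serves as a closed-form oracle.
* `tilt_angle()` — the "plane of the two tubulin dimers" is interpreted as
  the least-squares plane over *all* atoms of both dimers (normal =
  smallest-variance principal direction); the MIP long axis is its
  largest-variance principal direction; tilt = 90° − angle(axis, normal),
  folded into [0, 90]. The all-atom plane was chosen over a 4-point
  monomer-center plane because it is unambiguous and robust to how dimers
  are subdivided.
* `shrake_rupley_sasa()` / `interface_area()` — standard Shrake–Rupley
  quadrature (Fibonacci sphere points, default 960; probe 1.4 Angstrom;
  vdW radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, default 1.70
  with a warning) implemented in C++, and the PISA interface convention
  `A_int = (SASA(A) + SASA(B) − SASA(A∪B)) / 2`. Single-sphere and
  two-sphere spherical-cap closed forms bound the quadrature error in the
  tests (<1% and <2%). Hydrogens, when present, carry their own radius;
  the default radii set is heavy-atom oriented and differences from other
  radii sets are on the order of a few percent of the area.
* `axial_periodicity()` — per azimuthal column of copies, consecutive
  axial spacings; the median over all columns (median, not mean, so one
  missing copy cannot shift the estimate), reported in nm.
* `spiral_handedness()` — for each azimuthally adjacent pair of copy
  columns, the closest-in-z copy pair gives a local dz/dphi; the median
  slope's sign, viewed from the plus end, is left (negative), right
  (positive), or none when the rise per step is below 0.5 Angstrom (a
  flat ring).
* `copies_per_repeat()` — copies are indexed by repeat within each column
  (columns share the repeat set, so the window follows the spiral), and
  the best-covered repeat is counted; edge repeats may be truncated.
* `mip_pairwise_rmsd()` — each copy's anchor alpha-tubulin is the alpha
  with the largest buried interface area (ties within 5% resolve to the
  lower protofilament, then lower axial index; when no candidate shows
  real burial, as for idealized rods, the nearest alpha is used — the
  same lattice-relative choice for every copy). Copy j's anchor is
  superposed onto copy i's and the transform applied to copy j before the
  RMSD.

All descriptors are invariant to rigid-body transforms of the model, which
is tested with a random rotation plus translation at a tolerance of 1e-3
of each unit.

## Seam-register realignment

Microtubule particles refined as independent classes end up offset from a
common seam register by the pseudo-helical ambiguities: rotations by
multiples of 360/n_pf about the helical axis and axial shifts by one
tubulin monomer (4 nm at the default rise). `apply_register_correction()`
post-composes each particle's orientation matrix with the rotation by
`delta_phi` about the reference helical axis and shifts its origin by
`delta_shift` along the particle-frame image of that axis, then re-expresses
the result as Euler angles.

The Euler convention is fixed and documented: intrinsic Z-Y-Z,
`R = Rz(rot) · Ry(tilt) · Rz(psi)`, angles in degrees, tilt in [0, 180],
rot and psi in (−180, 180], the gimbal case `tilt = 0` resolved by placing
all in-plane rotation into psi. A silent convention mismatch is the main
failure mode of any such tool, so the conversion is exercised by a
round-trip property over hundreds of random triplets at 1e-9 and by a
composition (group-property) check. Under this convention a rotation about
the reference axis lands in psi; the correction axis is a per-run
parameter (default the reference helical axis, z) because subtomogram and
single-particle workflows orient their references differently. The shift
quantum is parameterized as `monomer_len = dimer_rise / 2` rather than
hard-coded at 40 Angstrom.

The scramble/recover harness builds a uniform orientation table, applies
known per-class offsets (k·360/13, m·40 Angstrom), realigns with the
negated corrections, and requires the residual rotation of every particle
to be below 1e-4 degrees. When corrections must be *estimated* rather than
known, choosing the reference class is out of scope of the correction math;
the CLI applies whatever corrections it is given, and the natural choice —
the most populated class — is left to the caller.

## Problem sizes and numerical choices

The test suite and acceptance checks run entirely on generated lattices.
Default generator conditions (used for the headline copy-count and
periodicity checks) are the canonical ones above with 440 pseudo-atoms per
monomer and six dimer repeats — a 48-nm column, the repeat length within
which six dimers yield five spacing measurements per protofilament. The
parameter-recovery sweep runs the full factorial grid n_pf ∈ {11…15} ×
rise ∈ {78…84} Angstrom × tilt ∈ {0, 30, 51.5, 75}° × periodicity ∈
{1, 2, 6} rises (420 lattices) at a reduced template density of 40 atoms
per monomer, a size at which every fit in the chain is still
over-determined by an order of magnitude; recovery tolerances are 0.1
Angstrom on rise, 0.1° on interprotofilament angle, 0.5° on tilt, exact
periodicity multiples and exact copy counts, with the seam found at the
generated interface in every cell.

Tie-breaks are uniform across the package: lowest protofilament index,
then lowest axial index. Degenerate inputs (single chains, collinear atom
sets, single-copy decorations, open arcs asked for a seam) raise errors
that name the violated precondition rather than returning placeholders.

## Limitations

* The annotation's automatic tubulin/MIP split is a residue-count
  heuristic; deposited models with unusual chain subdivisions need the
  chain-map override, and tubulin isotype calling is explicitly out of
  scope.
* The B tubule of the synthetic doublet is a labeled geometric stand-in;
  junction-dependent analyses cannot be validated against it.
* Interface areas depend on the vdW radii set; values computed here are
  comparable between models analyzed here, and agreement with other
  implementations is expected only to within a few percent.
* The deposited-model reproduction mode consumes PDB/mmCIF files the user
  supplies; no downloading is performed by the package.
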