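---
title: "Methods: orientation, contacts and PIP2 clustering at a model membrane"
author: "membmode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation, contacts and PIP2 clustering at a model membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`membmode` analyses coordinate trajectories of a membrane-proximal protein
kinase interacting with a PIP-containing bilayer. Its five analysis surfaces
are:

1. **Orientation** — least-squares superposition onto a reference pose, the
   per-frame pair (R~zz~, d~z~), the normalized orientation--distance density
   map, bound-state detection and binding-mode classification.
2. **Contacts** — per-residue, per-lipid-species contact frequencies at a
   distance cutoff, and intramolecular (juxtamembrane vs kinase) contact
   frequencies.
3. **Clustering** — per-frame interacting-lipid counts, Gaussian fits to the
   count distribution, per-lipid residence times, and species-resolved
   lateral diffusion from the mean squared displacement.
4. **Assembly** — rigid-body placement of domain poses onto shared anchor
   frames and inter-domain centre-of-mass distances.
5. **A synthetic Brownian-dynamics generator** that produces encounter
   trajectories with planted ground truth, so every stage above is testable
   without molecular-dynamics input.

The package never runs molecular dynamics, never infers chemistry (species
and headgroup identity always come from a user-supplied map), and works in
nm/ns units with the membrane normal fixed to the z axis.

# The orientation model

For each frame the protein selection is fitted onto a reference pose (by
default its own first-frame coordinates; the map's meaning is relative to
this choice, so any consistent reference is valid). The fit is the classic
SVD-based least-squares rigid superposition with the determinant sign
correction that excludes reflections. Three quantities are recorded per
frame:

* **R~zz~** — the zz element of the fitted rotation: +1 when the protein has
  the reference orientation about the membrane normal, -1 when flipped.
* **d~z~** — the absolute z separation of the protein and membrane centres
  of mass, minimum-image wrapped.
* **d** — the full 3-D COM separation, carried alongside because published
  encounter plots sometimes show the 3-D distance; the density map can be
  built on either, default d~z~.

The density map bins (R~zz~, d~z~) into a normalized 2-D histogram
$\rho$ and reports $\Delta D = \rho / \rho_0$ with $\rho_0$ the global
maximum bin probability, so $\sum \rho = 1$ and $\max \Delta D = 1$ by
construction. Default bin widths are 0.05 in R~zz~ and 0.1 nm in distance —
fine enough to separate the two binding modes without empty-bin noise at the
sampling depths used here.

**Bound state.** A frame is membrane-bound when d~z~ ≤ 5.0 nm, the upper
edge of the 4--5 nm COM-separation band that marks a stable
kinase--membrane interaction; intervals shorter than `min_dwell = 10` frames
are discarded to suppress grazing contacts.

**Binding modes.** Mode 1 engages the membrane through the kinase N-lobe
only (activation loop exposed); mode 2 through both lobes (activation loop
masked). Because published mode assignments are defined by lobe engagement
rather than by printed R~zz~ windows, classification here is contact-based:
a bound frame is MODE1 when the N-lobe has headgroup contacts within 0.8 nm
and C-lobe contacts stay at or below `clobe_contact_threshold = 0.25` times
the N-lobe count (tolerating incidental single-bead grazing), MODE2 when the
C-lobe reaches the one-bead contact floor. A bound frame in which neither
lobe touches (e.g. a tether-suspended pose) keeps the UNBOUND label. The
dominant mode is the majority label over bound frames.

# Contacts

A contact is a target particle (by default a lipid headgroup bead) within
0.8 nm minimum-image distance of any particle of a protein residue;
counting is per target particle. Profiles are time-averaged and normalized
**per species by the maximum over residues**, so the top residue of each
species sits at 1. The normalization denominator behind published
bar-height figures is not stated anywhere we could find; max-over-residues
is this package's documented choice and is scale-invariant (tests assert
idempotence and invariance under count rescaling). Pair pruning uses a
z-slab prefilter around the target span rather than a cell list — with the
membrane normal fixed to z this removes almost all pairs and provably
changes no result (tests compare against an all-pairs 27-image brute
force).

# Clustering statistics

* **Interacting-lipid counts** are per molecule: a lipid counts once per
  frame however many of its headgroup beads fall inside the cutoff.
  Distribution fits are by moments (mean, sd) — stable for small samples —
  and by default restricted to membrane-bound frames, since published count
  distributions describe the bound state; a flag pools all frames.
* **Residence times** are maximal interaction runs per lipid, merging gaps
  up to `gap_tolerance = 1` frame; a lipid is *persistent* when its longest
  dwell covers ≥ 50% of the analysed frames, otherwise *transient*. Both
  thresholds are exposed. At the generator's default attraction strengths
  recruited lipids exchange on the tens-of-ns scale, so the persistent label
  is rare on synthetic output; the dwell logic itself is exercised by
  hand-enumerated patterns in the tests.
* **Lateral diffusion** comes from the ensemble 2-D MSD of headgroup beads,
  unwrapped by accumulating minimum-image frame-to-frame displacements
  (exact while per-frame steps stay below half the box). D is fitted on
  MSD = 4Dt over lags between 10% and 50% of the maximum lag — below that
  window single-frame noise dominates, above it too few independent
  segments remain. The fit is **through the origin with 1/t² weights**
  (MSD(0) = 0 exactly, and the MSD sampling variance grows roughly as t²),
  which at the package's reference problem size (500 lipids × 1000 steps)
  keeps planted-coefficient recovery within 10% where an ordinary
  least-squares line with intercept does not reliably.

# The synthetic generator

The generator is an overdamped Brownian-dynamics toy, not a physical
membrane model. Its purpose is to *plant* the qualitative structure the
analyses must detect: diffusive encounter, two orientational binding modes
driven by charged patches, tether-enhanced binding, and attraction-driven
local PIP2 enrichment.

**Geometry.** Lipids are 2-D diffusers; each carries an upper headgroup bead
at z = +2 nm, a tail bead at 0 and a lower-leaflet bead at -2 nm sharing its
xy position, so the membrane COM sits exactly at z = 0 and a protein pressed
onto the headgroup plane shows d~z~ ≈ 4.6 nm — inside the 4--5 nm bound
band. The protein is a rigid body of two fused 40-bead spherical shells
(lobe radius 1.1 nm): residues 601--640 form the N-lobe with the P1 beads
(609/615/617) nearest the body -z pole and P2 (629/633/638/639) just
off-pole; 641--680 form the C-lobe with a 4-bead "C-face" patch on its +x
side; a JM-anchor bead sits beyond the N-lobe pole (residue 590). The
C-face is the generator's stand-in for the secondary (mode 2) interface:
real kinases expose basic residues on both lobes, which is why
aspartate-substituted patch mutants still bind — only differently.

**Dynamics.** Every degree of freedom moves by
$\sqrt{2 D \Delta t}\,\xi + (D/k_BT) F \Delta t$ per step (kT = 1). Patch
beads attract headgroups through a truncated cosine-ramped well of depth
$\epsilon\,w(\text{species})$ (default ε = 6 kT) vanishing at
`interaction_range = 1.4` nm; forces act laterally on lipids and as
force-plus-torque on the rigid body. Rotational diffusion composes a random
small rotation each step. The headgroup plane and box top reflect. A single
seeded RNG stream with a fixed draw order makes identical parameters
bit-identical.

**Default study conditions** (chosen once, during design, so that binding
occurs within desk-scale step counts): 14 × 14 × 18 nm box, 300 lipids at
90:5:5 PC:PS:PIP2 (the reference membrane; a PIP3 variant would use
83:15:2 PC:PS:PIP3), equal planted lateral D of 0.05 nm²/ns for all species
— so any PIP2 slowdown measured downstream is an emergent consequence of
binding, not an input — protein D 0.08 nm²/ns translational and 0.12 rad²/ns
rotational, 24 000 steps of 0.05 ns (1.2 µs) saved every 100 steps, start
height 8 nm, random start orientation. Patch weights (wild type): P1
PS 0.25 / PIP2 1.0, P2 PS 0.25 / PIP2 0.6, C-face PS 0.2 / PIP2 0.4. The
C-face well is deliberately shallow enough that mode-2 capture is
*reversible* on the simulated timescale: a wild-type protein caught C-face
first can escape and rebind via the deeper P1/P2 face, which both keeps
mode 1 dominant across ensembles (4 of 5 bound replicas in the reference
runs, with occasional mode-2-dominant replicas — a realistic minority) and
reproduces the observed mode-2 → mode-1 transitions. Named scenarios
(`patch_scenario()`): `p1_only` plants single-patch engagement with a
broad moderate P1 well (PS 0.5, PIP2 1.2; a very deep narrow well instead
torques the body into tilted, C-lobe-touching poses), and `mutant_p1p2`
flips the sign of both basic patches, emulating aspartate substitution.

**Ground truth** records per saved frame: d~z~, the bound flag, the engaged
patch (a patch is "engaged" when it carries positive net weight *and* has a
bead within interaction range of a headgroup — geometric proximity of a
repulsive mutant patch does not count), and the ids of lipids within range
of any patch bead.

**What the generator does not emulate:** MARTINI-level energetics, membrane
undulations or thickness fluctuations, explicit solvent, protein
flexibility, lipid--lipid electrostatics, and µs-scale kinetics.
Consequently, passing tests show that the *analysis pipeline* detects
planted encounter/mode/enrichment structure correctly; they do not validate
any force field, and quantitative values (e.g. mean interacting-PIP2 counts
of roughly 2--5 here versus 5--9 in published µs-scale coarse-grained
ensembles of the real receptor) agree only in direction and order of
magnitude.

# Numerical choices and degenerate inputs

* Coordinates are stored in nm; PDB is converted from/to Å at the boundary.
* Orthorhombic boxes only; triclinic input raises an explicit error.
* Superposition requires ≥ 3 non-collinear points (second singular value
  > 1e-12) and rejects degenerate geometry; returned rotations are
  orthogonal with det +1 to 1e-8 on all tested inputs.
* COM calculations are mass-weighted by default (uniform 72 amu beads when
  the input format carries no masses, making them centroids); bead-count
  weighting is available via a flag since published methods do not state
  which was used.
* All-zero contact species stay zero under normalization (no 0/0).
* An empty selection is a warning at construction and an error where it
  cannot be meaningful (COM, orientation series).
* `classify_bound` with an empty series returns zero intervals; the
  dominant mode over zero bound frames is reported as UNBOUND.
* Largest-remainder rounding makes generator species counts deterministic;
  ties break in PC, PS, PIP2, PIP3 order.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to give stable statistics on a single CPU: ensembles of five
1.2 µs replicas per condition (~300 lipids, 81 protein beads, 241 saved
frames each) for the qualitative contrasts, 500-lipid × 1000-step
membrane-only runs (three seeds) for planted-diffusion recovery, and
10--1000-particle constructed fixtures for the exact oracles
(27-image minimum-image distances, all-pairs contact counts, applied rigid
transforms, hand-enumerated dwell patterns).

# Known limitations

* XTC trajectories are not read or written; supported formats are GRO,
  (multi-model) PDB, DCD (read, via bio3d) and a deterministic plain-text
  dialect whose write→read→write cycle is byte-identical.
* The bilayer is a flat plane at fixed z; curved or undulating membranes
  would need a local-normal fit the package does not attempt.
* Mode classification depends on domain labels supplied by the user's
  domain map; mislabelled lobes silently produce mislabelled modes.
* The Gaussian count fit is a moment fit; it does not test normality.
* Assembled composites report steric clashes (pairs closer than 0.3 nm)
  but never resolve them — placement is purely rigid.
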