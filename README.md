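# membmode

Trajectory analysis for peripheral membrane binding of a protein kinase:
how a kinase domain docks onto a PIP2-containing bilayer, which of its two
orientational binding modes it uses, which residues touch which lipids, and
how the protein reorganizes the anionic lipids around itself.

The package is aimed at people analysing coarse-grained or atomistic
membrane-protein simulations (or Brownian-dynamics models of them) who need
the standard battery of protein–lipid observables as tested, scriptable R
functions rather than one-off analysis scripts.

## What it computes

Given a topology (with a user-supplied lipid species map and protein domain
map) and a multi-frame trajectory, `membmode` computes:

- **Orientation–distance density maps.** Each frame's protein is fitted onto
  a reference pose by least-squares rigid superposition (SVD/Kabsch, no
  reflections); the zz element of the fitted rotation *R*<sub>zz</sub> and
  the protein–membrane COM separation *d*<sub>z</sub> are binned into a
  normalized 2-D histogram ρ, reported as ΔD(*R*<sub>zz</sub>, *d*<sub>z</sub>) = ρ/ρ₀
  with ρ₀ the global maximum (so Σρ = 1, max ΔD = 1).
- **Bound-state detection** — maximal runs of frames with
  *d*<sub>z</sub> ≤ 5 nm (the upper edge of the 4–5 nm stable-interaction
  band) lasting at least a minimum dwell.
- **Binding-mode classification** — mode 1 (N-lobe engages the membrane,
  activation loop exposed) vs mode 2 (both lobes engage, activation loop
  masked), decided per frame from lobe↔headgroup contacts at a 0.8 nm
  cutoff.
- **Contact profiles** — per-residue, per-species interacting-particle
  counts within 0.8 nm, normalized per species to the top residue; plus
  juxtamembrane↔kinase intramolecular contact frequencies.
- **PIP2 clustering statistics** — per-frame interacting-lipid counts
  (molecule-level), Gaussian (moment) fits of the count distribution over
  bound frames, per-lipid residence times with persistent/transient labels,
  and species-resolved lateral diffusion coefficients from the 2-D MSD
  (MSD = 4Dt) with periodic-boundary unwrapping.
- **Rigid-body assembly** — superposition of domain poses onto shared
  anchor frames (e.g. a TM helix) and kinase–kinase COM separations of the
  composite models, with clash reporting.
- **Synthetic data** — `simulate_encounter()` is an overdamped
  Brownian-dynamics generator (rigid two-lobe protein with charged patches
  P1 = {609, 615, 617} and P2 = {629, 633, 638, 639}, optional
  juxtamembrane tether, 2-D diffusing PC/PS/PIP lipids at 90:5:5) that
  produces trajectories with planted ground truth: bound intervals, engaged
  patch per frame, recruited lipid ids and planted diffusion coefficients.
  Sign-flipped patch weights emulate aspartate-substitution mutants.

## Worked example

One config drives simulate → orient → contacts → clusters → diffusion:

```r
library(membmode)
report <- run_pipeline(list(
  output_dir = "results/pipeline",
  simulate = TRUE,
  synthetic = list(seed = 106,
                   tether = list(enabled = TRUE, k = 2, anchor = NULL,
                                 rest = 1.0)),
  analysis = list(cutoff = 0.8, bound_threshold = 5.0, min_dwell = 10,
                  species = "PIP2", diffusion_species = c("PC", "PIP2"))
))
```

With this seed the run prints (`analysis/06_pipeline_report.R`):

```
bound fraction: 0.87
dominant mode:  MODE1
interacting PIP2: 5.66 +/- 2.08
lateral D (nm^2/ns): PC 0.047, PIP2 0.024
```

Meaning: the tethered kinase is membrane-bound for 87% of frames, binds in
the productive N-lobe-down mode 1, keeps on average 5.7 PIP2 molecules
within 0.8 nm of its surface while bound, and those recruited PIP2 diffuse
about half as fast as the bulk PC — the local PIP2 nanocluster that the
bound protein maintains. Full per-stage tables (orientation series, ΔD
grid, contact profile, count series, residence labels, MSD curves) are
written under `output_dir`.

The numbered scripts under `analysis/` run the full study: `01` simulates
wild-type, patch-mutant and tethered ensembles (5 replicas each), `02`
classifies binding modes (wild type: mode 1 dominant in 4/5 bound
replicas; mutants: mode 2 or unbound), `03` locates the top PIP2-contact
residues (609, 615, 629, 617, 633 — the basic patches), `04` quantifies
tether-enhanced PIP2 recruitment (bound-frame mean 4.2 vs 2.1 untethered)
and slowed PIP2 diffusion, `05` builds the close/far dimer composites
(6 vs 10 nm kinase–kinase separations), `06` is the pipeline run above.

## Layout

```
R/                  package code (topology/IO, orient, contacts, clusters,
                    assembly, synth generator, pipeline)
analysis/           numbered study drivers writing results/ tables
scripts/acceptance.R  headline-quantity recomputation (JSON out)
tests/testthat/     oracle-based unit, property and acceptance tests
vignettes/          methods vignette (model, parameters, limitations)
```
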