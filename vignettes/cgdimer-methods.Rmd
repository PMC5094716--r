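---
title: "Methods: ensemble analysis of coarse-grained receptor dimerization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble analysis of coarse-grained receptor dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgdimer)
```

`cgdimer` analyses ensembles of coarse-grained two-receptor membrane
trajectories: it detects dimers, classifies their configurations,
estimates binding kinetics and thermodynamics, measures lateral diffusion
and quantifies cholesterol contacts. This vignette records the models,
conventions and numerical choices behind each stage, and what the
synthetic-data validation does and does not demonstrate.

## The dimerization criterion

Two receptors count as a dimer while the non-bonded interaction energy
between their transmembrane (TM) domains is below −50 kJ/mol. The energy
is the sum over TM bead pairs within 1.2 nm (minimum image) of

* a 12-6 Lennard-Jones term, force-shifted so that force and potential
  vanish smoothly at the 1.2 nm cutoff with a switch region starting at
  0.9 nm, and
* a Coulomb term with relative permittivity 15, shifted over 0–1.2 nm.

The shift coefficients are obtained by solving the two boundary
conditions (force and force derivative zero at the cutoff) for each
inverse power; the unit tests check the resulting polynomial against the
published closed forms and the continuity at 1.2 nm numerically. A plain
truncated-and-shifted scheme is available behind `scheme = "truncate"`:
the classification thresholds are two orders of magnitude coarser than
the difference between the schemes, so the choice does not affect state
assignment, but the shift-function form is the default because it matches
the simulation engine convention the energies come from.

State classification is a hysteresis automaton: bound when the energy
first drops below −50 kJ/mol, unbound (one dissociation event) when it
next exceeds −1 kJ/mol; frames between the thresholds keep the previous
state, and frames before the first crossing are unbound by definition.
Energies are classified instantaneously; `smooth_width` applies an
optional running mean first (default off — the instantaneous reading is
the stricter and simpler convention, and the two-threshold hysteresis
already suppresses flicker).

## Orientation angles

Each receptor carries an internal frame: origin at the center of mass of
its TM backbone beads, z along the membrane normal (toward the
extracellular side), x pointing from the origin through the mean position
of the TM5 and TM6 beads, y completing a right-handed triad. The
relative configuration of a pair is then

* β — azimuth of the partner's origin in the reference frame,
* φ — rotation of the partner about its own z relative to the reference
  ("phase"),
* χ = (180° + β − φ) mod 360° — the angle under which the partner sees
  the reference.

The x convention is the one free choice, and it is pinned by a single
anchor: the symmetric TM5,6/TM5,6 face-to-face dimer must give
β = χ = 0. Angles increase counterclockwise viewed from the
extracellular side; this sign convention makes the two face-to-back
worked cases come out as (β = 0, χ = 180°) and (β = 180°, χ = 0°), which
the test suite asserts. Swapping reference and partner maps (β, χ) to
(χ, β); this and the exact χ identity are enforced as property tests on
random poses. Of the five angles a full rigid-body parameterization
would need, only β, φ, χ are computed — the out-of-plane tilts of the
pair axis are not part of the configuration analysis.

Helix tilts are the angle between the first principal axis of a
segment's beads and the membrane normal, folded into [0°, 90°]. The TM5
sub-segments default to residues 193–205 (upper) and 206–227 (lower);
both ranges are arguments, because the residue boundary of the upper
segment is reported inconsistently (192 vs 193) in the source material
the convention follows — the later start was chosen and the choice is
configurable.

## Configuration density and watershed segmentation

Orientation samples are taken over the final 50 ns of every run that is
bound at its last frame. The (β, χ) samples are smoothed with a
wrapped-Gaussian product kernel on the torus; image terms are added until
an extra layer changes no cell by more than 1e−12, and the field is
renormalized to unit mass. Kernel and bandwidth are not prescribed by the
method's source; the defaults are bandwidth 10° and a 360×360 grid
(1° cells), chosen because observed configuration basins are tens of
degrees wide — both are arguments, and the scaled-down analyses in the
test suite use 72–120 cells, which resolves the same basins at a fraction
of the cost.

Local maxima are cells strictly above their eight toroidal neighbors
with height at least `min_height_fraction` (default 0.05) of the global
maximum; the floor suppresses noise maxima in thinly sampled regions.
Equal-height plateau components count as one maximum (represented by
their lowest cell index) only if everything adjacent is strictly lower; a
constant field therefore has no maxima and cannot be segmented.

The watershed transform follows simulated immersion: cells sorted by
descending height (ties broken by cell index for determinism) are
assigned the label that is unique among their already-labeled
4-neighbors, or marked watershed when two or more labels meet. Cells left
unassigned by a pass that makes no progress are re-processed with a grown
neighborhood (4 → 8 → Chebyshev radius r+1). The torus topology is
honored throughout — neighborhoods wrap in both axes. Label spreading is
the probability mass inside each region; frames are assigned by their
containing cell, with watershed cells resolved to the nearest region by
toroidal distance (ties to the lower label id).

A brute-force steepest-ascent basin assignment serves as an independent
oracle. The two algorithms provably agree in basin interiors but draw
their common boundary with up to a cell or two of discretization offset,
and around near-degenerate saddles (two bumps almost merging) the
immersion boundary can wander several cells: the equivalence check
therefore compares cells away from the boundary zone, and the agreement
is evaluated over the cell population of several random smooth fields.

## Kinetics and thermodynamics

The rate constant assumes an irreversible first-order association: a run
is "dimerized" permanently after its first binding event. The monomer
fraction m(t) over the ensemble is evaluated on the frame grid after a
500 ns equilibration cut, and k is minus the ordinary-least-squares slope
of ln m(t) over the interval where m(t) > 0. OLS is the default because
the method's source does not state a regression scheme; the estimator
recovers a planted rate within ~1% at 400 runs.

The dissociation constant uses the equilibrium bookkeeping
K_D = (P₀/P₁)·c⦵/(N_Av·V): P₀ counts only monomer time that follows a
dissociation event (pre-binding search time is not equilibrium sampling),
pooled over runs at frame-stride resolution; censored terminal monomer
intervals are included. Both conventions bias P₀/P₁ — and hence |ΔG| —
downward in finite runs, which is why resulting free energies should be
read as lower bounds; the validation suite quantifies the bias on the
pure two-state process (a few percent once runs contain many
binding/unbinding alternations). ΔG = RT·ln K_D uses R = 8.314 J/mol/K
and T = 310 K. V, the volume of the protein-lipid double layer, is
accepted as an explicit input; the helper `double_layer_volume()` (box
area × measured bilayer thickness) is an approximation and labeled as
such.

## Lateral diffusion

Mean square displacements are ensemble- and time-origin-averaged over the
per-molecule xy center-of-mass tracks (all time origins at full stride;
this choice affects error bars, not means). Tracks are unwrapped from the
periodic box, and the center-of-mass track of the whole membrane-protein
system is subtracted first — with only two protein molecules, subtracting
their own mean instead would halve the protein MSD, so the system COM
must be used. D = slope/4 by least squares on the 5–20 ns lag window,
converted from nm²/ns to cm²/s (× 1e−5). The ensemble protocol excludes
runs that dimerized before 250 ns and analyses the initial 200 ns of the
rest.

## Cholesterol contacts and bilayer thickness

A cholesterol is bound when any of its 8 beads is within 0.62 nm (the
first solvation shell) of any protein bead; all protein beads are
eligible, not only TM residues (configurable). Per-residue occupancy and
mean contact times are computed over the 200–1000 ns window, discarding
initial construction-biased contacts. A contact interval ends at the
first frame without any cholesterol in range — the frame stride therefore
bounds the time resolution of contact durations; an optional
`gap_tolerance` closes short gaps. Intercalation counts cholesterols
bound to both receptors in the same frame, with the probability of at
least one interfacial cholesterol reported over the final 50 ns.

Global bilayer thickness is the distance between the density maxima of
the upper- and lower-leaflet reference beads (PO4; GL1 for
monoacylglycerol membranes) along z, using 0.02 nm bins smoothed by a
3-bin running mean (bin and smoothing are package choices). Local
thickness averages, per frame, the mean z separation of reference beads
within 1 nm of the protein; leaflets are assigned per frame by the sign
of z relative to the membrane center, so rare flip-flopping reference
beads are handled frame by frame.

## The synthetic ensemble generator

The generator produces the statistical structure the analysis assumes,
not the physics that creates it: it is a kinematic two-state model with
geometric placement, built so that every estimator can be checked against
exact ground truth.

* **Receptor template.** One backbone bead per TM residue; each of the
  seven helices is a vertical rod on a ring of radius 1.2 nm spanning
  3 nm of membrane, at a fixed angular sector (counterclockwise
  TM6-TM7-TM1-TM2-TM3-TM4-TM5, so the TM5/TM6 boundary is the x
  reference). The ring is rotated once at construction so the
  bead-count-weighted TM5/TM6 mean direction lies exactly on azimuth 0,
  aligning generator and analysis conventions for any helix ranges.
* **Placement.** Receptor pairs start with a 3.5 nm circumscribed-sphere
  gap and independent uniform z-rotations. The default box is
  15 × 15 × 9 nm: the gap constraint must also hold under the
  rectangular minimum-image convention, which requires the initial
  center distance to stay below half the box edge.
* **Kinetics.** Binding is a homogeneous Poisson event at the configured
  association rate, so that rate *is* the ensemble's first-order rate
  constant analytically — the property the rate-fit validation needs.
  (A contact-gated hazard was considered and rejected: it has no
  closed-form ensemble rate.) Unbinding is Poisson at the dissociation
  rate; on unbinding the partner is displaced beyond interaction range.
  Defaults (2.74e−4 ns⁻¹ association, 8.47e−6 ns⁻¹ dissociation over
  3 µs runs) reproduce the pure-phospholipid assay's observed kinetics
  scale, where roughly half the runs dimerize within 3 µs.
* **Dimer modes.** On binding, a mode is drawn from the configured
  (β, χ, weight) list — by default five modes at the template's
  helix-interface angles with weights 0.26/0.24/0.20/0.13/0.17 — and the
  partner is placed with per-frame wrapped-normal angular jitter
  (default 7°) around the mode. The center distance is re-solved in
  closed form every bound frame so the closest bead pair sits exactly at
  the 0.5 nm contact gap whatever the jittered interface orientation.
* **Energy bridge.** Bead non-bonded parameters start from a single LJ
  type with a 3 kJ/mol well at 0.5 nm and are rescaled once per topology
  so that the reference face-to-face contact evaluates to −150 kJ/mol.
  This guarantees the contract between generator and criterion: bound
  frames classify below −50 kJ/mol (with margin for jitter) and fully
  separated frames are exactly 0, for templates of any size. Free
  receptors carry a hard-core exclusion so unbound frames never generate
  spurious contacts.
* **Membrane.** Two flat leaflets of PO4 beads at ±thickness/2 with
  0.1 nm Gaussian z-jitter (so density maxima are well defined);
  cholesterol is an 8-bead vertical rod with the ROH bead at the head.
  Lipids diffuse as independent Brownian walkers at their configured D
  (Δr ~ Normal(0, 2DΔt) per axis). Designated hotspot cholesterols
  follow a two-state Markov chain with the configured stationary
  occupancy (default 0.65) and mean contact time (6 ns); while in
  contact the rod is centered on the hotspot residue at a 0.45 nm
  lateral offset, and free cholesterols are excluded from a 0.9 nm shell
  around the receptors so the planted occupancy is exact. Optional
  intercalated cholesterols are placed midway between bound receptors.
* **Determinism.** Every run draws from a stream seeded by
  (master seed, run id), so any run is reproducible in isolation and
  identical seeds give bitwise-identical trajectories.

What passing the synthetic validation shows: the estimators recover
planted rates within 10%, equilibrium ratios within 20% (at ≥50
dissociation events), diffusion coefficients within 15%, mode centers
within 10° and hotspot occupancies within 5 percentage points, under the
statistical structure described above. What it does not show: behavior
under real-trajectory features the generator deliberately omits —
membrane undulations, protein flexibility and rotational diffusion,
correlated lipid motion, force-field-specific energetics, anomalous
(sub-diffusive) lipid transport. Conclusions about real systems still
require the usual convergence checks on real data.

## Problem sizes and degenerate inputs

The shipped tests and validation run on scaled-down instances chosen as
the smallest sizes at which each statistical criterion is meaningful:
reduced receptor templates (4 residues per helix) wherever geometry
conventions, not receptor size, are under test; 400 runs × 3 µs at 10 ns
stride for the rate constant; 50 runs × 3 µs at 5 ns stride (≥100
dissociation events) for P₀/P₁; 500 runs × 80 ns for mode recovery on a
120-cell grid; 72-cell grids for the watershed oracle; ~600 lipids ×
250 ns for diffusion; 1 µs single runs for occupancy. The full-size
template (217 TM residues) is used where the contract depends on it,
e.g. the ≥5-contact-pair guarantee of freshly placed dimers.

Degenerate inputs are defined errors, not silent results: empty energy
series, inverted thresholds, zero dimer time, non-positive volumes or
K_D, unimodal (single-leaflet) density profiles, degenerate/collinear
bead geometry, windows outside the run, and boxes too small for the
placement gap all raise typed errors with messages naming the offending
quantity; runs that end unbound are excluded (not errored) from the
final-window orientation sample, and a run shorter than the window is
flagged truncated.
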