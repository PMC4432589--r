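---
title: "Quantifying transporter state transitions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transporter state transitions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmgeom)
```

# The problem

MFS transporters move substrates by alternating access: the binding site,
wedged between an N-terminal and a C-terminal six-helix bundle, is exposed
to one membrane side at a time as the bundles rock against each other. For
the nitrate/nitrite antiporter NarK, the transition from the occluded to
the inward-open state is carried almost entirely by the C bundle: TM7,
TM10 and TM11 bend around conserved glycine hinges (G268; G363/G365/G367;
G408/G414/G417/G418), breaking three stacked layers of inter-bundle
contacts (C1–C3) that seal the cytoplasmic pathway, and loosening the
substrate site enough to release the anion. `tmgeom` turns each clause of
that description into a measurable number.

This vignette records how each quantity is defined, which defaults were
chosen where the underlying publications leave the procedure open, and
what the synthetic-fixture tests do and do not establish.

# Superposition and RMSD

`kabsch_fit()` solves the least-squares rigid superposition by SVD of the
3×3 covariance of the centred point sets. Reflections are removed by
flipping the sign of the smallest singular vector whenever the determinant
is negative, so the returned matrix is always a proper rotation. The fit
is unweighted: published Cα RMSDs for these structures are plain
unweighted figures, and occupancy/B-factor weighting would change them.

Atoms are paired by (chain, residue number, insertion code, atom name)
over the residues resolved in *both* structures; dropped atoms are counted
and reported. Published pairwise RMSDs are often quoted over a trimmed
subset without the trimming rule being stated (e.g. "435 Cα atoms" for a
~460-residue protein). `rmsd_between(trim_to = n)` provides a transparent
rule — iteratively discard the worst-deviating pair and refit — and the
achieved pair count is always reported next to the RMSD rather than being
forced to a quoted value.

Degenerate inputs (point-like or collinear sets, for which the rotation is
not determined) are rejected with an error rather than silently returning
one of the infinitely many minimisers.

# Helix bend angles

A helix half is reduced to an axis by a running mean over a 4-residue
window (about one turn, which cancels the helical wobble of the Cα trace)
followed by the principal direction of the smoothed points. The axis is
oriented N→C so that angles between axes are unambiguous in [0°, 180°].
An anisotropy ratio below 2 between the first two singular values flags an
axis that is not meaningfully linear (`flat` in the result).

`bend_angle()` first superposes the alternate state onto the reference
over a *global* selection — by default the N-bundle Cα set (residues
1–233), the half that does not move between these states — then fits axes
to the moving-half Cα run in each state and reports the angle between
them. Direction ("away from the centre", "towards the periphery") is
deliberately not folded into the angle: it is reported separately as
`radial_shift`, the signed change in distance between the moving-half
centroid and the whole-molecule Cα centroid.

The default segment table places the TM10 and TM11 cytosolic halves at
T369–L380 and A399–F409 — the only residue-exact cytosolic ranges
published for these helices (they define the gate order parameter) — and
the TM7 half at 269–278, immediately cytosolic of the G268 hinge. Helix
half boundaries behind published bend angles are otherwise unstated, which
is why the segment table is ordinary data the user can rescan; recovered
angles shift by a degree or two under reasonable boundary changes, and the
downstream tolerance for such angles should be a few degrees.

**What the tests establish.** Planted hinge bends of 5–60° on ideal
helices are recovered within 1° noise-free and monotonically. Under 0.3 Å
iid Gaussian Cα noise on the measured conformation, a *single*
realisation of the recovered angle scatters with a standard deviation near
1° (twelve smoothed axis points over a ~20 Å half), so the 2° criterion is
asserted on the mean over 20 noise replicates: it bounds the estimator's
bias. A single noisy measurement of a short helix half is simply not a 2°
measurement, and the tests do not pretend otherwise.

# Gate layers

Contact detection uses standard heavy-atom crystallographic heuristics:
4.5 Å for hydrophobic contacts, 3.5 Å donor–acceptor distance for
hydrogen bonds (N/O/S donors to N/O acceptors), 3.5 Å per leg for
water-mediated bridges (one hit per bridging water, recording the closest
partner on each side). No angular hydrogen-bond criterion is applied:
crystal structures at 2.3–2.4 Å resolution carry no hydrogens, and
inventing hydrogen positions would add a model where the data have none.
This is a documented limitation — a heavy-atom pair at 3.4 Å with hopeless
geometry will still be counted.

The default layer table transcribes the text-named C1–C3 interactions
(hydrophobic packing F370/L407 × F147/M151/L167 plus the A404–A148
water bridge; the C2 packing and R378/A400 hydrogen bonds; the C3
P20/E21 × D392/E393/M396 contacts). A layer counts as *formed* when at
least half of its listed residue pairs have a hit of the required kind —
published gate descriptions are qualitative ("formed" vs "none of the
interactions is formed"), so the rule is deliberately simple and the
threshold is an argument. The gate is *closed* only when every layer is
formed; unresolved layers (missing residues) count as not formed and are
flagged.

# Binding-site geometry and pocket volume

Site distances are direct coordinate measurements with explicit
conventions: site A reports NH1→O and NH2→O separately *and* their
minimum, and the single published site-A figure is compared against the
minimum, because the text does not name which guanidinium nitrogen carries
the quoted distance. Site B is the minimum Y263 OH → ligand O distance;
the protein-only Y263–R305–S366 network is reported even for apo
structures (ligand fields become `NA`). The F147/F267 sandwich is
characterised by ring-centroid distance and the interplanar angle between
least-squares plane normals, folded into [0°, 90°].

`pocket_volume()` measures the probe-excluded cavity: grid points within
(vdW + probe) of any occluding heavy atom are blocked (radii C 1.70,
N 1.55, O 1.52, S 1.80 Å; ligand and waters excluded from the occluding
set so the pocket they occupy is measured), and a 6-connected flood fill
from the seed counts the connected free voxels. Defaults: 0.25 Å spacing,
1.4 Å water probe, a 12 Å box centred on the seed. Two numerical choices
matter:

* **Half-offset voxel centres.** Voxel centres sit at
  `-bounds + (i - ½)·spacing` (midpoint rule). With centres on lattice
  multiples, centres fall *exactly on* symmetric molecular surfaces and
  boundary voxels flip inclusion between grid resolutions: on the analytic
  test cavity the 0.5 Å→0.25 Å volume change was ~14 % with an aligned
  grid and is <1 % with the midpoint rule, which also recovers the 64 ų
  analytic cube exactly.
* **Seed validity.** A seed inside an atom's *bare* vdW sphere is a user
  error and raises; a seed excluded only by probe inflation means the
  probe fits nowhere, and the volume is legitimately 0. A fill that
  reaches the bounding box is an *open* pocket: the truncated volume is
  returned with `open = TRUE` rather than pretending closure.

Published cavity volumes rarely state the algorithm, probe or boundary
definition, so agreement with a quoted volume should only ever be judged
at the ±15 % level; the package's own tests validate the implementation
against analytic fixtures and a direct-enumeration oracle instead.

# Trajectory statistics

`rmsd_series()` superposes every frame onto the reference over the fit
selection before measuring, so whole-body drift and tumbling do not
register. `rmsf()` uses a two-pass alignment (fit to frame 0, build the
time mean, refit to the mean) and reports the per-residue RMS deviation
from the time-mean positions. Published per-residue fluctuation plots are
ambiguous about whether the reference is the crystal structure or the
trajectory mean; both modes are implemented (`reference = "mean"` is the
default, being the standard definition of a fluctuation) and neither is
asserted to be "the" published convention.

The inter-bundle order parameter — the distance between the Cα centroids
of the TM4–TM5 cytosolic part (148–171) and the TM10–TM11 cytosolic parts
(369–380 ∪ 399–409) — is computed *without* any superposition: it is an
internal coordinate, invariant under per-frame rigid motion, which is what
makes it a clean open/closed coordinate. `crystal_reference_distances()`
evaluates the same functional on static structures to draw the reference
lines a trajectory is read against.

# The synthetic-data module

The generators state a small world with exactly known answers:

* `make_helix()` — ideal α-helix (1.5 Å rise, 100° twist, 2.3 Å Cα
  radius; textbook constants, overridable). A requested hinge bend is
  planted as an *exact* rigid rotation of the distal half about an axis
  through the hinge Cα, so the planted angle is the ground truth to
  machine precision. The optional backbone (N, C, O, CB on concentric
  helical curves) is geometric, not chemically valid.
* `make_two_bundle()` — two helix bundles whose chain-wise Cα centroids
  are placed at an exact separation (no sterics enforced).
* `make_cavity()` — a cubic shell of pseudo carbon atoms whose vdW surface
  lies exactly on the faces of the requested inner cube, so the probe-0
  enclosed volume is analytically `inner_side³`. Wall pitches above 1.2 Å
  would leak and are rejected.
* `make_trajectory()` — linear interpolation between two conformations,
  optionally restricted to a moving selection, plus iid Gaussian noise of
  stated σ applied after interpolation (never to the endpoints).
  Deterministic under its seed, without disturbing the caller's RNG.
* `plant_site()` — verbatim atom placement for planted hydrogen bonds,
  salt bridges and water bridges.

Every planted quantity is recovered by the corresponding analysis within
a stated tolerance, and the fixtures are routed through the real PDB I/O
path in at least one test. **What a green suite establishes:** the
geometry, pairing, fitting, counting and flood-fill machinery are correct
on inputs with known answers, including under rigid transforms and noise.
**What it does not establish:** agreement with any deposited structure's
published numbers (that requires the coordinates, which the test
environment cannot download), physical realism of the fixtures, or the
behaviour of the hydrogen-bond heuristics on genuinely ambiguous
crystallographic geometry.

# Degenerate inputs and error policy

Zero-atom selections, sub-minimal point sets (<3 for fitting, <4 for an
axis), collinear fits, mismatched trajectory rosters, malformed PDB
coordinate fields (reported with their line number), leaky cavity walls
and duplicate planted atoms are all hard errors. Per-segment and per-stage
failures inside tabulating calls (`bend_report()`,
`run_state_comparison()`) are caught and recorded in a status column or
error list instead, so one disordered helix does not cost the rest of the
report.

# Known limitations

* Heavy-atom contact criteria only; no angular hydrogen-bond term, no
  energetics.
* Pairing assumes the two inputs are the same protein (no sequence
  alignment); chain correspondence across crystal forms must be given
  explicitly via `chain_map`.
* The bend angle depends on the chosen half boundaries at the level of a
  degree or two; the boundaries are data, not code, for exactly this
  reason.
* Pocket volumes depend on probe, radii set and boundary convention;
  cross-tool comparisons are only meaningful at the ±10–15 % level.
* No binary trajectory formats; multi-model PDB is the interchange format.
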