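---
title: "Trajectory analysis of NBD dimer opening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis of NBD dimer opening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdtraj)
```

## The scientific problem

ABC transporters hydrolyse ATP at two composite active sites buried in the
interface of a nucleotide-binding-domain (NBD) sandwich dimer. Each site is
formed by the Walker A/B motifs of one monomer's *core* subdomain and the
LSGGQ signature (C-motif) of the other monomer's *helical* subdomain. A
central mechanistic question is whether, after hydrolysis, an empty site can
open far enough to exchange nucleotide while the dimer stays associated.
Molecular-dynamics simulations of an isolated NBD dimer address this by
watching whether the empty site opens by way of intrasubunit rotations
between the core and helical subdomains.

`nbdtraj` implements the analysis battery such a study needs, on top of
standard PDB/DCD trajectory I/O:

1. **Subdomain-resolved RMSD** against the starting structure, separating
   monomer-internal stability from intermonomer rearrangement.
2. **Active-site opening distances**: per frame, the distance between the
   geometric centres of the Cα atoms of a Walker A motif
   (residues 43–46, GKST in MJ0796 numbering) and the opposing C-motif
   (147–150, SGGQ).
3. **Essential dynamics**: PCA of the aligned Cα covariance,
   with self- and cross-run projections, subspace overlaps, and
   projection–distance correlations.
4. **Rigid-domain / hinge analysis**: partitioning the dimer into
   quasi-rigid domains between two conformers and describing each domain's
   motion as a screw transform (angle, hinge axis, pivot, pitch, centre
   displacement).
5. **A synthetic generator** that plants a known opening motion with
   Gaussian noise, so that every stage can be validated against closed-form
   ground truth without any trajectory download.

## Residue scheme

All selections derive from a configurable `residue_scheme()`. The defaults
are the MJ0796 numbering:

| region            | residues          | used for                         |
|-------------------|-------------------|----------------------------------|
| core              | 1–90, 164–228     | core RMSD, hinge domain work     |
| helical (RMSD)    | 94–111, 117–161   | helical RMSD                     |
| helical (domain)  | 94–161            | domain membership                |
| Q-loop            | 91–93             | assigned to neither subdomain    |
| Pro-loop          | 161–163           | assigned to neither subdomain    |
| α3-4 loop         | 112–116           | excluded from helical RMSD only  |
| C-terminal tail   | 229–235           | excluded from core RMSD          |
| Walker A centre   | 43–46 (GKST)      | opening-distance gauge           |
| C-motif centre    | 147–150 (SGGQ)    | opening-distance gauge           |
| D-loop residue    | 175               | trans-site contact check         |

Two helical selections are deliberately distinct: the α3-4 loop is highly
mobile and is excluded from the helical *RMSD* selection, but it still
belongs to the helical region for domain-membership purposes. The
C-terminal tail (a mobile, unstructured 7-residue stretch) is excluded from
the core RMSD selection. The scheme is overridable (including via the YAML
pipeline config), so the toolkit generalises to other NBDs; nothing
downstream hard-codes MJ0796 numbers.

## Geometry

**Superposition.** All fits are unweighted least-squares rigid
superpositions of Cα coordinates (Kabsch SVD solution with the
determinant correction that excludes reflections). Degenerate inputs
(fewer than 3 atoms, collinear point sets) are rejected. In tests the fit
is checked against a brute-force rotation-grid + simplex-refinement oracle
that knows nothing of the SVD algebra.

**RMSD series.** `rmsd_series(traj, fit_sel, calc_sel, reference)` fits
each frame over `fit_sel` and evaluates RMSD over `calc_sel`. The pipeline
uses self-fit for per-monomer and per-subdomain series (fit and compute on
the same selection) because their purpose is to measure *internal*
stability; a dimer-frame fit would fold intermonomer motion into them. The
caption-level convention for the published monomer panels does not state
this; self-fit is this package's documented choice. Smoothing uses a
trailing (not centred) moving window, the common spreadsheet convention,
default period 20 samples; output length is `n - period + 1`.

**Screw decomposition.** A proper rigid transform `x -> R x + t` is
reduced to: angle `acos((tr R - 1)/2)`; axis from the antisymmetric part
of `R` (switching to the symmetric part near 180° where the antisymmetric
part vanishes); pitch `t · axis`; and a pivot solving
`(I - R) p = t - pitch·axis` in the plane perpendicular to the axis. The
screw axis is a line, so any point on it solves that equation; the
reported pivot is made unique by choosing the point on the axis closest to
the domain centroid's projection. Below `angle_min` (default 1°) the axis
direction is numerically meaningless and is flagged undefined, while the
angle and the centre displacement are still reported. Axis sign is fixed
so the rotation about `+axis` is by a positive angle in (0°, 180°].

## Essential dynamics

`fit_pca()` aligns every frame of the selection to the reference (by
default the starting structure), assembles the 3N coordinate vectors,
and diagonalises their covariance about the trajectory mean. Choices that
matter:

* **Unweighted covariance over Cα atoms.** Mass weighting is nearly a
  constant factor for Cα-only selections (all carbons) and is not used.
* **Projections are deviations from the trajectory mean**, not from the
  alignment reference — the convention of the standard essential-dynamics
  tools. Consequently the self-projection variance of mode *i* equals its
  eigenvalue exactly.
* **Mode sign is arbitrary** and fixed by making the largest-magnitude
  component positive; projection functions expose `flip_sign` because
  comparing runs sometimes reads better with one series negated.
* **Eigen-solver**: full symmetric eigendecomposition. For NBD-dimer-sized
  problems (~460 Cα atoms, 3N ≈ 1400) this takes about a second; an
  independent SVD of the centred data matrix reproduces eigenvalues to
  1e-8 in the tests.
* **Subsampling**: PCA and projections default to frames at 75 ps
  intervals (`pca_interval_ps`), applied everywhere in the pipeline for
  consistency between the fitted model and the projected series; a config
  flag disables subsampling.

**Subspace overlap** between a mode and the leading *k* modes of another
run's model is the root-sum-of-squares of inner products — at `k = 1` just
`|cos θ|`. The root-sum-of-squares form is the standard definition and is
what reduces correctly to containment (1) and orthogonality (0).

**Cross-projection and re-projection.** Projecting run B's trajectory onto
run A's mode 1 needs only atom correspondence. One subtlety: structures
built *in the model's aligned frame* (e.g. by `interpolate_mode()`) are
re-projected exactly only with `align = FALSE`, because a fresh Kabsch fit
of `mean + p·mode` onto the reference is not exactly the identity. With
re-alignment the round-trip is approximate (typically to ~1e-3 of the
projection value); without it, it is exact to machine precision. Both are
tested.

## Hinge analysis

Domain-motion analyses in this field have mostly been produced with
closed-source tools whose partitioning internals (a slow partitioning
mode governed by a percentage tolerance) are not published. This package
defines its own normative, deterministic partitioning with the same
intent — classify residues into groups that move coherently, with a
tolerance-scaled admission radius:

1. Fit conformer `y` onto `x` over the full selection; let `D` be the
   mean per-residue Cα displacement after this fit.
2. Rank all 12-residue sequence windows by internal fit RMSD.
3. Grow the best fully-unassigned window to a fixed point: fit the
   current domain, admit unassigned residues displaced ≤ `tolerance × D`
   after that fit, drop members exceeding it.
4. Accept domains of ≥ 15 residues; leftovers are hinge/flexible.

The tolerance (default 0.4, i.e. 40%) is interpreted as a fraction of
`D`. Seed window length (12) and the minimum domain size (15) are smaller
than any subdomain of interest and larger than loop wobble; both are
exposed as arguments. Identical conformers (`D = 0`) are a single rigid
domain. Domains may be sequence-discontinuous, exactly as real subdomain
motions demand. Note that `D` is *not* the raw magnitude of the planted
motion: a global fit between two rigid bodies absorbs much of their
relative rotation, so `D` scales with the bodies' internal extent. The
partition is therefore most reliable when rigid bodies have lever arms
(distance from hinge, body radius) large relative to the noise, which is
the regime of NBD subdomains.

**Reporting frame.** `hinge_report()` aligns `y` onto `x` over the
*largest* domain (tie broken by lowest residue number) and reports every
domain's screw relative to that frame, ordering domains by decreasing
angle. This is the convention of domain-motion analysis generally: an
identity pair reports a single domain at 0°, and a fixed-block/rotated-block
pair reports the planted angle for the moving block, not an arbitrary
split between the two. `analyse_mode_extremes()` composes the PCA and
hinge stages: the minimum- and maximum-projection frames of a mode are the
conformer pair, with the minimum-projection structure as reference.

## The synthetic generator

`build_toy_dimer()` lays each monomer out as two globular Cα blobs (core
and helical) with the Walker A and C-motif residues placed explicitly at
the interface; chain B is chain A rotated 180° about the dimer axis, so
the two composite-site distances start exactly equal. Named pseudo-atoms
(C-motif serine OG, glutamine OE1/NE2, nucleotide β-phosphate oxygens and
ribose O2') are planted at known offsets — in particular the serine
OG sits exactly 3.0 Å from the nearest β-phosphate oxygen — because the
contact observables only need named atoms at known positions, not
stereochemistry.

`generate_opening_trajectory()` rotates the apo monomer's core block
(core residues plus the attached C-terminal tail) about a hinge axis
through the core/helical junction by θ(t), linear by default (a sigmoid
switch schedule is available because real openings are switch-like), and
adds iid Gaussian noise (default σ = 0.2 Å) to every atom of every frame,
7.5 ps apart. Defaults: θ_max = 20°, 500 frames. The ground truth carries
the hinge geometry, the schedule, and the closed-form expected apo-site
opening, so noise-free runs must reproduce the prediction to 1e-9 Å.
`generate_control_trajectory()` is the matching no-motion control;
`generate_rigid_pair()` plants arbitrary sets of block screws for the
hinge fixtures. All randomness flows from a single integer seed; the same
seed regenerates trajectories bit-identically.

What the generator does *not* emulate: physical force-field dynamics,
solvent, realistic local geometry (bond lengths between consecutive toy
Cα positions are not 3.8 Å), anharmonic loop dynamics, or correlated
thermal motion. Passing tests therefore demonstrate the correctness of
the analysis machinery on data with the assumed statistical structure
(rigid collective motion + isotropic noise), not that any particular
biological system behaves this way.

## Pipeline

`run_analysis(analysis_config(...))` emits, per run, the RMSD panels
(with moving averages), the two opening-distance series, PCA fractions
and mode-1 projections, cross-projections onto the reference run's PC1
with subspace overlaps and projection–distance correlations, the hinge
report on the reference run's mode-1 extremes (JSON plus PDB pseudo-atom
axes), and a 10-model interpolation PDB along PC1 — all hashed into a
manifest with a log. Every stage failure aborts with the stage name
(exit code 3 from the CLI wrapper; 2 for configuration errors). The
analysis itself is deterministic: rerunning a config reproduces the CSV
outputs byte-identically.

Problem sizes used in the shipped tests and the acceptance script: toy
dimers of ~470 Cα atoms, trajectories of 150–500 frames (subsampled to
30–75 ps for PCA), 20-seed Monte-Carlo for the noisy partition check.

## Known limitations

* The partition tolerance semantics ("fraction of mean global-fit
  displacement") are this package's normative definition; the original
  closed-source tool's exact meaning is unrecoverable, so residue-exact
  agreement with published domain lists is not guaranteed or claimed.
* PDB support covers wwPDB v3.3 ATOM/HETATM records, altLoc filtering
  (keep blank/'A', warn and drop others) and multi-model files; insertion
  codes are rejected rather than renumbered. XTC/TRR/PSF are out of scope.
* The D-loop–phosphate contact check (`dloop_phosphate_distance()`)
  requires the user to supply the crystal structure (e.g. PDB entry 3TIF);
  the package does not redistribute PDB entries.
* Near-degenerate PCA eigenvalues make individual mode directions
  unstable (only the spanned subspace is meaningful); subspace overlap
  against PCs 1–2 is the robust comparison and is what the pipeline
  reports.
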