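# nbdtraj

Trajectory analysis of ABC transporter nucleotide-binding-domain (NBD)
dimers: subdomain-resolved RMSD, active-site opening distances,
essential-dynamics PCA with cross-run projection and subspace overlap, and
rigid-domain/screw-axis hinge decomposition — with a synthetic trajectory
generator that plants known rigid-body openings so every stage is testable
against closed-form ground truth.

## Who this is for

ABC transporters hydrolyse ATP at two composite sites at the interface of
an NBD sandwich dimer: the Walker A/B motifs of one monomer's *core*
subdomain face the LSGGQ C-motif of the other monomer's *helical*
subdomain. MD studies of this system ask whether an empty (apo) site can
open — by intrasubunit core/helical rotations — while the dimer stays
associated. `nbdtraj` packages the analysis battery those studies run on
their trajectories, for anyone with a topology PDB and a DCD or
multi-model-PDB trajectory of an NBD dimer (defaults use the MJ0796
numbering; the residue scheme is fully configurable).

## The quantities it computes

* **Opening distance** of each composite site: per frame, the Euclidean
  distance between the geometric centres of the Cα atoms of a Walker A
  motif (residues 43–46) and the opposing monomer's C-motif (147–150) —
  the per-site gauge of active-site closure.
* **RMSD panels** against the starting structure: dimer-wide (all-Cα
  fit) versus per-monomer and per-subdomain self-fit series, separating
  internal stability from intermonomer rearrangement; trailing moving
  averages (default period 20).
* **Essential dynamics**: eigendecomposition of the aligned Cα
  covariance. For a 3N mode set, projections are signed amplitudes (Å)
  of each frame's deviation from the trajectory mean along a mode;
  cross-run projection and the subspace overlap
  `sqrt(sum_j (v·m_j)^2)` quantify how much one run samples another
  run's dominant motion; Pearson correlation connects a mode's projection
  to the opening distance.
* **Hinge analysis**: a deterministic seeded-growth partition of the
  residues into quasi-rigid domains between two conformers (tolerance =
  0.4 × the mean post-fit displacement, by default), then each domain's
  motion as a screw transform — angle, hinge axis, pivot point, pitch,
  and the distance moved by the domain's geometric centre — reported
  relative to the largest (reference) domain.

## Worked example

A synthetic opening run: the apo monomer's core subdomain rotates 20°
about a planted hinge over 500 frames (7.5 ps apart, σ = 0.2 Å noise),
and the analysis recovers the motion end to end.

```r
library(nbdtraj)

dimer <- build_toy_dimer()
opening_distances(dimer)
#> site_nuc site_apo
#>        8        8

run <- generate_opening_trajectory(dimer, theta_max = 20, n_frames = 500,
                                   noise_sigma = 0.2, seed = 1)
traj <- subsample(run$trajectory, 75)   # 75 ps sampling, as for PCA

model <- fit_pca(traj)
model
#> <ed_pca> 470 atoms, 50 frames
#>   top eigenvalue fractions: PC1 83.9%, PC2 0.5%, PC3 0.5%

proj <- project_trajectory(traj, model, 1)
open <- opening_distance_series(traj)
projection_distance_correlation(proj, open$site_apo)
#> [1] -0.9925655

analyse_mode_extremes(traj, model, 1)
#> <hinge_report> 2 domains, global rmsd 3.596 A (reference domain 2)
#>   domain 1 [B:1-67, B:69-82, B:84-90, B:164-235]: <screw_transform> 19.73 deg
#>     about (-0.013, 0.001, -1.000), pivot (0.8, 13.2, -0.3), pitch -0.01 A,
#>     centre moved 5.08 A
#>   domain 2 [A:..., B:91-163]: <screw_transform> 0.000 deg (axis undefined),
#>     centre moved 0.00 A
```

Reading the output: the two sites start equidistant (8 Å, the toy dimer is
C2-symmetric); one PCA mode carries ~84% of the Cα fluctuation; its
projection tracks the apo-site opening with |r| ≈ 0.99 (mode sign is
arbitrary, hence the negative sign); and the hinge analysis of the mode's
extreme frames recovers the planted 20° rotation of the chain-B core block
about the planted z-axis hinge, with the rest of the dimer as the static
reference domain.

The same battery runs from a config over any set of labelled runs:

```r
cfg <- analysis_config(dimer,
                       list(open = run$trajectory,
                            ctrl = generate_control_trajectory(dimer, seed = 2)$trajectory),
                       reference_run = "open", output_dir = "out")
res <- run_analysis(cfg)
```

which writes the full CSV/JSON/PDB bundle (RMSD panels, opening series,
PCA fractions, cross-projections, overlap and correlation tables, hinge
report, mode-1 interpolation PDB, hashed manifest). A thin CLI wrapper
over the same function lives at `inst/scripts/run_analysis.R`
(`--config analysis.yaml --seed 1`).

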