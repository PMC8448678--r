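# assemblyED

Essential dynamics and trajectory analysis for tubulin assemblies, in R.

Microtubules are built from αβ-tubulin heterodimers stacked into
protofilaments (PFs).  How a microtubule moves — bending, growth,
catastrophe — traces back to a handful of collective internal motions of the
heterodimer: wobbling toward the microtubule axis, rotation about the common
monomer axis, and compression along it.  This package implements the
trajectory-analysis layer used to extract and diagnose those motions from
molecular-dynamics trajectories of assemblies, for structural-bioinformatics
and biophysics users who have trajectories (or want synthetic ground truth)
rather than a simulation engine:

* **Superposition** — Kabsch least-squares fitting (proper rotations only)
  and RMSD time series with per-subunit mean ± sd aggregation.
* **Concatenated-subunit PCA** — trajectories of all equivalent heterodimers
  are superposed on a common reference and pooled into one ensemble; the
  population covariance C of the pooled coordinate rows is
  eigendecomposed, `C v_k = λ_k v_k`, with mode fractions
  `λ_k / Σ λ`, accumulated dynamics, Cattell-kink detection on the scree
  spectrum, centered projections, inner-product (overlap) matrices
  `|v_i · u_j|` with RMSIP, and a convergence curve of split-subset mode
  overlap versus the number N of concatenated subunits.
* **Filament geometry** — per-frame bending angles between the
  monomer-center-of-mass axes of adjacent heterodimers along each PF,
  classified by lattice position (plus/minus end, central, corners), with
  1° histograms; an intra-dimer variant is included.
* **Dynamics observables** — the self part of the van Hove function
  G_s(r, t), the self-intermediate scattering function
  `F_s(q,t) = ⟨sin(qΔr)/(qΔr)⟩` (for free diffusion
  `F_s = exp(−q²Dt)`), curve-ordering reports, and axis-resolved mass
  density profiles.
* **Synthetic assembly generator** — toy sheets and 13-PF microtubule walls
  with planted orthonormal modes of prescribed eigenvalue fractions,
  isotropic noise, imposed bends, and Brownian tracer fixtures, so every
  analysis is testable by parameter recovery.
* **Pipeline** — `run_pipeline()` executes a configuration-driven analysis
  graph (YAML or list) with seeded reproducibility, CSV outputs and JSON
  metadata; `demo_pipeline()` runs it end to end on a bundled synthetic
  sheet.  A thin CLI wrapper lives in `inst/scripts/assembly-ed`.

Units are nm and ps; q values in nm⁻¹ (`q_angstrom_to_nm(1.26)` → 12.6).

## Worked example

Plant three orthonormal heterodimer modes at eigenvalue fractions
0.15/0.10/0.08 in a 3×3 PF sheet, then recover them with the pipeline:

```r
library(assemblyED)

lat  <- build_lattice(lattice_spec(3, 6, "sheet", atoms_per_monomer = 20))
plan <- plant_variance_fractions(c(0.15, 0.10, 0.08), n_coords = 120)
dirs <- random_orthonormal_modes(120, 3,
                                 reference = dimer_reference(lat, 1, "all"),
                                 seed = 7)
pm   <- planted_modes(dirs, plan$variances, plan$noise_variance)
traj <- generate_trajectory(lat, pm, n_frames = 2000, seed = 7)

subs  <- lapply(lat$topology$dimers$id, function(d)
  extract_subunit(traj, lat$topology, d, "all"))
ens   <- concatenate_subunits(subs, dimer_reference(lat, 1, "all"))
modes <- covariance_modes(ens)

head(scree(modes), 4)
#>   mode_index eigenvalue fraction accumulated
#> 1          1    0.07435  0.15445       0.154
#> 2          2    0.04879  0.10135       0.256
#> 3          3    0.04029  0.08371       0.340
#> 4          4    0.00331  0.00688       0.346

cattell_kink(scree(modes))[1]
#> [1] 3

abs(crossprod(modes$vectors[, 1:3], pm$directions))
#>       [,1]  [,2]  [,3]
#> [1,] 1.000 0.001 0.019
#> [2,] 0.000 0.998 0.058
#> [3,] 0.019 0.058 0.998
```

Reading the output: the first three eigenvalue fractions (15.4 %, 10.1 %,
8.4 %) recover the planted 15/10/8 % within sampling error; the scree kink
at mode 3 marks the boundary between the planted (essential) subspace and
the isotropic noise floor; and the near-identity inner-product matrix shows
each recovered eigenvector aligned with its planted direction.

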