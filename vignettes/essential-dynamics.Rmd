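---
title: "Essential dynamics of tubulin assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential dynamics of tubulin assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyED)
```

## The problem

Microtubules are hollow cylinders built from αβ-tubulin heterodimers arranged
in protofilaments (PFs).  Their mechanics — growth, shrinkage, bending,
catastrophe — are believed to be encoded largely in the internal motions of
the individual heterodimer: a wobbling of the dimer toward the microtubule
axis, a rotation about the common monomer axis, and a compression along that
axis.  Molecular-dynamics trajectories of assemblies (a small PF sheet, a
13-PF microtubule wall fragment) are the natural observations, but a single
heterodimer trajectory samples conformational space poorly.  This package
implements the analysis layer for such trajectories:

* rigid-body (Kabsch) superposition and RMSD series;
* *concatenated-subunit* principal component analysis: the trajectories of
  all equivalent heterodimers are superposed on a common reference and pooled
  into one long ensemble before the covariance analysis, trading subunit
  identity for sampling depth;
* mode diagnostics: scree fractions and accumulated dynamics, the Cattell
  kink, inner-product (overlap) matrices and RMSIP, and a subset-split
  convergence curve of mode overlap versus concatenation depth;
* protofilament bending angles between the monomer-COM axes of adjacent
  heterodimers, classified by lattice position (plus end, minus end,
  central, corner);
* single-particle dynamics observables: the self part of the van Hove
  function, the self-intermediate scattering function (ISF), and
  axis-resolved mass density profiles;
* a synthetic trajectory generator that plants known modes, noise and bends
  into toy lattices, so that every stage above is testable by parameter
  recovery without running molecular dynamics.

Internal units are nm and ps throughout.  Scattering vectors are stored in
nm⁻¹; `q_angstrom_to_nm()` converts the Å⁻¹ values common in the scattering
literature (1.26 Å⁻¹ → 12.6 nm⁻¹) at the boundary.

## The model behind the generator

The generator is a geometry-plus-noise model, not a physics simulator: no
force field, no energies, no thermostat.  `build_lattice()` places straight
heterodimers (alpha→beta axis along +z, toward the plus end) on a sheet or a
cylinder.  Each monomer is a rigid cloud of pseudo-atoms on a deterministic
spherical spiral, so any four atoms are non-collinear and all monomers share
one shape; atom 1 sits at the monomer center and is flagged as the Cα, the
first half of the atoms as backbone.  Defaults follow tubulin dimensions: a
4 nm monomer spacing, and for cylinders a 13-PF circumference with a 3-start
helical rise (3 × spacing / n_PF per PF).  Dimer layers at the lattice ends
are classified `plus_end` / `minus_end`, interior layers `central`, and on
cylinders the dimers where the helical lattice terminates are the
`plus_corner` / `minus_corner`.

`generate_trajectory()` displaces each dimer independently in its local
frame:

$$x(f) = x_\mathrm{ref} + \sum_k a_k(f)\, v_k + \eta(f),$$

with mutually orthonormal mode directions $v_k$ (3M-dimensional, M atoms per
dimer), amplitudes $a_k \sim \mathcal N(0, \lambda_k)$ drawn independently
per frame, and isotropic Gaussian noise $\eta$ of per-coordinate variance
$\sigma^2$.  Two design choices matter:

* **Rigid-subspace orthogonality.**  Planted directions are sampled
  orthogonal to the 6-dimensional rigid-body subspace (translations and
  infinitesimal rotations) of the reference dimer
  (`random_orthonormal_modes(..., reference =)`).  Least-squares
  superposition in the analysis projects out approximately that subspace;
  planting inside it would let the fit silently absorb signal.  The
  isotropic noise does have rigid components, of which the fit removes about
  $6\sigma^2$ of trace — a sub-percent effect at the default sizes, visible
  as recovered fractions sitting a few tenths of a percentage point above
  their targets.
* **Fraction planting.**  Because the noise adds $\sigma^2$ along *every*
  direction, the covariance eigenvalue of a planted mode is
  $\lambda_k + \sigma^2$ and the trace is
  $\sum_k \lambda_k + 3M\sigma^2$.  `plant_variance_fractions()` solves for
  $\lambda_k$ and $\sigma^2$ so the eigenvalue *fractions* equal requested
  targets exactly in expectation.  The default study conditions plant
  fractions 0.15/0.10/0.08 at total trace 0.5 nm² — a per-atom RMSF near
  0.1 nm, typical of backbone fluctuations, with the first-mode fraction at
  the level reported for tubulin sheets — and 5000 frames at a 10 ps
  sampling interval.

Amplitudes are i.i.d. per frame by default because PCA is insensitive to
frame order; an optional Ornstein–Uhlenbeck correlation time (`ou_tau`, in
frames) provides temporal memory for time-dependent observables, with the
stationary variance held at $\lambda_k$.

Bends are applied as rigid rotations of whole dimers about a lateral axis
through the inter-dimer interface below the dimer, optionally ramped over
the first frames.  Rotating a dimer by θ relative to a straight neighbour
produces an inter-dimer bending angle of exactly θ, which is what makes bend
recovery an exact, closed-form test.  Note that bending *consecutive* layers
by the same angle about parallel axes cancels in the relative angle; plans
that should show a lattice-wide bend therefore rotate alternate layers.

What the generator does **not** emulate: anharmonicity and multi-well
landscapes, inter-dimer dynamical coupling (each dimer fluctuates
independently), solvent structure, and any nucleotide-state dependence.
Passing recovery tests therefore demonstrates the *analysis* is correct and
well-conditioned, not that real microtubule trajectories satisfy the model.

## Numerical conventions

* **Covariance.**  Population convention (divide by N), non-mass-weighted by
  default; mass weighting is a flag (`covariance_modes(mass_weighted =,
  masses =)`).  Eigenvector signs are fixed by making the largest-magnitude
  component positive, so overlap matrices and projections are reproducible
  across platforms.
* **Superposition reference.**  `concatenate_subunits()` uses a two-pass
  fit: frames are fitted to the supplied reference, then refitted to the
  resulting mean structure, removing reference bias from the covariance.
  `refine_reference = FALSE` restores the single-pass behaviour;
  RMSD series use the first frame as reference by default, matching the
  usual "RMSD to initial structure" presentation.
* **Cattell kink.**  The criterion is operationalized as local maxima of the
  discrete second difference of log-eigenvalues; a kink at mode m means
  modes 1..m precede the drop (for eigenvalues 10, 9, 8, 1, 0.9, 0.8 the
  kink is at mode 3).  An exactly geometric spectrum has a constant second
  difference and reports no kink.  Eigenvalues below 1e-12 (degrees of
  freedom removed by superposition) are ignored.
* **Projections.**  Centered dot products in nm; the population variance of
  the projections onto mode i equals eigenvalue i to machine precision, an
  identity the tests assert at 1e-6 relative.  Projection histograms use
  edges symmetric about zero (default 100 bins spanning ±4σ), flag empty
  bins as NA — distinct from log10(1) = 0 — and clamp outliers into the edge
  bins so counts are conserved.
* **Convergence curve.**  For each N, disjoint random subsets of N subunits
  are drawn, a mode set built from each, and the absolute first-mode inner
  product and k-mode RMSIP recorded; means and standard errors over
  replicates are reported.  Seeded and reproducible.
* **ISF.**  Isotropic sinc kernel,
  $F_s(q,t) = \langle \sin(q\,\Delta r)/(q\,\Delta r)\rangle$, exact for
  isotropic systems and exactly 1 at t = 0; a series expansion below
  $q\Delta r < 10^{-8}$ avoids 0/0.  Time origins default to every frame in
  the first half of the trajectory (configurable stride).  Global
  center-of-mass motion is *not* removed.  The van Hove self part is
  histogrammed over particles and origins and normalized so
  $\sum_r G_s\,4\pi r^2\,\Delta r = 1$; `isf_from_van_hove()` provides the
  independent sinc-quadrature route used to cross-validate `isf_self()`.
* **Bending angles.**  Unsigned, `acos` of the clamped dot product, in
  [0°, 180°].  The inter-dimer variant (axes of adjacent dimers on one PF)
  is the default; the intra-dimer variant measures the angle between the
  alpha-half and beta-half axes within one dimer, each half's axis running
  between the centers of mass of its two terminal atom groups.  Histograms
  use 1° bins; per-frame records are the default, with `aggregate = "pair"`
  for time-averaged per-pair angles.
* **Degenerate inputs.**  Collinear point sets are rejected by the Kabsch
  fit; zero-variance ensembles yield all-zero eigenvalues without error; a
  PF with a single dimer yields no inter-dimer pairs (empty, not an error);
  truncated trajectory frames are rejected naming the frame index.

## Worked example

A miniature end-to-end run on the synthetic sheet (sizes kept small here;
the package's acceptance script runs the full study conditions):

```{r example, eval = FALSE}
lat <- build_lattice(lattice_spec(3, 6, "sheet", atoms_per_monomer = 20))
plan <- plant_variance_fractions(c(0.15, 0.10, 0.08), n_coords = 120)
dirs <- random_orthonormal_modes(120, 3,
                                 reference = dimer_reference(lat, 1, "all"),
                                 seed = 7)
pm <- planted_modes(dirs, plan$variances, plan$noise_variance)
traj <- generate_trajectory(lat, pm, n_frames = 2000, seed = 7)

subs <- lapply(lat$topology$dimers$id, function(d)
  extract_subunit(traj, lat$topology, d, "all"))
ens <- concatenate_subunits(subs, dimer_reference(lat, 1, "all"))
modes <- covariance_modes(ens)
head(scree(modes), 4)
cattell_kink(scree(modes))[1]
abs(crossprod(modes$vectors[, 1:3], pm$directions))
```

The same graph, configuration-driven, with CSV/JSON outputs and a report:

```{r pipeline, eval = FALSE}
report <- demo_pipeline("demo-out", seed = 1)
str(report$pca)
```

## Problem sizes and testing strategy

The test suite and the acceptance script use deliberately chosen study
conditions: the 3×3 sheet (9 dimers, 20 atoms per monomer, 5000 frames,
45 000 concatenated rows) for mode recovery; 78 subunits of 60 frames each
for the convergence experiment (few frames per subunit keep the
single-subunit mode estimate ambiguous, so the growth of overlap with N is
informative); 10⁴ Brownian tracers at D = 0.01 nm²/ps for the scattering
closed forms, probing $q^2 D t$ up to ≈ 3 at q = 12.6 nm⁻¹.  Every expected
value in the tests is either an arithmetic closed form, an independently
computed oracle (brute-force covariance assembly, quaternion grid-search
superposition, direct projection of generated displacements, the
free-diffusion Gaussian), or an established external implementation used
solely as a cross-check.

## Known limitations

* The generator's dimers fluctuate independently; collective lattice modes,
  inter-dimer couplings and solvent-mediated effects are out of scope.
* ISF relaxation of *bounded* internal motion does not decay to zero; fully
  decaying curves require diffusive degrees of freedom, as in the tracer
  fixture.  The relaxation-lag report is therefore meaningful only for
  systems with net diffusion.
* Trajectory exchange is via multi-frame XYZ + JSON assembly maps; binary MD
  formats are intentionally unsupported in the core (adapters can wrap the
  same reader contract).
* PDB output carries coordinates only at PDB precision (10⁻³ Å); the JSON
  map is the authoritative topology carrier.
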