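---
title: "Methods: quantifying loop flexibility from ensembles and trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying loop flexibility from ensembles and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models, conventions and numerical choices behind
each analysis in `flexscan`, and what the synthetic validation does and does
not establish about real data.

## The flexibility model

All four analyses rest on one assumption: the molecule fluctuates
approximately harmonically about a single mean conformation. Independent
crystallographic copies of a molecule are then draws from that fluctuation
(filtered through lattice contacts), trajectory frames are a dense sample
of it, and the three observables — per-residue RMSD to the mean,
temperature factors, and quasiharmonic mode amplitudes — are three views of
the same underlying displacement covariance. The package's synthetic
generators sample from exactly this model, which is why planted parameters
are recoverable and why agreement on synthetic data validates the
estimators rather than the harmonic assumption itself.

## Ensemble superposition

`kabsch()` computes the optimal proper rotation by SVD of the weighted
cross-covariance of centred coordinates, with the standard sign correction
on the smallest singular value so reflections are never returned. Inputs
with fewer than three points, or with collinear points (second singular
value below `1e-8` of the largest), are rejected: the rotation is not
unique there.

`ensemble_superpose()` alternates fitting every conformer to the current
mean and recomputing the mean, starting from the first conformer in input
order. This is plain unweighted iterative least squares. Maximum-likelihood
superposition (as implemented in Theseus) down-weights variable regions and
can shift peak values slightly; we chose least squares because it is
deterministic, dependency-free and transparent, and because per-residue
peak positions are insensitive to the choice. Convergence is declared when
no mean atom moves more than `tol = 1e-6` Å between iterations (default
`max_iter = 100`); non-convergence returns a flagged result with a warning
rather than an error, so partial diagnostics remain inspectable.

The per-residue profile is `sqrt(mean over conformers of |x − x̄|²)` per
mapped Cα. Residues absent from any conformer simply drop out of the atom
map (they are never zero-filled), and known disordered stretches can be
excluded explicitly — the analysis of multiple crystal forms routinely
needs this.

One caveat worth stating: fitting removes six rigid-body degrees of
freedom, so ensemble RMSD and trajectory mean-square displacements are
deflated by roughly `6/(3N_atoms)` in aggregate, concentrated on the most
mobile atoms. For the 20–60-residue synthetic systems used in the tests
this is a few percent; recovery tolerances account for it.

## B-factor profiles

The conversion `B = (8/3)π²⟨u²⟩` links a mean-square displacement about the
mean position (Å²) to an isotropic temperature factor (Å²). "Main chain"
means N, Cα, C, O; Cα-only inputs fall back to Cα automatically.
Averaging over monomers happens on raw B **before** normalization, and
normalization uses the population (divide-by-n) standard deviation so the
normalized profile has mean 0 and variance exactly 1 — both choices matter
for comparability of experimental and theoretical profiles. Profile
similarity is reported as a Pearson correlation over the inner join of
residue numbers; at least three shared residues are required.

## Quasiharmonic analysis

The mass-weighted covariance is `C = (1/F) Σ_f y_f y_fᵀ` with
`y_f = M^{1/2}(x_f − x̄)` and `M^{1/2}` applying `√m_i` to each coordinate
of atom *i*. Two conventions are fixed here:

* **Rigid-body removal.** Frames are superposed to the iteratively
  converged trajectory mean on Cα atoms before the covariance is formed —
  the standard essential-dynamics preprocessing. Without it the six
  rigid-body modes dominate the spectrum.
* **Sampling interval.** Frames are subsampled toward a 5 ps target
  interval (`stride = round(5 / frame_interval)`), the customary
  quasiharmonic frame rate; an explicit `stride` overrides it.

Diagonalisation uses the symmetric eigensolver; asymmetry beyond `1e-8` is
an error, eigenvalues below zero by round-off are clamped to 0, and each
eigenvector's sign is fixed by making its largest-magnitude component
positive so outputs are bit-reproducible.

For mode *i* with eigenvalue λ (amu·Å²), the quasiharmonic frequency
satisfies `ω² = k_BT/λ`, so a harmonic oscillator excited `E = c·k_BT`
above its ground state turns at mass-weighted amplitude
`q = sqrt(2c)·√λ` — notably independent of temperature. With the
conventional `c = 2` (the "2kT" device for visualising a mode's reach)
this is `q = 2√λ`, and the Cartesian extremes are `x̄ ± M^{−1/2} v q`.
The temperature parameter (default 310 K) is retained in the interface
because the frequency itself, not just the turning points, depends on it.
The per-mode energy convention is our explicit choice; alternatives (e.g.
distributing 2kT over several modes) would shrink all amplitudes by a
common factor and change no direction cosines.

`loop_displacement_summary()` reduces a mode to one mean Cα displacement
vector per residue range and reports signed pairwise direction cosines:
positive for concerted motion, negative for opposing motion. This turns the
qualitative statement "loops open and close together" into a number.

## Solvent accessibility

`atom_asa()` is a direct Shrake–Rupley implementation: each atom's van der
Waals sphere is expanded by the probe radius (default 1.4 Å, a water
molecule), covered with `n_points` deterministic golden-spiral points
(default 960), and the accessible fraction is the share of points outside
every neighbour's expanded sphere. With 960 points the two-sphere
configuration agrees with the spherical-cap closed form to well under 2%
across all separations, doubling the point count moves totals by under 1%,
and rigid motions move totals by under 0.5% (per-atom values carry
somewhat larger sampling noise because the point grid is fixed in the
laboratory frame). The radii set is a fixed Chothia-style table
(C 1.80, N 1.65, O 1.40, S 1.85 Å), overridable per element; an element
without a radius or mass is a hard error, never a silent default.
Hydrogens are ignored throughout — crystal structures at typical
resolution have none, and all reported quantities are heavy-atom or Cα
quantities.

Fractional side-chain accessibility divides a residue's summed side-chain
ASA by the same residue's side-chain ASA in an extended Gly-X-Gly
tripeptide built internally with ideal geometry (φ = ψ = ω = 180°, side
chains extended at χ = 180°) and evaluated with identical parameters —
the NACCESS-style convention. Glycine's "side chain" is its Cα, so glycine
rows remain defined. Values slightly above 1 are possible because the
reference is one conformation, not a supremum; degenerate inputs such as
Cα-only traces can exceed it further (an isolated Cα is more exposed than
glycine's Cα in the reference peptide). The ideal-geometry templates are
approximate for rings and prolines; this cancels almost entirely in the
fraction because the same templates define the denominator, and the
conserved-residue comparisons of interest live at the 2-decimal level
where the approximation is immaterial.

## Synthetic data: what it emulates, and what it does not

`make_flex_ensemble()` draws each conformer as the base structure plus
independent Gaussian Cα displacements with per-coordinate standard
deviation `amplitude/√3` — so the expected RMSD-to-mean converges to the
planted amplitude — followed by a random rigid motion that forces the
superposition stage to do real work. Generated B-factors are set to
`(8/3)π²·amplitude²`, keeping the three observables mutually consistent.
`make_mode_trajectory()` samples frames from a planted mass-weighted
Gaussian with known orthonormal modes and variances, so the quasiharmonic
estimator can be checked for eigenvalue, eigenvector and variance-fraction
recovery. Both are pure functions of their seed.

What the generators deliberately omit: anharmonicity and multi-well
landscapes, correlated inter-residue displacements in the ensemble
generator, crystal-contact bias, side-chain rotamer excursions, and solvent.
Passing the planted-recovery tests therefore shows the estimators are
correct and well-conditioned at realistic sizes — it does not show that a
real protein's fluctuations are harmonic, and trajectory-derived
percentages for a real system depend on simulation length and force field
in ways no desk-scale test can certify.

## Problem sizes and tolerances used in validation

The test suite and the acceptance script run ensembles of 16–256 conformers
over 20–60 residues, trajectories of 5,000–10,000 frames over 8–24
residues, and 960-point ASA grids — sizes chosen so every planted
parameter is recoverable within its sampling noise (eigenvalues to 10%,
eigenvector overlaps above 0.95, variance fractions to ±0.02, amplitude
profiles at r > 0.95, profile-level amplitude convergence to 5% RMS at
N = 256). Comparisons against deposited crystal structures (asymmetric-unit
chain counts, the 16-monomer RMSD peak profile, conserved-residue
fractional ASA) require the user to supply the PDB files locally; the
package never fetches them, keeping every run hermetic.

## Known limitations

* Least-squares rather than maximum-likelihood superposition (see above);
  covariance-weighted fitting is out of scope.
* The quasiharmonic analysis assumes rigid-body motion is removable by Cα
  fitting; for multi-domain systems a per-domain analysis is the right
  unit, mirroring the per-chain convention used throughout.
* ASA is accessible surface, not molecular (solvent-excluded) surface, and
  no interface decomposition is attempted.
* Trajectory input is text-based (multi-model PDB or XYZ frames); binary
  MD formats are intentionally unsupported to keep the I/O surface small
  and dependency-free.
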