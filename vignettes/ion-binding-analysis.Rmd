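---
title: "Probing metal-ion binding at protein sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing metal-ion binding at protein sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionprobe)
```

ionprobe post-processes molecular-dynamics output to answer one family of
questions: where does a metal ion localize around a protein site, what free
energy does it pay to get there, how does the protein's conformational
dynamics respond, and does the resulting coordination sphere look like a
recognizable binding motif? The motivating system is a divalent cation
(e.g. Cd(II)) invading the active site of a DNA glycosylase, where an
aspartate/histidine pair normally positions a catalytic water; but every
stage is generic. Because production MD engines and quantum-chemical
refinement are out of scope, the package ships seeded synthetic generators
that emulate each input class with known ground truth, so all claims the
test suite makes are parameter-recovery claims against planted truth.

## Ion localization: distances, g(r), and Boltzmann inversion

`track_distances()` reduces each ion's position per frame to a scalar
distance from a reference site, either the minimum over the reference atoms
or the distance to their unweighted centroid. For a carboxylate-anchored
site the default reference is the centroid of the side-chain carboxylate
oxygens (`OD1`/`OD2`); the literature convention for "distance to residue
X" is ambiguous, so the reference selection is fully configurable.

`compute_rdf()` histograms all (frame, ion) observations into half-open
bins of width 0.25 Å by default (r_max 20 Å) and normalizes by the
ideal-gas shell expectation,

$$g(r_i) = \frac{\langle n_i\rangle}{\rho\, 4\pi r_i^2 \Delta r},
\qquad \rho = \frac{n_\mathrm{ions}}{V_\mathrm{box}}.$$

Two deliberate biases are worth knowing about. First, the bulk density uses
the full box volume with no correction for the volume excluded by the
protein, matching the behaviour of common trajectory-analysis tools; g(r)
is therefore depressed near a solute surface and only relative peak
structure should be interpreted there. Second, periodic images are not
unwrapped — inputs are assumed whole-molecule imaged, which the synthetic
generators guarantee by construction.

`boltzmann_invert()` converts g(r) to a free-energy profile
$F(r) = -k_B T \ln g(r)$ (with $k_B$ = 0.0019872041 kcal mol⁻¹ K⁻¹),
drops zero-occupancy bins from the grid rather than producing infinities,
and anchors $\min F = 0$. The $4\pi r^2$ Jacobian of the volume element
cancels between the sampling density and the RDF normalization, which is
exactly why the inversion of a correctly normalized g(r) recovers the
radial potential and not the potential plus $2 k_B T \ln r$.

## Stiff-spring pulls and the potential of mean force

A constant-velocity pull drags a harmonic restraint's target as
$\lambda(t) = \mathrm{start} + vt$. The external work accumulates as
$dW = (\partial U/\partial\lambda)\, v\, dt$, integrated by the trapezoid
rule (`accumulate_work()`), and is reported on the target grid $\lambda$
rather than on the particle's instantaneous position — the alternative
mapping smears work over the coordinate when the particle lags, and the
target grid is what the restraint actually controls.

A point that matters for reproducing AMBER-style runs: a restraint quoted
as "k kcal/mol/Å" is dimensionally a force, not a spring constant. ionprobe
interprets such a value as the spring constant in the AMBER restraint
convention $U = k(x-\lambda)^2$ (so the gradient stiffness is $2k$), and
exposes `spring_convention = "half"` for codes that define
$U = \tfrac12 k (x-\lambda)^2$.

`estimate_pmf()` offers three estimators over replicate work profiles:

* `mean_work` — $F = \langle W\rangle$. The default, because with a handful
  of replicates (the realistic number for hundreds-of-ns pulls) the
  exponential average is dominated by its smallest sample and is badly
  biased, whereas the mean with an inter-replicate standard-deviation band
  is an honest summary of a near-reversible pull.
* `cumulant2` — $F = \langle W\rangle - \mathrm{var}(W)/2k_BT$, the
  second-order cumulant expansion, exact when the work distribution is
  Gaussian (the stiff-spring/linear-response regime).
* `jarzynski_exp` — $F = -k_BT\ln\langle e^{-W/k_BT}\rangle$, computed via
  log-sum-exp so hundreds of kcal/mol of work do not underflow.

The profile is anchored at the grid start — the bulk-solvent end of a pull
toward a binding site — so barrier heights read as work on the way in.
Jensen's inequality guarantees `jarzynski_exp` never exceeds `mean_work`
pointwise; the test suite asserts this on every replicate set it builds.

Barrier detection (`detect_extrema()`) smooths with a centered moving
average (default 5 bins), scans for local extrema, filters by topographic
prominence (default 1 kcal/mol — below that level, thermal noise on a
desk-scale profile produces spurious crests), and reports positions at the
extremal unsmoothed grid point so smoothing cannot shift a reported
barrier. `correlate_profiles()` re-bins two profiles onto the coarser grid
over their overlap by linear interpolation and reports the squared Pearson
correlation; `mode = "invert_a_first"` Boltzmann-inverts an RDF first so an
equilibrium-route profile can be compared with a pull-route PMF on a common
(free-energy) scale. Both modes are provided because published
RDF-versus-PMF correlations rarely state which scale was correlated.

## Essential dynamics and anharmonicity

`align_ensemble()` performs iterative least-squares rigid-body
superposition (Kabsch, via the SVD) of every frame onto the running mean of
the selected atoms until the mean drifts by less than 1 μÅ. Superposition
before covariance analysis is not optional: without it, rotational and
translational diffusion dominates the spectrum and the leading "modes" are
artifacts. `build_pca()` then eigendecomposes the 3N × 3N covariance
(unbiased n−1 denominator) of the mean-centered flattened coordinates; for
215 selected alpha carbons that is a 645 × 645 problem. Projections
(`project_frames()`) subtract the model mean before the inner product with
an eigenvector — a plain inner product without centering offsets every
displacement by ⟨mean, e⟩ and makes displacement histograms land far from
zero.

`classify_modality()` replaces the by-eye judgement "this component's
histogram has two peaks" with an explicit rule: fit 1- and 2-component
Gaussian mixtures, and call the series anharmonic only if the 2-component
fit wins by at least 10 BIC points (lower-is-better convention
$-2\log L + k\log n$), both weights are at least 0.2, and the means are
separated by at least one pooled standard deviation. All three thresholds
are arguments. The EM fit itself is delegated to mclust, whose
deterministic quantile-based initialization makes random restarts
unnecessary — which is also why fixed seeds give bit-identical verdicts.
The 10-point BIC margin is deliberately conservative: over 200 synthetic
Gaussian null series of 5000 samples the false-anharmonic rate is 0%,
while the well-separated bimodal alternative (±2 Å means, 0.5 Å component
sd) is detected every time.

`project_vs_distance()` pairs per-frame displacements of a pulled
trajectory (projected onto an equilibrium component) with the matched
ion-site distances and bins them (default 0.5 Å) into a mean ± sd profile;
empty bins are omitted rather than interpolated.

## Metal sites, motifs, and geometry

`extract_sites()` collects all non-metal, non-hydrogen atoms within a
cutoff (default 3.0 Å) of each metal. The cutoff is exposed rather than
hard-coded because published metal-site databases do not agree on one;
3.0 Å comfortably covers M–O/M–N coordination distances for the divalent
metals of interest. `classify_ligand()` is a pure lookup on
(residue, atom): Asp/Glu carboxylate oxygens, His imidazole nitrogens,
backbone carbonyl O of standard residues, water O, else "other".

Motif matching counts *residues*, not donor atoms — a bidentate carboxylate
is one carboxyl group. Two presets encode the motifs of interest: the
relaxed "UNG-like" motif (exactly one Asp/Glu carboxyl plus exactly one His
imidazole, anything else tolerated) and a strict active-site motif (those
two plus at least one backbone carbonyl oxygen, water unconstrained, no
other donor chemistry). `census()` tallies sites and matches per metal over
a structure set; the result is invariant to structure order and additive
over structures, both property-tested.

`coordination_geometry()` reports distances, all ligand–metal–ligand
angles, the mean absolute deviation from the tetrahedral angle, and the
four-coordinate index $\tau_4 = (360° - (\beta+\gamma))/(360° - 2\theta_t)$
for the two largest angles $\beta, \gamma$. The denominator uses the exact
tetrahedral angle $\theta_t = \arccos(-1/3) \approx 109.471°$ (i.e.
141.06°) rather than the rounded 141° seen in the literature, so an ideal
tetrahedron scores exactly 1 and square planar exactly 0; distorted inputs
can score above 1 and are reported as computed.

## The synthetic generators: what they emulate, and what they don't

* `gen_ideal_gas()` — ions uniform in a box: the null model under which
  g(r) = 1.
* `gen_boltzmann_ions()` — Metropolis sampling of the radius under
  $p(r) \propto r^2 e^{-U(r)/k_BT}$ with uniform angles (proposal sd
  0.3 Å, 1000-step burn-in, 10× thinning). Metropolis rather than
  inverse-CDF sampling so arbitrary tabulated potentials work; the
  acceptance rate is checked against [0.1, 0.9].
* `gen_smd_pulls()` — overdamped Langevin dynamics in a 1-D radial
  potential under the moving restraint. Overdamped (no inertia) is
  sufficient because only work statistics, not kinetics, are compared
  downstream. The stability bound $k_\mathrm{eff}\Delta t/\gamma < 0.1$ is
  enforced with a suggested time step in the error.
* `gen_mode_ensemble()` — pseudo-alpha-carbons on a helix-like curve
  (2.3 Å radius, 1.5 Å rise, 100°/residue, giving the canonical ~3.8 Å
  CA–CA spacing) displaced along planted orthonormal 3N directions with
  Gaussian or double-well amplitude distributions, plus isotropic noise
  and optional random rigid-body jitter. Mode directions are
  orthogonalized against the base geometry's six rigid-body degrees of
  freedom by default (`internal_modes = TRUE`): a planted mode with a
  rigid-body component would be partially removed by superposition, and
  the planted eigenvalue would no longer be the ground truth the recovery
  tests compare against.
* `gen_metal_fixtures()` — metal at the origin, donor atoms on prescribed
  geometry vertices at prescribed distances, randomly rotated as a whole
  (angle-preserving). Ground-truth match labels travel with the data.

None of these emulate explicit solvent, force-field realism, or a real
fold. A passing recovery suite therefore demonstrates that the estimators
are correct *given* Boltzmann-distributed inputs of the assumed form — it
does not validate force fields, sampling convergence of real trajectories,
or the protein-excluded-volume bias of the RDF normalization.

## Study conditions and numerical choices

The desk-scale problem sizes used by the tests and the acceptance script
were fixed as part of the study design:

* PMF recovery: 16 replicates (4× the realistic replicate count, to
  separate estimator bias from replicate noise) over a double-well with a
  5 kcal/mol barrier between minima at 3 and 7 Å; pull velocity
  0.005 Å/ns with friction 50 kcal mol⁻¹ ns Å⁻², chosen so the mean
  dissipated work over the 2 Å approach to the crest (~γvΔ ≈ 0.5 kcal/mol)
  sits well inside the ±1 kcal/mol recovery tolerance while barrier
  diffusion stays slower than the pull. Work is reported on a 0.25 Å grid
  (the same spatial resolution as the RDF default), which defines the
  "within one bin" crest-position criterion.
* RDF: 40 ions × 1000 frames in a 40 Å box for the ideal-gas null;
  4000 Metropolis samples for the harmonic-recovery check, with the
  0.3 kcal/mol tolerance applied only to bins holding ≥100 counts, where
  the statistical error on $-k_BT\ln g$ is below ~0.06 kcal/mol.
* PCA: a planted 4 Å² mode over 0.01 Å² isotropic noise, 2000 frames —
  large enough that the sampling error of a variance (relative sd
  $\sqrt{2/n}$ ≈ 3%) sits inside the 10% recovery band.
* The workflow demo pulls at 0.01 Å/ns with friction 10 so the
  equilibrium (RDF) and nonequilibrium (pull) routes to the same harmonic
  landscape agree to r² > 0.9 — the same internal-consistency comparison
  one would run on real data to check that a crowded equilibrium
  simulation and a single-ion pull see the same energetics.

Degenerate inputs are handled by contract rather than by accident:
zero-occupancy RDF bins are masked, constant profiles yield empty barrier
sets, zero-variance series are errors ("degenerate series"), a single
replicate makes `cumulant2` warn and treat the variance as zero, and
sub-4-coordinate sites report $\tau_4$ as `NA`.

## Reproducibility

Every generator consumes an explicit seed and is bit-reproducible; the
workflow runner (`run_workflow()`) seeds once from its config and writes a
manifest listing every tunable, so the determinism contract — identical
config and seed implies hash-identical outputs — is testable and tested.
The frame interval of a trajectory is carried as metadata only; no stage
assumes a stride.

## Known limitations

* The RDF bulk density ignores protein-excluded volume; absolute g(r)
  levels near a surface are biased low.
* Work is attributed to the restraint target, not the particle position;
  with a soft spring and a fast pull the two axes can differ visibly.
* The bimodality rule is a calibrated stand-in for a visual judgement; a
  BIC margin of 10 is conservative by design and will miss weakly
  separated substates.
* The motif census is a transparent local scanner, not a replica of any
  external database's site-extraction semantics; counts from database
  queries with unknown radii and shell rules are not comparable
  number-for-number.
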