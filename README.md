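# ionprobe

Post-analysis toolkit for studying how metal ions localize at — and
perturb — protein binding sites in molecular-dynamics ensembles. The
motivating problem is a toxic divalent cation (e.g. Cd(II)) invading the
active site of a DNA-repair glycosylase, displacing the catalytic water
that an Asp/His pair normally positions; the package provides the four
computational routes by which such a mechanism is characterized, plus
seeded synthetic generators so every route is verifiable against planted
ground truth without an MD engine.

**Who it is for:** computational structural biologists post-processing
equilibrium and steered-MD trajectories (or anyone benchmarking the
estimators below on synthetic data).

## What it computes

1. **Ion localization** — per-frame ion–site distances, the radial
   distribution function
   `g(r) = ⟨n(r)⟩ / (ρ 4π r² Δr)` (0.25 Å bins by default), and its
   Boltzmann inversion `F(r) = −k_B T ln g(r)` to a free-energy profile
   with zero-occupancy bins masked.
2. **Steered-pull free energies** — nonequilibrium work accumulated along
   a constant-velocity stiff-spring pull
   (`dW = (∂U/∂λ) v dt`, AMBER convention `U = k(x−λ)²` or the ½k
   alternative), combined across replicates into a PMF by `mean_work`,
   the second-cumulant correction `⟨W⟩ − var(W)/2k_BT`, or the Jarzynski
   exponential average `−k_BT ln⟨e^(−W/k_BT)⟩` (log-sum-exp stabilized);
   barrier detection with prominence filtering; r² correlation between an
   RDF-derived free energy and a pull-derived PMF.
3. **Essential dynamics** — iterative Kabsch superposition, PCA of the
   3N × 3N alpha-carbon covariance (215 atoms → 645 components),
   displacement projections `⟨x − x̄, e_j⟩`, and a calibrated
   BIC-margin Gaussian-mixture rule that classifies a component's
   displacement distribution as harmonic or anharmonic (bimodal).
4. **Metal-site motifs and geometry** — coordination-sphere extraction
   from PDB structures, donor classification
   (carboxylate O / imidazole N / backbone carbonyl O / water),
   residue-level motif matching (e.g. the "UNG-like" motif: exactly one
   Asp/Glu carboxyl + one His imidazole), per-metal census over structure
   sets, and the τ₄ four-coordination index
   `(360° − (β+γ)) / (360° − 2·109.47°)`.

A config-driven runner (`run_workflow()`, YAML configs, manifest with
every tunable) orchestrates the four stages end to end; identical config
and seed give hash-identical outputs. A thin CLI wrapper for the runner
ships in `inst/scripts/ionprobe`.

## Worked example

Pull an ion 4 Å across a synthetic double-well landscape with a planted
5 kcal/mol barrier (16 stiff-spring Langevin replicates), estimate the
PMF, and detect the barrier:

```r
library(ionprobe)

pot   <- radial_potential("double_well", height = 5, r1 = 3, r2 = 7,
                          temperature = 300)
sched <- pull_schedule(start_position = 3, pull_distance = 4,
                       velocity = 0.005, spring_constant = 20,
                       time_step = 0.02)
pulls <- gen_smd_pulls(sched, pot, friction = 50, n_replicates = 16,
                       seed = 1, stride = 2500)
pmf   <- estimate_pmf(pulls$works, temperature = 300,
                      estimator = "cumulant2")
detect_extrema(pmf, "maxima", smooth_window = 5, min_prominence = 1)
#>   position    value   height prominence
#> 1        5 4.805567 4.805567   3.815359
```

The planted barrier (5 kcal/mol at r = 5 Å) is recovered at the right
grid point with a height of 4.81 kcal/mol — within the inter-replicate
noise of the planted truth. `estimator = "mean_work"` on the same pulls
reads slightly high (dissipation is not subtracted), and
`jarzynski_exp` is bounded above by it pointwise.

Scan a constructed 10-structure set (3 sites match the UNG-like motif by
construction) and inspect one coordination sphere:

```r
fix <- ung_like_fixture_set(seed = 1)
census(fix$structures, metals = "Cd", spec = motif_ung_like(),
       cutoff = 3.0)
#>   metal n_structures n_sites n_matches percent_matches
#> 1    Cd           10      10         3              30

site <- extract_sites(fix$structures$site_1, metals = "Cd",
                      cutoff = 3.0)[[1]]
site
#> <metal_site> Cd (serial 1), 4 ligand(s)
#>   ASP 2 OD1  2.20 A  [carboxylate_O]
#>   HIS 3 ND1  2.20 A  [imidazole_N]
#>   PRO 4 O  2.20 A  [backbone_carbonyl_O]
#>   HOH 5 O  2.20 A  [water_O]
coordination_geometry(site)
#> <geometry_report> CN 4, tau4 1.000
#>   distances (A): 2.20, 2.20, 2.20, 2.20
#>   mean |angle - 109.47|: 0.00 deg
```

An end-to-end run on the bundled synthetic demo (all four stages, with
the RDF route correlated against the pull route):

```r
res <- run_workflow(default_config())   # writes ionprobe_out/
res$manifest$rdf_pmf_r_squared
```

See `vignettes/ion-binding-analysis.Rmd` for the model assumptions,
estimator trade-offs, calibration of the anharmonicity rule, and the
study conditions behind the numbers.

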