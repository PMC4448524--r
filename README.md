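# EncounterMD

Analysis of protein–protein **encounter, binding and oligomerization** in
multi-copy molecular dynamics trajectories, for structural biologists and
simulators who have several copies of a globular protein diffusing in a
periodic box and want to dissect *how* they meet: who contacts whom and
through which residues, how the copies are mutually oriented, how strong
the long-range dipolar steering is, how fast the copies diffuse, and how
the conformational ensemble shifts along the binding pathway.

## What it computes

For every chain pair and frame: the center-of-mass distance (minimum-image
in the cubic box), the optimal-superposition **orientation angle**
θ = arccos((tr R − 1)/2) ∈ [0°, 180°] (180° for a perfect C2 dimer), the
angle between molecular dipole moments, and the **heavy-atom contact
count** (atoms of each side within 4 Å of the other side). On top of
those:

- per-residue contact-frequency profiles with running residue averages
  and profile comparison (Pearson r, peak overlap);
- the scalar dipole–dipole interaction
  E = μ_A μ_B (1 − 3cos²θ) / (4π ε₀ D r³) and its radial force
  |F| = 3|E|/r per molecule, in a dielectric continuum (D = 78);
- translational diffusion from time-origin-averaged MSD (D = slope/6),
  per chain and as ensemble MSD, plus the Brownian exploration length
  √(6 D t) and the box concentration n/(N_A V);
- Arrhenius barrier-to-timescale conversion τ = exp(ΔG/RT)/k₀;
- PCA frames from structural ensembles (Cα covariance, iterative
  superposition onto the converged mean), trajectory projection, and
  −k_B T ln(N_i/N_0) log-probability landscapes;
- binding/dissociation event detection with persistence filtering, and
  per-frame oligomer-state classification from the chain contact graph
  (monomer / dimer / linear vs compact trimer / n-mer);
- a rigid-body Brownian **synthetic trajectory generator** with scripted
  binding events and a ground-truth sidecar, so every stage above is
  testable without external data.

## Worked example

```r
library(EncounterMD)

## a deterministic 70-residue pseudo-protein with a constructed 250 D dipole
tpl <- makeTemplate()
tpl
#> Trajectory: 1 frame(s) x 630 atoms; no box
#>   time 0.000 .. 0.000 ns; chains: A

## dipolar steering at 50 A and 135 degrees, 300 D dipoles, water dielectric
dipoleForce(300, 300, theta = 135, r = 50)$force_pN
#> [1] 0.277          # pN per molecule, attractive

## three copies in a 100 A box
boxConcentration(3, 100)
#> [1] 4.981617       # mM

## simulate two copies with a scripted binding event at 10 ns ...
script <- data.frame(chain_i = 1L, chain_j = 2L,
                     bind_time_ns = 10, approach_speed_A_ns = 8)
spec <- SyntheticSpec(nCopies = 2L, template = makeTemplate(n_residues = 20),
                      nSteps = 300L, seed = 42L, script = script)
res <- generateTrajectory(spec)

## ... and detect it from the contact/distance series alone
ps <- computePairSeries(res$trajectory, c("A", "B"),
                        metrics = c("distance", "contacts"))
detectEvents(ps, gyrationDiam = res$groundTruth$gyration_diameter_A)
#>   kind chain_a chain_b onset_ns completion_ns peak_contacts
#> 1 bind       A       B     12.1          12.7           157
res$groundTruth$events
#>   chain_i chain_j bind_time_ns contact_time_ns
#> 1       A       B           10            13.2
```

The detected onset (12.1 ns) sits where the approaching copy first holds
≥ 10 contact atoms, just before the scripted approach completes
(13.2 ns); the plateau of ~157 contact atoms is typical of a compact
rigid-body dimer of this size.

The full pipeline — pair-series CSVs, contact profiles, event tables,
state timelines, optional landscapes, JSON summary and manifest — runs
from a config with `runSimulate()` / `runAnalyze()`, or from the shell via
`inst/scripts/encountermd.R simulate|analyze|electro`.

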