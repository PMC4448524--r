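---
title: "Methods: encounter, binding and landscape analysis of multi-copy protein trajectories"
author: "EncounterMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encounter, binding and landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EncounterMD)
```

# Scope and data model

EncounterMD analyzes trajectories of several copies of the same globular
protein diffusing and associating in a periodic cubic box. The data model
is deliberately small: a `Topology` (chains, residues, atoms with element,
mass and partial charge), a `Trajectory` (frames x atoms x 3 coordinates in
Angstrom, a cubic box edge, frame times in ns), and derived containers for
pair metrics (`PairSeries`), PCA frames (`PCAFrame`), binned landscapes
(`LandscapeGrid`) and diffusion estimates (`DiffusionEstimate`).

Multi-model PDB is the one mandatory trajectory dialect: it is plain text,
bit-exactly testable, and every MD package can emit it. Charges enter only
through PQR (or the synthetic generator); a topology read from plain PDB
carries zero charges, and every dipole operation on such a topology warns
rather than silently producing a zero vector. Residue numbering is kept
verbatim (1-based PDB convention), coordinates are never wrapped on read,
and chain/atom order is preserved exactly through every read/write cycle.
PDB output stores coordinates to 0.001 A, which bounds round-trip error.

Frame times default to 0.1 ns spacing when the file carries none. PDB has
no time record, so some spacing must be assumed; 0.1 ns matches the sub-ns
granularity at which encounter events are typically inspected, and it is a
config entry, not a constant.

# Pair geometry

**COM distances.** Inter-chain separations are distances between mass-
weighted centers of mass under the minimum-image convention. Intra-chain
geometry (gyration radius, dipole moments, superpositions) always uses the
stored whole-molecule coordinates: the generator and the readers keep each
chain whole across the boundary, because radii of gyration and dipoles are
meaningless for a molecule split across a periodic face.

**Orientation angle.** For two copies of the same protein, both are
centered on their COM, the optimal (Kabsch) superposition rotation R is
computed over heavy atoms, and the reported angle is
arccos((tr R - 1)/2) in [0, 180] degrees. Identically oriented copies give
0; a perfect two-fold symmetric (C2) dimer gives the maximum of 180. Heavy
atoms are the default selection (configurable); the choice barely matters
for rigid copies and avoids committing to a backbone subset. Note that
arccos is ill-conditioned near +-1, so angles within ~1e-6 degrees of 0 or
180 are at the attainable floating-point precision.

**Contacts.** A contact count at cutoff 4 A tallies the heavy atoms of
each chain lying within the cutoff of any heavy atom of the other chain,
each atom counted once per side — so an isolated close atom pair counts 2.
This reads "number of heavy atoms of each protein" literally as atoms, not
atom pairs; the pair convention is exposed via `convention = "pairs"` for
sensitivity checks. Per-residue contact-frequency profiles increment each
residue by the number of its counted atoms, per frame and chain pair, are
summed over frames, then averaged across replicas. Whether such profiles
should be per-frame averages or trajectory totals is a reporting choice;
the table carries both (`count` and `per_frame`). The running residue
average uses a centered 5-residue window (truncated at the termini) — the
smoothing scale that makes interface segments visible without erasing
them; it is a parameter, not a constant.

**Interfacial waters.** Water molecules (residue names HOH/WAT/TIP3,
configurable) whose oxygen lies within the cutoff of a heavy atom of
*both* chains are the bridging waters whose expulsion accompanies the
final approach of two surfaces.

# Dipole electrostatics

Molecular dipoles are computed as the charge-weighted position sum about
the COM, converted with 1 e A = 4.80320 D. The interaction between two
molecular dipoles is evaluated in the scalar single-angle form

$$E = \frac{\mu_A \mu_B (1 - 3\cos^2\theta)}{4\pi\varepsilon_0 D r^3},$$

with relative dielectric D = 78 (bulk water) by default, and the force
magnitude per molecule as its radial derivative, |F| = 3|E|/r, reported in
pN. All constants (CODATA e, eps0, N_A, k_B; 1 D = 3.33564e-30 C m) live
in a single table, `physicalConstants()`, so every conversion is
auditable. The per-mole/per-molecule round trip through Avogadro's number
that some formulations carry cancels exactly; the package computes
per-molecule quantities directly and never exposes per-mole values.

Two caveats are inherent to the scalar form. First, a single inter-dipole
angle cannot represent the full two-angle dipole tensor: it is a
reduction, adequate for order-of-magnitude force estimates along a binding
pathway, not for orientational free-energy surfaces. Second, the sign of
$1 - 3\cos^2\theta$ makes configurations with $\theta$ between the magic
angle (54.74 degrees) and its supplement repulsive; a 70-degree pair is
repulsive in this form even when the magnitude falls in an "attractive"
bracket quoted from a trajectory — the package reports the sign exactly as
the formula gives it.

The Arrhenius conversion $\tau = \exp(\Delta G / RT)/k_0$ turns a
dissociation barrier (kcal/mol) into an escape timescale with a default
attempt frequency of 1 per microsecond; it is strictly increasing in the
barrier and decreasing in temperature, and with barriers of 5-20 kcal/mol
spans roughly 1e-2 to 1e9 seconds.

# Diffusion from mean-squared displacement

Translational diffusion coefficients come from the time-origin-averaged
MSD over a lag grid, fitted linearly and divided by 6 (3D Brownian
motion), with 1 A^2/ns = 1e-11 m^2/s. Two windowing decisions matter:

* **Analyzed lag span.** Lags are analyzed only up to 5% of the
  trajectory span by default. The time-averaged MSD of a single particle
  at lag tau has relative sampling error growing like sqrt(tau/T); beyond
  a few percent of the span the curve is noise-dominated and fitting it
  degrades the estimate.
* **Fit window.** The default fit covers 10-50% of that analyzed lag
  span, skipping the shortest lags (transient-prone in real data) and the
  tail of the analyzed range.

Both are arguments. For multi-copy systems, `ensembleDiffusion` averages
the per-chain MSD curves before fitting (the ensemble MSD), shrinking the
statistical error by roughly the square root of the copy number; the
recovery tests use three copies, matching the study geometry. D is
reported per chain by `chainDiffusion` because the spread over chains and
replicas — not a single number — is the meaningful description. A negative
fitted slope (possible in pathological or confined series) clamps D to 0
with a warning. The helper `brownianLength` converts D and a time into the
RMS exploration length sqrt(6 D t); `boxConcentration` converts copy count
and box edge into mM.

# PCA frames and log-probability landscapes

The PCA reference frame is built from an ensemble of structures on the
C-alpha atoms of a residue range (default 2-70, dropping the flexible
termini of a ~70-residue protein). All members are superposed onto the
*running ensemble mean* — align, re-average, repeat until the mean moves
less than 1e-6 A (at most 10 rounds) — rather than onto the first
structure, which would make the frame depend on input order. The
covariance of the flattened 3m coordinates is eigendecomposed; variance
fractions are eigenvalue over trace and sum to 1.

Projection superposes each snapshot onto the converged mean and dots the
centered coordinates with the leading eigenvectors, which makes scores
invariant to any rigid transform of the input. Landscapes bin the 2D
scores (default 40 x 40 over the data range padded 5%) and report
$-k_B T \ln(N_i/N_0)$ in kcal/mol with $N_0$ the most populated bin, so
the minimum is exactly 0 and a bin with $N_i = N_0/e$ sits at exactly
$k_B T$ (0.596 kcal/mol at 300 K). Empty bins are masked rather than given
infinite values. Only count ratios enter, so duplicating the data leaves
the landscape unchanged.

The reference ensembles used in published work (e.g. large sets of
crystal structures) are not shipped; the frame builder accepts any user
ensemble, and the tests build synthetic ensembles by displacing a template
along constructed orthonormal modes. Those modes are built orthogonal to
the six rigid-body modes (translations and infinitesimal rotations about
the mean), because any rigid component would be silently absorbed by the
superposition step and the engineered variance ratio would not survive.
Mode scores are standardized exactly, so a 4:1 variance ratio yields
variance fractions of 0.8/0.2 up to alignment nonlinearities (second order
in the displacement amplitude).

# Events and oligomer states

A pair is *bound* when its contact count holds at or above `c_on` (default
10 atoms) for at least the persistence time (default 5 ns); it unbinds
when contacts hold at or below `c_off` (default 0) equally long. Bound
pairs in compact dimers show contact counts of order 100, so 10 atoms is a
conservative onset; the persistence filter removes single-frame brushes.
Completion of a bind is the first frame where the COM distance comes
within 10% of the gyration diameter — the expected COM separation of a
maximally compact dimer — or, failing that, where the rolling-mean contact
count changes by less than 5% across one persistence window (a plateau).
Events per pair alternate bind/unbind by construction, and completion
never precedes onset.

Oligomeric state per frame comes from the chain contact graph (edge when a
pair has >= 1 contact atom, threshold configurable): connected components
are labeled monomer, dimer, or for three chains by edge count — exactly 2
edges is a *linear* trimer (a middle chain bridging two ends), 3 edges a
*compact* trimer (every pair in contact); larger components are n-mers.
The state timeline tabulates transitions between consecutive frame labels
so directional claims (e.g. linear-to-compact conversions without the
reverse) become countable.

# The synthetic generator

`generateTrajectory` produces rigid-body Brownian dynamics with known
ground truth: per step each free copy translates by Gaussian displacements
of variance 2 D_t dt per axis and rotates about a random axis by an angle
of variance 2 D_r dt. Defaults emulate the study conditions: three copies
of a ~70-residue template (560 heavy atoms, neutral, constructed 250 D
dipole) in a 100 A cubic box — about 5 mM — with D_t = 3e-11 m^2/s
(mid-range of the 2-5e-11 observed for freely diffusing copies), D_r =
1e7 rad^2/s (a rotational correlation time of tens of ns, the right order
for a small globular protein), dt = 0.1 ns. Initial placements enforce
>= 30 A pairwise COM separation. Scripted pairs switch to a deterministic
mutual approach at their bind time and attach rigidly once the COM
distance reaches 75% of the template's gyration diameter (enough surface
interpenetration for rigid bodies to hold hundreds of contact atoms); the
sidecar records both the scripted bind time and the realized contact
time, which is what detection should be compared against. Optional dipole
coupling adds a deterministic drift along the inter-COM vector with
velocity mobility x force (Einstein mobility D/k_B T) from the scalar
dipole force.

What the generator does *not* emulate is as important for interpreting
green tests: there is no internal flexibility (conformational variability
for landscape tests is produced separately along synthetic modes), no
hydrodynamics, no solvent, no realistic binding thermodynamics, and
scripted events are deterministic rather than diffusive encounters.
Passing recovery tests therefore demonstrates that the *analysis* stages
are correct on data with known truth — not that any force field or
sampling protocol is adequate.

The template itself is a deterministic pseudo-protein: 70 residues on a
volume-filling Fibonacci spiral in an ~11 A ball, nine atoms per residue
(eight heavy), masses by element, charges constructed as a zero-sum
pattern proportional to the centered z coordinate and rescaled so the
dipole magnitude hits its target exactly. Identical arguments give
bit-identical output, which the I/O round-trip tests rely on.

# Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with the determinant sign fix; collinear
  (rank < 2) coordinate sets raise an error rather than returning an
  arbitrary angle.
* Minimum imaging for contacts shifts the second chain by the box vector
  that minimizes the COM separation, then measures plain Euclidean
  distances — exact for whole molecules smaller than half the box, which
  the data model guarantees.
* Degenerate PCA ensembles (all structures identical) raise a
  "degenerate ensemble" error; tiny negative eigenvalues from symmetric
  eigendecomposition are clamped to zero.
* Landscape ties at the maximum count all map to exactly 0; a zero range
  along an axis is padded to a unit interval so single-point inputs bin
  cleanly.
* Empty tables are refused by `writeTable` (an empty file is
  indistinguishable from a failed stage); CSV output is byte-stable for
  identical input.
* Unwrapping assumes no chain moves more than half a box edge between
  frames, which holds by orders of magnitude at the default D and dt.

# Problem sizes

The shipped tests run the full pipeline at sizes chosen so the whole
suite completes in a few minutes on one core: diffusion recovery uses
three seeds of 1e4-step, 3-copy systems with a reduced 5-residue template
(COM diffusion is independent of template size); event recovery uses
three scripted 2-copy runs of 450-750 frames with a 20-residue template;
PCA recovery uses 150-200 member ensembles of the full 70-residue
template. Nothing in the method depends on these sizes; they are stated
here so the scaling choice is explicit.

# Known limitations

* The scalar dipole model ignores orientation-resolved tensors, higher
  multipoles and screening beyond a uniform dielectric.
* Rotational diffusion is generated but not estimated; only translational
  D is fitted.
* The event detector is threshold-based; it does not estimate kinetic
  rates and is not a Markov state model.
* Oligomer labels describe contact-graph topology only; they carry no
  energetic meaning.
* Binary trajectory formats (DCD/XTC) are not parsed; convert to
  multi-model PDB upstream.
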