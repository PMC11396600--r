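---
title: "Methods: from conformational trajectories to kinetics, flux and binding energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from conformational trajectories to kinetics, flux and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmflux)
```

# Scope and model

`msmflux` implements the post-simulation analysis chain used to connect a
protein's conformational dynamics to a functional phenotype — in the
motivating application, the glow- versus flash-type bioluminescence of
luciferase mutants binding their luciferin substrate. The chain is:

1. **Trajectory observables** — RMSD, radius of gyration, RMSF,
   solvent-accessible surface area, dynamical cross-correlation matrices
   (DCCM), inter-helix pocket distances and per-residue α-helix content.
2. **Microstate discretization** — k-means clustering of trajectory
   features, scored with VAMP-2.
3. **Markov state model (MSM) estimation and validation** — transition
   counting at a lag time τ, maximum-likelihood (optionally reversible)
   transition matrices, implied timescales and the Chapman–Kolmogorov test.
4. **Coarse-graining and transition-path theory (TPT)** — PCCA+
   macrostates, committor probabilities, reactive gross/net flux and
   pathway decomposition.
5. **MM/PBSA energetics** — aggregation of per-frame energy components into
   the standard summary tables and per-residue contribution rankings.

Raw MD engines, force fields and the Poisson–Boltzmann solver are out of
scope: the package consumes trajectories and per-frame component energies.
Because production MD trajectories at the hundreds-of-nanoseconds scale are
rarely shareable, every stage is exercised against **synthetic generators
with known ground truth** (below), which is also how the test suite works.

Units are Å, ns and kcal/mol throughout; nothing converts implicitly.

# Synthetic data generators

The generators emulate the statistical structure the analyses assume — not
the physics of a solvated protein.

**Discrete jump chains.** `sample_markov_chain()` draws a state sequence
from a known row-stochastic matrix `T`. The empirical row-normalized count
matrix converges to `T` at the binomial rate `n^{-1/2}`, which gives exact
sampling bounds for tests.

**Diffusive dynamics.** `langevin_double_well()` integrates the overdamped
Langevin equation `dx = -(D/kT) ∇U dt + √(2D dt) ξ` by Euler–Maruyama on a
harmonic single well or a quartic double well with minima at the specified
centres and a barrier of the specified height (in kT). First-order
overdamped dynamics is the simplest process with tunable metastability,
which is all MSM estimation needs. The integrator subdivides the frame
spacing automatically until the deterministic update is stable
(`(D/kT)·dt·U'' ≤ 0.1` at the well curvature), so recorded frames are
always at the configured spacing while the integration step respects the
stiffness of the landscape.

**Correlated Gaussian ensembles.** `gaussian_ensemble()` adds correlated
isotropic Gaussian displacements to a reference structure. For each
Cartesian axis the site displacement vector is drawn from
`N(0, diag(σ) C diag(σ))` through the *symmetric* matrix square root, and
the axes are independent. This makes the ground truth analytic: the
ensemble DCCM converges to `C` entrywise and the per-site RMSF to `σ√3`. A
non-positive-semidefinite `C` is an error; the generator never applies a
nearest-PSD repair, because silently altering the prescribed correlation
would invalidate the ground truth the tests rely on.

**Energy tables.** `synth_energy_table()` draws independent Gaussian
per-frame values per MM/PBSA component. Real component time series are
anticorrelated (electrostatics against polar solvation); independence is a
deliberate simplification — adequate for testing aggregation identities,
not for emulating realistic error propagation between components.

All generators draw every random number under a single explicit seed per
call and restore the caller's RNG state, so identical calls are
bit-identical and nothing leaks into the session RNG.

**What passing tests do and do not show.** Ground-truth recovery on these
generators validates the estimators' correctness (the code computes what
the formulas say). It does not validate their adequacy on real MD data,
where discretization error, non-Markovian memory at short lags and
force-field error dominate.

# Observables: numerical choices

**Superposition** is Kabsch's SVD solution on the selected atoms, with the
determinant sign correction so the rotation is always proper. The fitting
and measurement selections of `rmsd_series()` are independent parameters,
supporting ligand-style RMSD with the binding site aligned. An independent
quaternion (Horn) implementation serves as the oracle in the tests.

**DCCM** uses deviations from the time-mean structure after a *single*
superposition pass onto the mean (standard practice; no iteration —
iterating changes entries at the third decimal and buys nothing for
correlation structure). Sites with zero positional variance yield `NaN`
with a warning, never 0: absence of motion is not absence of correlation.
`rmsf()` by contrast iterates superposition onto the evolving mean until
the mean stabilizes, which is the conventional definition of fluctuation
about the average structure.

**SASA** is Shrake–Rupley with Bondi van der Waals radii (user-overridable),
a 1.4 Å water probe and a deterministic golden-spiral quadrature lattice —
deterministic so results are reproducible without a seed. Quadrature error
falls as the point count grows; 960 points puts an isolated sphere within
0.5% of `4π(r + w)²`.

**Helix content** uses a Kabsch–Sander reduction: the backbone
hydrogen-bond energy
`E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a
bond when `E < −0.5`, restricted to i→i+4 bonds, and the minimal-helix rule
(two consecutive 4-turns) for per-residue assignment. Full 8-class DSSP is
deliberately not implemented: the analysis chain only consumes α-helix
probability. Amide hydrogens are reconstructed from the preceding carbonyl
(`H = N + unit(C − O)`, 1 Å), so only N, CA, C, O are required; residues
missing any of them are excluded with a warning, and chain breaks suppress
the affected bonds.

# Discretization and model estimation

**k-means** uses k-means++ initialization under an explicit seed and Lloyd
iterations until the maximum centre shift falls below `tol`. Ties in
assignment break to the lowest centre index, and empty clusters re-seed at
the farthest sample. `stats::kmeans` is used in the tests as an independent
inertia oracle, never as the implementation.

**Counting** defaults to sliding windows (every pair `(t, t+τ)`), which
maximizes data use; strided counting is available. Estimation first trims
to the largest strongly-connected component — without ergodic trimming the
stationary vector is undefined. The reversible estimator maximizes the
likelihood under detailed balance by the standard fixed-point iteration on
symmetric flows, to a tolerance of 1e-10; tests verify it against a
brute-force constrained optimizer on 3 states.

**Implied timescales** are `t_i = −τ / ln λ_i`. Non-positive or complex
eigenvalues carry no timescale and are reported `NA` with a warning rather
than silently dropped.

**Chapman–Kolmogorov test.** The published adequacy criterion — "within 95%
agreement" — has no standard operational definition, so the package defines
one and exposes it: the test compares macrostate self-transition
probabilities of `T(τ)^k` against a model re-estimated at lag `kτ`, scoring
each prediction step as `1 − mean(|predicted − estimated| / predicted)`
clamped to `[0, 1]`. Step `j = 1` is identically 1 (both sides are the same
matrix), so the aggregate averages steps `2..k`. On an exactly Markovian
chain with 10^5 samples the aggregate sits near 0.998 — comfortably above
the 0.95 adequacy threshold, with the gap to 1 set purely by sampling
error.

**Hyperparameter selection.** The VAMP-2 score of an indicator
discretization (sum of squared singular values of the half-weighted Koopman
matrix, including the trivial stationary value) is non-decreasing under
partition refinement, so a literal argmax over k always drifts to the
largest candidate on the back of ~1e-4 estimation bias; cross-validated
scoring does not separate the candidates either (the overfit components
genuinely generalize with near-zero weight). `select_hyperparameters()`
therefore picks the *smallest k on the score plateau* — the first k whose
score is within 1% of the grid maximum — which is the same
convergence-heuristic logic used for the lag: the selected lag is the
smallest whose slowest implied timescale varies by less than 10% over the
next two grid points, falling back to the largest lag with a warning when
nothing converges.

# Coarse-graining and flux analysis

**PCCA+** takes the top-n right eigenvectors, locates the simplex vertices
with the inner-simplex algorithm (successive orthogonal deflation), and
obtains fuzzy memberships from the vertex-coordinate representation,
clamping small negative coefficients to zero and renormalizing rows. Crisp
labels are the argmax. Requesting more macrostates than the real leading
spectrum supports is an error that names the usable maximum. The
vertex-based construction (rather than the full PCCA+ objective
optimization) is exact for block and nearly-uncoupled chains, which is the
regime macrostating is meant for.

**Committors** solve the interior linear system densely; `q⁻ = 1 − q⁺` is
used as printed in the field's standard treatment, and is exact for
reversible chains — for non-reversible models the true backward committor
differs, which the documentation flags. **Gross flux** is
`f_ij = ρ_i q⁻_i T_ij q⁺_j` with the diagonal zeroed; **net flux** is
`max(f_ij − f_ji, 0)` (the published formula omits the second max argument;
the standard nonnegative form is implemented). Flux conservation at
intermediates and net-flux support disjointness are enforced by tests on
random reversible models.

**Pathways.** The greedy decomposition repeatedly extracts the
strongest-bottleneck source→sink path (widest-path search), assigns its
bottleneck flux and subtracts, until the total flux is exhausted. For ≤ 12
states an exhaustive simple-path enumeration with bottleneck capacities on
the unmodified net-flux graph serves as the reference; path probabilities
are normalized path fluxes in both modes. Endpoint macrostates for
reporting are named `SA` (highest stationary-weighted backward-committor
density) and `SB` (highest forward-committor density); the source-state
naming rule in the motivating study ("the initial state") is not
operationalizable from a model alone, so this committor-density rule is the
package's documented choice.

# MM/PBSA aggregation

Derived quantities are computed per frame and then summarized, so the
summation identities hold exactly in the averages:
`ΔG_gas = ΔE_ele + ΔE_vdW (+ ΔE_int)`, `ΔG_sol = ΔG_pb + ΔG_np` (formed on
ingestion when given separately), `ΔG_total = ΔH = ΔG_gas + ΔG_sol`. The
entropy term `−TΔS` is optional and absent by default — published summary
tables routinely omit it — and when supplied yields
`ΔG_bind = ΔH − TΔS`. `ΔE_int` defaults to absent because it cancels in
single-trajectory analyses. The SEM uses the sample standard deviation
(n−1) over `√n`, consistent with published tables at n = 450 frames; with
one frame the SEM is undefined and reported `NA`. Unicode column headers
(`∆E_vdW`, …) are accepted as aliases of the ASCII canonical names.

# Pipeline, problem sizes and determinism

`run_pipeline()` executes declared stages in order from a YAML config in
which every stochastic stage carries an explicit seed, and records a
manifest (file → MD5, seeds) sufficient to reproduce every output
bit-identically. The bundled demo uses a 20,000-frame double-well Langevin
trajectory, four microstates, a lag grid of 1–20 steps and a 450-frame
synthetic energy table — sizes chosen so the full demo completes in well
under a minute per stage on one CPU while leaving the slow process with
hundreds of barrier crossings to estimate from. The test suite uses 10^5
samples where a spec-level sampling bound is asserted (binomial bounds,
implied-timescale recovery within 10%, CK agreement) and smaller sizes
elsewhere.

# Known limitations

- The committor's backward component assumes reversibility (`q⁻ = 1 − q⁺`).
- PCCA+ memberships come from the inner-simplex construction without the
  subsequent objective optimization; for strongly mixed (non-metastable)
  spectra the fuzzy memberships are approximate even though crisp labels
  are robust.
- The synthetic energy components are drawn independently, so derived-term
  variances add; real MM/PBSA components are anticorrelated.
- `vamp2_score()` estimates covariances from a single trajectory with
  sliding windows and no reweighting; scores at long lags on short
  trajectories are biased upward.
- No Bayesian error bars on transition matrices or timescales; validation
  is by the Chapman–Kolmogorov test and lag-convergence heuristics only.
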