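# msmflux

Markov state models, transition-path flux analysis and trajectory
observables for molecular dynamics, in R.

## What problem this solves

Explaining *why* a protein variant behaves differently — for instance why a
glow-type luciferase mutant keeps emitting light while a flash-type mutant
burns out — usually comes down to connecting conformational kinetics to
structure and energetics. The standard analysis chain runs: trajectory
observables (RMSD, R_g, RMSF, SASA, DCCM, pocket distances, helix content)
→ k-means microstate discretization (scored with VAMP-2) → Markov state
model estimation at a lag time τ, validated with implied timescales and the
Chapman–Kolmogorov test → PCCA+ macrostates → transition-path-theory
committors, reactive flux and pathway decomposition → MM/PBSA
binding-energy aggregation. That chain usually lives in a mix of Python
tooling and MD-engine utilities; `msmflux` provides it as one tested R
package, plus synthetic-data generators with analytic ground truth so every
stage is verifiable without running MD.

The core objects and formulas, in the field's standard notation:

- **Transition matrix** `T(τ)` with stationary distribution ρ,
  `ρᵀ T = ρᵀ`; implied timescales `t_i = −τ / ln λ_i`.
- **Chapman–Kolmogorov**: a Markovian model satisfies `T(kτ) = T(τ)^k`;
  the test scores agreement on macrostate self-transitions.
- **Committors**: `q⁺_i` solves the absorbed linear system between a source
  set A and sink set B; `q⁻ = 1 − q⁺` (reversible dynamics).
- **Reactive flux**: `f_ij = ρ_i q⁻_i T_ij q⁺_j`,
  `f⁺_ij = max(f_ij − f_ji, 0)`; pathway probabilities
  `P_i = f_i / Σ_j f_j`.
- **MM/PBSA**: `ΔG_bind = ΔH − TΔS`, `ΔH = ΔE_MM + ΔG_sol`,
  `ΔE_MM = ΔE_ele + ΔE_vdW (+ ΔE_int)`, `ΔG_sol = ΔG_pb + ΔG_np`.

## Worked example

Estimate and validate an MSM from a three-state metastable chain, then run
the flux analysis:

```r
library(msmflux)

T3 <- matrix(c(0.95, 0.04, 0.01,
               0.04, 0.92, 0.04,
               0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
dtraj <- sample_markov_chain(T3, 50000, initial_state = 1, seed = 42)

model <- markov_model(dtraj, lag_steps = 1, reversible = TRUE,
                      frame_spacing_ns = 0.1)
summary(model)
#> Markov state model, 3 states, lag 1 step(s)
#> eigenvalues:  1.0000 0.9361 0.8763
#> implied timescales: 1.514 0.757

ck_test(dtraj, lag_steps = 1, k = 5)
#> Chapman-Kolmogorov test, k = 5, 3 macrostate(s)
#> aggregate agreement: 0.9978

fx <- flux_network(model, committor(model, A = 1, B = 3))
decompose_paths(fx, mode = "exhaustive")
#> path decomposition (exhaustive): total flux 0.0106573, residual 0
#>     path        flux probability
#>  1->2->3 0.006868262   0.6444628
#>     1->3 0.003789082   0.3555372
```

The implied timescales are in ns (lag 1 step = 0.1 ns); the aggregate
Chapman–Kolmogorov agreement of 0.998 (≥ 0.95) confirms the chain is
Markovian at this lag, as it must be by construction. The flux
decomposition says 64% of the reactive 1→3 current passes through the
intermediate state, the rest jumping directly.

Aggregating published-style MM/PBSA component rows reproduces the derived
rows exactly:

```r
aggregate_energy(data.frame(dE_vdw = -65.4621, dE_ele = -106.6130,
                            dG_solv = 125.5495))
#> MM/PBSA summary over 1 frame(s) (kcal/mol)
#>  Energy Component   Average Std. Dev. Std. Err. of Mean
#>            dE_vdw  -65.4621    0.0000                 -
#>            dE_ele -106.6130    0.0000                 -
#>            dG_gas -172.0751    0.0000                 -
#>           dG_solv  125.5495    0.0000                 -
#>          dG_total  -46.5256    0.0000                 -
```

An end-to-end run on a synthetic double-well system (Langevin trajectory →
k-means → MSM → PCCA+/TPT → energetics → report) ships as a config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "msmflux"),
             "demo-out")
```

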