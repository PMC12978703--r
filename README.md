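# msmflux

Markov state model (MSM) analysis of ligand translocation kinetics from
ensembles of short molecular-simulation trajectories.

Membrane proteins that shuttle lipidic ligands — sterols crossing a receptor
between membrane leaflets and internal binding sites being the motivating
case — operate on millisecond timescales that no single simulation reaches.
The field's answer is to run many short, adaptively seeded trajectories and
stitch their statistics together with an MSM: a row-stochastic transition
matrix `T(τ)` between `k` conformational microstates whose stationary
distribution `π` (with `π T = π` and detailed balance
`π_i T_ij = π_j T_ji`) recovers equilibrium thermodynamics from
far-from-equilibrium sampling, and whose spectrum yields kinetics. On top of
the MSM, transition path theory (TPT) gives committors `q⁺`, reactive fluxes
`f_ij = π_i q⁻_i T_ij q⁺_j`, rates and mean first passage times (MFPTs).

`msmflux` implements this entire analysis chain for R, with every estimator
testable against analytic ground truth:

- **Synthetic ground truth** — overdamped Langevin simulator (compiled) on
  analytic potentials: quartic double wells, a two-channel translocation
  landscape with exact per-channel saddle heights, tabulated 1D landscapes,
  plus discrete Markov-chain and Ornstein–Uhlenbeck feature generators and
  a synthetic-pore PDB builder.
- **Featurization** — centres of mass, ligand tilt angle with the membrane
  plane (`asin(v_z/|v|)`, ±90° conventions), minimum group distances.
- **tICA** — time-lagged independent component analysis with symmetrized
  (reversible) covariance estimation, ridge regularization, and
  trajectory-aware lagged pairs.
- **Discretization** — Lloyd and mini-batch k-means with k-means++
  initialization, and least-counts adaptive-sampling seed selection.
- **MSM estimation and validation** — sliding-window counts, connectivity
  trimming, reversible maximum-likelihood estimation (compiled fixed
  point), implied timescales, VAMP2 model selection (sum of squares of the
  top five eigenvalues), trajectory-level bootstrap (default 200 rounds ×
  80%), Chapman–Kolmogorov tests.
- **Thermodynamics** — MSM-reweighted 1D/2D free-energy surfaces (frame
  weight `π_s / N_s`), bootstrap errors, minimax ("lowest highest-energy")
  paths with barrier extraction, Welch-test barrier comparison.
- **Kinetics** — TPT committors, flux networks, rates, MFPTs with
  bootstrap errors.
- **ABF** — 1D adaptive-biasing-force PMF estimation with harmonic walls
  (default 45 kcal/mol/Å², 3 replicates) and peak-PMF comparison between a
  reference and a perturbed landscape.
- **Tunnel profiling** — sphere-probe channel radius profiles of PDB
  structures along the z axis (Bondi radii, multi-start per-slice
  optimization), with sphere-per-slice PDB export.

## Worked example

The bundled pipeline emulates a two-pathway translocation study: a 2D
landscape with two channels of unequal barrier (5.8 and 6.5 kcal/mol —
the two pathway barriers the analysis is designed to resolve) at
kT = 0.616 kcal/mol (310 K), sampled by 100 short trajectories (a
stage-seeded ladder along both channels plus least-counts adaptive
rounds), then analysed end to end:

```r
library(msmflux)
res <- run_pipeline(default_pipeline_config(master_seed = 1L))
print(res)
#> Translocation pipeline result
#>   trajectories: 100; active states: 100
#>   channel barriers: a = 5.76, b = 6.80 kcal/mol (p = 4.34e-106)
#>   MFPT forward 4.367e+04, reverse 3.725e+04 (frame-time units)
```

The reweighted free-energy surface recovers both channel barriers within
half a kcal/mol of the constructed truth (5.8, 6.5) and resolves their
ordering: the bootstrap barrier distributions differ by about 1 kcal/mol
with a vanishing Welch p-value, and the forward and reverse MFPTs between
the two (symmetric) end basins agree to within the expected statistical
spread. `res$fes` holds the surface, `res$tpt` the committors, fluxes and
MFPTs, and `pipeline_report(res, "report.txt")` writes a plain-text
summary. The run takes a few minutes on one core.

Individual estimators work standalone, e.g.

```r
m <- estimate_reversible(count_transitions(make_markov_chain(
       matrix(c(.9, .1, .1, .9), 2, byrow = TRUE), 1e5), lag = 1))
model_timescales(m, 1)   # ~4.48 frames = -1/ln(0.8)
vamp2_score(m)           # ~1.64
```

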