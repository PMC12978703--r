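---
title: "Methods: Markov state models of ligand translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov state models of ligand translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msmflux)
```

This vignette is the package's account of its science: the models and
estimators, the assumptions behind them, the parameters that matter, what
the synthetic data emulate (and do not), and the numerical choices made
where the design was genuinely open.

## The problem

A lipidic ligand translocating through a membrane receptor — from either
membrane leaflet to an internal binding site — crosses free-energy barriers
of several kcal/mol, making the process a rare event on simulation
timescales. The established strategy is statistical: run many short
trajectories from adaptively chosen starting points, discretize
conformational space into microstates, and estimate a Markov state model
(MSM) whose stationary distribution recovers equilibrium thermodynamics
from deliberately non-equilibrium sampling. Everything downstream —
free-energy surfaces, barriers, committors, fluxes, first-passage times —
derives from that model. `msmflux` implements the chain end to end with a
synthetic simulator supplying exact ground truth at every step.

## Units and physical constants

Lengths are in ångström, time in nanoseconds, energies in kcal/mol, angles
in degrees. The Boltzmann constant is 0.0019872041 kcal/mol/K, so the
package-wide default thermal energy is `kT_at(310) = 0.61603` kcal/mol —
physiological temperature.

## The synthetic simulator

Dynamics are overdamped (Brownian) Euler–Maruyama:
`x ← x − (D/kT) ∇U dt + sqrt(2 D dt) η`. Inertia is irrelevant for the
configurational observables studied here, which is why the underdamped
variant was not implemented. Reflecting walls at the declared domain
boundaries conserve probability, so long runs sample `exp(−U/kT)` exactly
(a χ² test against the Boltzmann histogram is part of the test suite).
Defaults `D = 1 Å²/ns` (a lipid-like diffusion coefficient) and
`dt = 0.005 ns` keep the per-step drift well below the smallest landscape
feature; the simulator warns when the diffusive step approaches a tenth of
the domain.

The two-channel landscape `U(s, w)` is the central fixture. `s` is
translocation progress, `w` the channel coordinate. The channel structure —
an inter-channel quartic ridge and a smoothstep interpolation of the
saddle height between `barrier_b` (channel B, `w < 0`) and `barrier_a`
(channel A, `w > 0`) — is multiplied by a *flat-topped* envelope
`exp(−s⁴/2σ_s⁴)`, so both channels emerge from shared start and end
basins, as they do in the biological system where both pathways connect
the membrane to the same binding site. Two deliberate choices live here.
First, the smoothstep has zero slope at the channel centres, which makes
the saddle heights exactly the requested barriers; a dense-grid minimax
search verifies the stored truth to 10⁻³ kcal/mol in the tests (the
envelope leaves a residual basin floor of `barrier × g(s_half)`, ~10⁻³
kcal/mol at the defaults, which the stored truth accounts for). Second,
the flat top matters for estimator fidelity: a knife-edge (Gaussian)
saddle is read through microstates that straddle its slope, and with 100
states the within-state distribution of adaptively seeded frames biases
the reweighted barrier by up to ~1 kcal/mol; over an extended flat
bottleneck corridor — arguably the more realistic picture of a ligand
sliding through a protein tunnel — the top states span negligible energy
and the estimator reads the true height. Defaults 5.8 and 6.5 kcal/mol
are the two translocation-pathway barriers this analysis is designed to
resolve; `σ_s = 1.6 Å`, domain half-width 3.2 Å.

Other generators: quartic double wells (optionally tilted to stabilise the
product basin — the fixture for forward/reverse MFPT asymmetry),
tabulated 1D landscapes (the four-well fixture for model selection),
discrete Markov chains (exact oracles for every MSM estimator),
Ornstein–Uhlenbeck mixtures with known relaxation times (the tICA oracle:
at lag `L` the true eigenvalues are `exp(−L/τ_c)`), and ring-built pore
structures with exact clearance truth for the tunnel profiler. One master
seed drives everything; per-stream seeds derive from it by a fixed hash
(`derive_seed`), never from the clock.

## Sampling protocol

`run_pipeline` emulates the adaptive protocol of large translocation
studies. A stage-seeded block (default 80 of 100 trajectories) starts
trajectories on both channel centrelines at rungs spaced uniformly in `s`
across the saddle plateau and flanks, mirrored on both sides of the
barrier — the synthetic analogue of production runs launched from
steered-MD structures placed along the pathway. Symmetric, dense rungs
are what keep the barrier top populated on both of its sides; an
asymmetric or sparse ladder directly biases the cross-barrier
free-energy difference. The remaining trajectories run in least-counts
adaptive rounds: cluster everything sampled so far (k-means while the
pool is small, mini-batch k-means beyond 3×10⁵ frames), rank clusters by
ascending population, and restart from frames drawn from the rarest
clusters — the standard exploration heuristic, which here keeps
re-seeding the barrier region automatically.

Trajectories are 2×10⁵ steps each, saved every 4 steps (`thin = 4`,
0.02 ns/frame). The fine saving matters: uphill moves against the
descent drift are only visible when the lag is comparable to the
per-frame diffusion length, and those apparent "uphill" transitions are
what make the transition counts bidirectional along the barrier flanks.

What the emulation does **not** reproduce: real MD has hundreds of
coupled degrees of freedom, anisotropic and position-dependent diffusion,
and featurization error; trajectories here live directly on the 2D model
landscape. Passing tests therefore demonstrate the correctness of the
estimators under known conditions, not the adequacy of any particular
featurization of real data.

## tICA

Time-lagged independent component analysis solves the generalized
eigenproblem `C_τ v = λ C_0 v` over lagged frame pairs formed strictly
within trajectories. Estimation is symmetrized (reversible): the mean and
instantaneous covariance pool both ends of every pair and `C_τ` is
symmetrized, which bounds eigenvalues by 1 in exact arithmetic; estimated
values are clipped to `[−1, 1]` with a warning beyond 10⁻⁶. A ridge
`ε = 10⁻⁶ tr(C_0)/p` (configurable) keeps duplicated or constant features
harmless. Plain tIC projection is the default; kinetic-map scaling (by
eigenvalues) is available via `kinetic_map = TRUE`. The tICA lag is an
explicit argument everywhere — there is no sensible universal default, so
the pipeline config carries it (default 60 frames = 1.2 ns for the bundled
emulation).

## Discretization

`kmeans_fit` is Lloyd's algorithm from k-means++ seeding with two contract
details the tests rely on: assignment ties break to the lowest centre
index, and an emptied cluster is re-seeded at the point farthest from its
assigned centre. On pools above 2×10⁵ points the k-means++ pass runs on a
seeded subsample (the Lloyd iterations still see all data).
`minibatch_kmeans_fit` uses per-centre learning rates `1/count` and a
final full-data assignment. `least_counts_select` ranks non-empty clusters
by ascending population (ties by index) and draws one frame per cluster,
round-robin, uniformly without replacement.

Plain k-means allocates centres in proportion to data density, which
leaves rarely visited regions — barrier tops, exactly where adaptive
sampling spends least time — as single huge states. `flattened_kmeans`
therefore clusters a subsample that contributes the same number of
frames from every occupied cell of a coarse grid over the projected
space, then assigns all frames to the resulting centres: the centres
spread roughly uniformly over *visited* space and the transition region
is resolved at the same length scale as the basins. The pipeline builds
three such layouts (different derived seeds) and averages the barrier
readings over them, which damps the residual sensitivity of the reading
to where state boundaries happen to fall.

## MSM estimation

Counts are sliding-window pairs `(t, t+τ)` within trajectories. The
reversible maximum-likelihood transition matrix comes from the classical
fixed point on symmetric auxiliary variables
`x_ij ← (c_ij + c_ji) / (c_i/x_i + c_j/x_j)` (compiled; convergence
criterion: max relative change < 10⁻¹⁰ by default, capped at 10⁶ sweeps
with an error on failure). π is the normalized row sum of `x`; detailed
balance holds by construction to round-off (< 10⁻¹⁰ asserted in tests,
achieved ~10⁻¹⁶).

Connectivity: `largest_connected_set` returns the largest strongly
connected component of the directed count graph (ties to the lowest state
index). The *estimator*, however, trims to the largest component of the
symmetrized graph `C + Cᵀ`: detailed balance supplies the reverse rate of
any observed transition, so a state pair is estimable from counts in
either direction. The distinction matters for barrier states fed by
descent-dominated adaptive seeding, where forward and backward counts can
be very unbalanced; requiring strong directed connectivity would discard
exactly the states the analysis needs. For equilibrium-sampled data the
two sets coincide.

The pipeline estimates its production MSM at lag 2 saved frames
(0.04 ns) with a relaxed fixed-point tolerance of 10⁻⁶ — weakly coupled
saddle states make the final decades of the fixed point extremely slow
while leaving π stable far beyond the accuracy the barriers need. The
short lag is a deliberate choice: implied timescales do not strictly
converge at this state resolution (descent-dominated counts decay with
lag, drifting the readings upward), and the pipeline's target quantity
is thermodynamic — π — for which the shortest bidirectionally connected
lag maximizes the usable statistics. Kinetic quantities from the same
model are order-of-magnitude estimates, and the dedicated kinetics
criteria use exact discrete-chain fixtures instead. Validation tooling: implied
timescales `t_i = −τ/ln λ_i` versus lag (values above `1 − 10⁻¹²` report
∞), VAMP2 (sum of squares of the top five transition-matrix eigenvalues,
computed on full data as is conventional when comparing discretizations of
the same data), whole-trajectory bootstrap (resampling trajectories, not
frames, to respect temporal correlation; default 200 rounds at 80%), and
Chapman–Kolmogorov tests comparing `T(τ)^k` set-to-set probabilities with
re-estimated models at `kτ`, banded by a trajectory bootstrap.

## Free-energy surfaces and barriers

Each frame in an active state `s` gets weight `π_s / N_s`; binned masses
give `F = −kT ln(mass)`, min-shifted. Bins are half-open with the last
closed; empty bins are `NA`, never infinite. Frames in states outside the
active set are dropped and the fraction recorded. Bootstrap errors are
per-bin standard deviations after per-round min-shifting (free energies
are gauge-fixed per round, so constant offsets between rounds do not count
as error); bins defined in under half the rounds are undefined.

"Minimum energy path" is operationalized as the *minimax* path — the path
minimizing the maximum free energy encountered (widest-path Dijkstra over
8-connected defined bins, cumulative-sum tie-break) — because the
reported observable is the barrier, and the minimax value is exactly the
saddle a transition must cross. A threshold-bisection flood-fill variant
computes barrier values without paths; it is provably equivalent (asserted
against the path search and against brute-force enumeration on small
grids) and fast enough for 200-round bootstrap loops. Barrier
significance uses a two-sided Welch t-test on the bootstrap barrier
samples — a reasonable choice where the original analysis reports a
p-value without naming a procedure; it is documented as this package's
choice. The default grid for the bundled emulation is 32 × 20 bins with
a minimum of 2 frames per defined bin (single-frame bins have enormous
free-energy variance and can fake low passes through high ridges); if
the masked path search cannot connect the basins at that threshold the
pipeline falls back to counting every frame and then to a half-resolution
grid — the plateau-topped saddle makes the coarser read nearly unbiased.
Bootstrap rounds reuse a precomputed bin-by-state frame histogram, which
is algebraically identical to re-binning per round and is unit-tested
against the reference route.

## Kinetics

Committors solve the standard boundary-value linear system; backward
committors use `q⁻ = 1 − q⁺` (valid for reversible models). Gross
reactive flux is `f_ij = π_i q⁻_i T_ij q⁺_j`, net flux its positive
antisymmetric part, the rate `F / (τ Σ_i π_i q⁻_i)`. MFPTs solve
`m = τ + T m` outside the target set; the reported value averages over the
source set under π restricted to that set (an explicit choice — a uniform
start distribution would be equally defensible; stationary restriction
matches how an equilibrium ensemble enters the source states). Bootstrap
MFPTs skip (and count) rounds where the sets fall outside a round's
active set.

## ABF

The 1D adaptive-biasing-force sampler accumulates the running mean force
per bin and applies minus that estimate as bias, ramped linearly until 200
samples per bin to avoid amplifying the noisy early estimate — standard
ABF practice. Harmonic walls (default 45 kcal/mol/Å², the conventional
wall stiffness for translocation PMFs) confine the collective variable.
The PMF is minus the trapezoid integral of the final mean force,
min-shifted; never-visited bins stay undefined. Three replicates with
derived seeds report a per-bin spread. In this overdamped 1D setting the
instantaneous CV force equals the systematic force exactly, so the
estimator is very low-variance; on real systems the thermal projection
term would add noise. The "mutant" in `delta_peak_pmf` comparisons is a
parametric perturbation of the model potential (e.g. a raised saddle)
standing in for a mutated molecular system.

## Tunnel profiling

Per z-slice, the probe centre maximizes the clearance
`min_i(‖p − a_i‖ − vdW_i)` with full 3D distances, warm-started from the
previous slice and refined by five seeded Nelder–Mead restarts (guarding
against off-axis channels); radii clamp to `[0, r_max]` (default 15 Å,
slices at the cap flagged). Bondi radii (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20, P 1.80) with a warned 1.70 fallback; water and ion residues are
excluded before profiling. A geometric subtlety the synthetic truth must
respect: neighbouring rings of a narrowing pore also constrain the probe
in 3D, so the exact on-axis clearance is
`min_j sqrt(R_j² + Δz_j²) − vdW`, slightly below the local ring clearance
— the generator stores both.

## Problem sizes and reproducibility

The bundled emulation uses 100 trajectories × 2×10⁵ steps (5×10⁶ saved
frames), 100 MSM states over three clustering layouts, 200 bootstrap
rounds; the ABF fixture uses 10⁶ samples × 3 replicates; oracle chains
use 10⁵–10⁶ steps. These sizes give each estimator enough statistics to
meet its stated tolerance while a full pipeline run completes in about
four minutes on one core. At this sampling budget the recovered channel
barriers carry an uncertainty of roughly ±0.3–0.5 kcal/mol per master
seed (the barrier ordering and its Welch test are far more robust than
the absolute heights). Every stochastic
stage is a pure function of (parameters, derived seed); reruns with the
same master seed are bit-identical, which the integration tests assert.

## Known limitations

- No periodic-boundary handling in distance features (synthetic systems
  are non-periodic; real MD input would need pre-imaging).
- No binary MD format readers; coordinates enter as CSV/tables.
- Barrier recovery at β·ΔU ≈ 10 depends on the seeding protocol
  supplying barrier-region frames; purely basin-seeded unbiased sampling
  of this landscape would need orders of magnitude more data.
- Committor/flux formulas assume a reversible model; applying them to a
  non-reversible estimate would require the generalized backward
  committor.
- No hidden-Markov or PCCA+ coarse-graining; macrostates are defined by
  the caller (typically from free-energy minima).
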