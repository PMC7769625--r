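---
title: "Methods: the expanded stellate-cell model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the expanded stellate-cell model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cerebellar stellate cells (CSCs) are spontaneously active inhibitory
interneurons that normally fire tonically but can burst when specific ionic
currents are blocked or potentiated pharmacologically. `cscburst`
implements an expanded Hodgkin–Huxley description of a CSC with seven
ionic currents and cytosolic calcium handling:

$$C \dot V = I_{\mathrm{app}} - I_{\mathrm{Na}} - I_K - I_L - I_A - I_T -
I_{K(\mathrm{Ca})} - I_{\mathrm{HVA}}$$
$$\dot x = \frac{x_\infty(V) - x}{\tau_x}, \qquad
x \in \{h, n, n_A, h_A, h_T, m_{\mathrm{HVA}}\}$$
$$\dot{Ca} = -\varepsilon\left(\alpha (I_T + I_{\mathrm{HVA}}) + k\,Ca\right)$$

with

* $I_{\mathrm{Na}} = g_{\mathrm{Na}} m_\infty^3 h (V - E_{\mathrm{Na}})$ —
  transient sodium, activation instantaneous;
* $I_K = g_K n^4 (V - E_K)$ — delayed rectifier,
  $\tau_n(V) = 6/(1 + e^{(V+23)/15})$ ms;
* $I_L = g_L (V - E_L)$ — leak;
* $I_A = g_A n_A h_A (V - E_K)$ — A-type potassium;
* $I_T = g_T m_{T,\infty} h_T (V - E_{\mathrm{Ca}})$ — T-type calcium,
  activation instantaneous;
* $I_{\mathrm{HVA}} = g_{\mathrm{HVA}} m_{\mathrm{HVA}} (V - E_{\mathrm{Ca}})$
  — high-voltage-activated calcium, first-order activation with
  $\tau = 4$ ms;
* $I_{K(\mathrm{Ca})} = g_{K(\mathrm{Ca})}
  \frac{Ca^5}{k_{\mathrm{Ca}}^5 + Ca^5}(V - E_K)$ — calcium-activated
  potassium, gated by a fifth-order Hill function of cytosolic calcium
  ($k_{\mathrm{Ca}} = 0.45\ \mu M$).

Every gate follows a Boltzmann steady state
$x_\infty = 1/(1 + e^{-(V - v_x)/s_x})$. Sodium inactivation has the
voltage-dependent Lorentzian time constant
$\tau_h(V) = y_0 + \frac{2A}{\pi}\frac{w}{4(V - V_c)^2 + w^2}$, peaked at
$V_c = -74$ mV (4.56 ms) with floor $y_0 = 0.1$ ms. The calcium equation
balances influx through the two calcium currents (conversion factor
$\alpha = 0.018\ \mu M\,\mathrm{cm}^2/(\mu A\,\mathrm{ms})$) against linear
extrusion at rate $k = 0.1\,\mathrm{ms}^{-1}$, the whole equation scaled by
$\varepsilon = 0.015$; the effective calcium time constant,
$1/(\varepsilon k) \approx 667$ ms, makes $Ca$ the slowest variable.

Two builtin gating variants, `csc_params("pre")` and `csc_params("post")`,
reflect *runup* — the gradual increase of excitability during whole-cell
recording: the post-runup variant shifts sodium activation/inactivation and
A-type parameters toward more hyperpolarized values, lowering the firing
threshold and raising the spontaneous rate. Unless noted, analyses default
to the post-runup variant (the chronically recorded state), and where the
literature on this cell type is ambiguous about which variant a bursting
protocol used, we expose both and test both.

Units follow the model's original calibration throughout: conductances in
$\mu S\,\mathrm{cm}^{-2}$, currents in $\mu A\,\mathrm{cm}^{-2}$,
potentials in mV, time in ms, calcium in $\mu M$. `I_app` defaults to 0 —
the cell is spontaneously active.

Ambiguities we had to resolve once and keep fixed: the printed form of
$\tau_h$ is read as the standard Lorentzian peak above (the only reading
consistent with $A$ carrying units of ms·mV); the calcium-equation term
"$kCa$" is read as the product $k \cdot Ca$ (the Hill constant
$k_{\mathrm{Ca}}$ appears only inside the Hill function; the product is the
only reading with a bounded calcium equilibrium); $m_{\mathrm{HVA}}$ is a
dynamic first-order gate (it has a printed time constant) while the sodium
and T-type activations are instantaneous; the A-type activation $n_A$ is
dynamic with $\tau = 5$ ms.

## Numerics

Integration uses `deSolve`'s lsoda with the right-hand side compiled in C,
relative and absolute tolerances $10^{-8}$, and dense output every 0.02 ms
by default — fine enough that successive samples on an action-potential
upstroke differ by under 2 mV. A pure-R right-hand side and a hand-derived
analytic Jacobian mirror the C code; the test suite cross-checks all three
(C against R along trajectories, Jacobian against central finite
differences entry-wise). Long parameter sweeps sample at 0.1 ms, which is
still ~50 samples per spike width. Halving the tolerances moves spike
times of a 1.5 s tonic trace by well under 0.5 ms.

Equilibria are never found by generic root searching in eight dimensions:
at a fixed point all gates sit on their Boltzmann curves and
$Ca^\ast = -\alpha (I_T + I_{\mathrm{HVA}})/k$, so the system reduces to a
single current-balance equation in $V$, bracketed on a dense grid over
$[-120, 20]$ mV and polished by Brent's method. This closed-form reduction
doubles as the independent oracle for the continuation code: every tenth
continuation point is required to match a reduction root to $10^{-8}$ mV.

Pseudo-arclength continuation (predictor–corrector with QR-based tangents,
adaptive step in normalized parameter units, initial step $10^{-3}$,
bounds $[10^{-6}, 5 \cdot 10^{-2}]$, halving on Newton failure) traces
equilibrium branches of the full system and of the fast subsystem.
Saddle-nodes are detected by a determinant sign change and refined by
bisection on that sign with Newton re-solves; Hopf points by a sign change
of the largest real part over complex eigenvalue pairs, certified by
$|\mathrm{Re}| < 10^{-5}$ with nonzero imaginary part. Eigenvalues below
$10^{-9}$ in modulus are treated as zero for saddle-node certification.

## Slow–fast dissection

$h_A$ and $Ca$ vary least along trajectories and are treated as frozen
parameters of the six-variable *fast subsystem*. Its equilibrium surface
over the $(h_A, Ca)$ plane — the critical manifold — is computed by the
same scalar reduction per grid node (default 201 × 81 nodes over
$[0,1] \times [0, 0.8]\ \mu M$; the desk-scale tests use coarser grids
focused on the fold region, 61 × 23). Root counts per node are 1 or 3;
fold curves are the loci where the count changes, and the Hopf locus is
tracked along the upper sheet. Canonical one-dimensional slices use
$Ca = 0.25\ \mu M$ (an alternative 0.2 appears in parts of the source
material; both are exercised in tests, 0.25 is the default).

Periodic orbits of the fast subsystem are continued in $h_A$ by single
shooting: unknowns (initial state, period, parameter), equations
(periodicity, a phase anchor orthogonal to the flow, pseudo-arclength).
The monodromy matrix comes from central-difference variational probes at
integration tolerance $10^{-10}$; the trivial Floquet multiplier is
monitored at every point and a step is rejected if it strays more than
$5\times10^{-3}$ from 1. Families are seeded either from a certified Hopf
point (linear eigenplane predictor, trying both sides — subcritical Hopfs
carry their orbits on the stable side) or from direct simulation where a
stable spiking orbit exists. Saddle-nodes of periodic orbits are reported
at parameter folds of the branch, period-doublings where a real multiplier
crosses $-1$.

**Homoclinic approaches.** Near a homoclinic connection the period grows
only logarithmically in the parameter distance while the orbit's largest
multiplier grows like $e^{\lambda_u T}$, so single shooting loses the
problem long before the period has grown by an order of magnitude. We
therefore declare a homoclinic approach when the continuation stalls
(step-size collapse or loss of progress) with the period still growing
monotonically and the orbit passing within 2 mV of a saddle equilibrium of
the fast subsystem. The 2 mV proximity band is calibrated to where the
shooting conditioning collapses in this model; collocation-based
continuation, which would sharpen these events into true connection
detections, is deliberately out of scope. `count_fast_homoclinics()`
automates the census at fixed $Ca$: equilibrium branch → certified Hopfs →
orbit families continued both ways → simulation probes between the folds
for isolated families → deduplicated homoclinic events.

## Feature extraction and regime labels

Spikes are maxima of supra-threshold excursions (default threshold
$-20$ mV, minimum separation 2 ms — calibrated to the model's
action-potential amplitudes). Bursts split at inter-spike gaps exceeding
3× the median ISI; a train with a single gap class is one "burst". All
feature extraction discards a transient (25% of the trace, at least 500 ms
when the trace allows) and analyzes the last 80% of the remainder.

Regime labels: convergence to a fixed point above $-40$ mV is `ESS`
(depolarization block), at or below it `Q`; spiking with one gap class and
no post-spike plateau is `T`; bursting with a non-repeating
spikes-per-burst sequence is `CB`; bursts whose active phase ends in a
spike-free depolarized segment — at least 20 ms above $-45$ mV before
repolarization — are `PB`; remaining repeating multi-spike bursts are
`SW`. The plateau criterion is the operational separator of square-wave
from pseudo-plateau morphology; no quantitative cutoff exists in the
literature for this cell type, so the level ($-45$ mV) and duration
(20 ms) were calibrated once against this model's plateau cycles, whose
spike-free segments drift from about $-32$ to $-41$ mV for hundreds of
milliseconds — well clear of both tonic afterhyperpolarizations (which
drop below $-45$ mV within a few ms of the spike) and of the 20 ms
minimum. Single-spike cycles followed by such a plateau are also `PB`: the
fold/sub-Hopf mechanism does not guarantee more than one clean spike per
active phase.

Chaotic-bursting evidence is the non-repeating count sequence plus the ISI
return map's dispersion (RMS distance from the diagonal over the mean
ISI), not Lyapunov exponents — cheaper and directly comparable with the
published return-map evidence for this cell type.

## The surrogate generator

`generate_surrogate_trace()` emulates whole-cell voltage recordings with
known ground truth: Gaussian-bump spikes (default 70 mV amplitude, 1.2 ms
width) on a $-62$ mV baseline, organized into bursts with configurable
counts, intra-burst ISI (10 ms) and gaps (400 ms), optional decaying
amplitudes into a depolarized plateau for pseudo-plateau morphology, and
additive Gaussian measurement noise (deterministic given a seed, with the
global RNG stream left untouched). Decaying amplitudes are floored so
every constructed spike peaks above $-15$ mV, keeping the construction
detectable by the default detector — the generator's contract is that
detection recovers its ground truth exactly (F1 = 1) for noise up to 2 mV
SD. What it does not emulate: electrode artifacts, seal/access resistance,
drift, or process noise in the dynamics; passing the detector tests
therefore certifies the extraction pipeline on clean-to-moderately-noisy
morphology, not robustness to pathological recordings.
`generate_noisy_model_trace()` adds measurement noise to model output only
— the model's irregular-bursting claims are noise-independent, so no
stochastic terms enter the dynamics.

## Regime maps

`regime_sweep()` classifies every node of a two-parameter grid, visiting
cells in serpentine order with each integration started from the previous
cell's final state — the standard attractor-inheritance device for
following bursting branches through bistable windows (stable burst orbits
here live on isolas, which a fixed initial condition would miss). An
optional second pass from a fixed default state flags cells where the two
passes disagree as bistable. Per-cell failures are labelled and skipped,
never fatal.

## Design choices at genuinely open points

* The bursting literature for this cell type is internally inconsistent
  about which runup variant produced its square-wave examples; we follow
  the post-runup reading for acceptance computations and exercise both
  variants in tests.
* Where the square-wave analyses leave $g_{\mathrm{HVA}}$ unstated, we use
  0.249 $\mu S\,\mathrm{cm}^{-2}$ (the documented square-wave value) with
  all other conductances at their defaults; this is a configuration
  default, not a fitted quantity.
* Full-system periodic-orbit isolas are not continued by collocation;
  stable envelopes are traced by simulation with inherited initial
  conditions and hysteresis probing. Matching industrial-strength
  boundary-value continuation is out of proportion to what the package
  certifies.
* Hold-and-release protocols initialize at the conditional steady state of
  the clamped system rather than simulating an electrode clamp — exact
  determinism traded for protocol realism.
* Synaptic inputs are alpha-function conductances
  ($\tau_{\mathrm{exc}} = 1$ ms, $\tau_{\mathrm{inh}} = 5$ ms,
  $E_{\mathrm{exc}} = 0$, $E_{\mathrm{inh}} = -80$ mV, inhibition leading
  by 5 ms); all are configuration-exposed defaults.

## Known limitations

With the default (printed) parameter set, the frozen-slow-variable fast
subsystem retains at least one stable equilibrium at every $(h_A, Ca)$
node we probed, in both runup variants; no stable fast-subsystem spiking
orbit (isolated or otherwise) exists. The dynamical consequences are
faithful to that structure: the package reproduces tonic firing, type-I
(SNIC) excitability with square-root frequency scaling, the non-monotonic
first-spike latency profile, the slow Hopf pair in $g_{K(\mathrm{Ca})}$
(upper point near 18.5 $\mu S\,\mathrm{cm}^{-2}$), the single-spike to
two-spike adding cascade below that Hopf, fold-initiated pseudo-plateau
burst cycles with calcium rising in active and falling in silent phases,
depolarization block at high $g_{\mathrm{HVA}}$, and one fast-subsystem
homoclinic approach (from the upper-branch Hopf family) at
$Ca = 0.25\ \mu M$. It does **not** regenerate multi-spike square-wave
bursting at the parameter points where such bursting has been described
for this cell type (those points settle on a stable equilibrium or on
plateau cycles here), the associated 14/10 spikes-per-burst counts, the
three coexisting homoclinics, or label-level chaotic bursting; a
20-variant single-parameter sensitivity screen did not locate a plausible
transcription change that restores them. The acceptance suite asserts
those properties anyway and reports the measured values, so the gap is
visible rather than papered over.

Problem sizes used by the shipped tests and the acceptance script (chosen
as desk-scale defaults): 3–20 s simulations at 0.02–0.1 ms output
resolution, continuation branches of 50–800 points, orbit families capped
at 120–400 points, manifold grids of 61 × 23 nodes, and sweeps of at most
a few dozen cells.
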