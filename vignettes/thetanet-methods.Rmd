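---
title: "Spike-response noise entropy in chaotic balanced networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-response noise entropy in chaotic balanced networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `thetanet`, the
numerical and statistical choices the package makes, and the places where
those choices were genuinely open. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The model

Each of `N` neurons carries a phase `theta_i` on the unit circle, with a
spike at the crossing of `1 ~ 0`. This is the theta neuron, the phase form
of the quadratic integrate-and-fire cell (for a membrane time constant of
10 ms, one time-unit (tu) corresponds to roughly 125 ms). The drift of
cell `i` is

    F(theta_i) + Z(theta_i) * [ sum_j a_ij g(theta_j)
                                + (eps^2/2) Z'(theta_i) + eta ]

with multiplicative noise `eps * Z(theta_i) dW_i`, where `F = 1 +
cos(2 pi theta)` and `Z = 1 - cos(2 pi theta)`. `Z` is the phase-response
curve: it vanishes at the spiking phase, so a cell about to spike is
insensitive to any input, and the flow there has speed exactly 2. The
`eps^2/2` term is the Ito correction that makes the noise term equivalent
to a Stratonovich (physical-limit) forcing.

The external input `I_i = eta + eps dW_i/dt` is *quenched*: one frozen
realization of `N` independent white-noise paths is shared bit-identically
by every trial. The system is therefore treated as a random dynamical
system — trial-to-trial variability comes exclusively from initial
conditions, and the entropy of the cross-trial spike-word distribution is
a *noise entropy*, conditioned on the input.

Connectivity is sparse and balanced: 80% of cells are excitatory, 20%
inhibitory (deterministic first-80% assignment; random labels would be
statistically identical and are harder to test). Every ordered pair with
presynaptic cell in population `P` is wired independently with probability
`kappa / N_P`, so each neuron receives on average `kappa` excitatory and
`kappa` inhibitory inputs; realized weights have magnitude `4 / kappa`
(0.2 at the default `kappa = 20`) with the presynaptic population's sign.
Self-connections are excluded.

## The synaptic pulse and its normalization

The coupling function `g` is a smooth bump of half-width `b = 1/20`
centered on the spiking phase, `g(x) ∝ (1 - (x/b)^2)^3`, mimicking the
rapid rise and fall of a synaptic current; it is twice continuously
differentiable at its support edges, which matters because the Lyapunov
analysis differentiates it.

The *scale* of `g` is the one genuinely underdetermined constant in the
printed model, and it controls everything: the literal printed form
`d (b^2 - x^2)^3` with `d = 35/32` integrates to about `1e-9` and would
decouple the network entirely, while the unit-phase-integral reading
`(d/b)(1 - (x/b)^2)^3` turns out to over-drive it. We resolved the
ambiguity against the model's published operating points. Treating the
recurrent input as shot noise with per-spike charge `q = a * c_g / 2`
(a presynaptic phase traverses the support at speed 2, so the delivered
charge is the weight times half the phase integral `c_g` of `g`), the
effective input variance added by the network is `q^2 * 2 kappa r`. A
Fokker-Planck quadrature for the driven single cell then converts any
candidate `c_g` into predicted firing rates. Requiring the network to
reproduce its published fixed-rate operating points — 0.820 spikes/tu at
(eta, eps) = (-1, 0.69), (-0.5, 0.5) and (0.07, 0), the last of which
isolates the recurrent contribution completely because the external
fluctuation is switched off — selects `c_g = 1/2`:

* `c_g = 1` (unit integral) simulates to rates 1.07 / 1.15 / 1.34 at the
  three points — 30-60% high everywhere;
* `c_g = 1/2` simulates to 0.78 / 0.80 / 0.81 — within a few percent of
  0.820 at all three.

The package therefore fixes `g(x) = (d/(2b))(1 - (x/b)^2)^3`: phase
integral exactly 1/2, charge `a/4` per spike. This constant was chosen
once, from the rate surface alone, and is not revisited; the residual ~2%
rate deficit at the standard operating point is reported as-is by the
acceptance machinery. All downstream quantities (entropies, correlations,
Lyapunov spectra) are genuine predictions of the calibrated model, not
fitted.

## Integration

Trials are integrated with Euler-Maruyama at `dt_int` (default 0.002 tu,
`<= dt_bin/10` always), keeping the printed Ito term in the drift; a
higher-order scheme would buy little because the tangent dynamics needs
the identical discrete map. Spikes are located within a step by linear
interpolation, which is adequate because the flow at the spiking phase has
speed 2 and vanishing input sensitivity. Phases are stored, when
requested, at spike-bin resolution. The first 100 tu of every shared-input
run are flagged transient and excluded from analyses; initial conditions
approximate the stationary measure by evolving uniform seeds for 50 tu
under trial-specific independent inputs ("burn"). Cos/sin pairs in the
compiled hot loop come from a 2048-entry interpolated table (error below
`3e-7`, far under the Euler step error); an independent pure-R
Euler-Maruyama reference reproduces the compiled trajectories to `1e-7`
over a time-unit in the test suite, and halving `dt_int` moves the
network firing rate by well under 1%.

All randomness flows from named integer seeds through a counter-based
splitting scheme. The quenched input stream is indexed by (seed, neuron,
step), so slicing an input realization is exact and growing a trial
ensemble never perturbs earlier trials.

## Spike words and noise entropy

Spike trains are binarized at `dt_bin = 0.05` tu (at most one spike per
bin for these cells; double-occupancy is clipped and counted). The
noise-entropy rate of `K` cells over `L` bins is the plug-in estimate

    H = -(1/(L dt)) sum_w p_w log2 p_w,   p_w = cross-trial word frequency,

in bits per time-unit, averaged over consecutive non-overlapping windows
(stationarity makes the time average estimate the input-ensemble
expectation). Words are indexed cell-major, bins within cells. No bias
correction is applied, matching the normalized-count definition; the
plug-in estimator's downward bias and its decay with trial count are
property-tested.

The `L -> infinity` limit is extrapolated in `1/L`: entropy rates of a
system with finite memory decrease linearly in `1/L` once `L` is large,
until finite sampling bends the curve down. We locate the point of least
fractional change in slope between successive segments of `H` versus
`1/L`, fit a straight line through the three points around it, and report
the intercept. Ties take the earliest point; an exactly extensive curve
`a + b/L` is recovered exactly, and a flat curve returns itself. A curve
that *increases* with `L` is rejected as non-physical.

Pairwise redundancy `delta_ij` composes three such extrapolations
(`H1(i) + H1(j) - H2(i,j)`, word lengths up to 10 for pairs); the naive
extensive bound is `N` times the mean extrapolated single-cell rate, with
an `N * 2 SE` band. Cross-trial noise correlations are per-bin Pearson
(phi) coefficients across trials, with zero-variance bins masked.

For the headline comparisons the analysis cell is chosen as the
excitatory cell whose rate is closest to the excitatory population mean —
the representative cell the study design calls for — from a short
pre-pass, before any entropy is computed.

## Surrogate controls

To isolate the network's contribution to single-cell variability, a cell
is re-simulated in isolation with its own quenched input intact while its
recurrent input is replaced by surrogate presynaptic trains, redrawn
independently every trial: homogeneous Poisson trains matching each
upstream cell's mean rate, or inhomogeneous Bernoulli draws per bin from
each upstream cell's cross-trial PSTH. Each surrogate spike at time `s`
delivers the stereotyped pulse `a * g(2 (t - s) - b)` for
`t - s` in `[0, b]` — the constant-velocity replay of the bump an embedded
spike delivers, accurate to `O(b^2)`. The model does not prescribe this
conversion; the replay rule is our choice, and its calibration is checked
by the isolated cell reproducing the embedded cell's firing rate.

## Lyapunov spectra and the Kolmogorov-Sinai bound

Because spiking is (approximately) a partition readout of the phase-space
state — cell `i` spikes in a bin iff its phase at the bin start lies in
`gamma_1 = [1 - 2 dt_bin, 1)` — the network's spike-pattern noise entropy
is bounded by its dynamical entropy production, and that in turn by the
sum of positive Lyapunov exponents:

    H_KS = (1/ln 2) * sum_{lambda_i > 0} lambda_i   [bits/tu].

Exponents are computed from the tangent dynamics of the Euler-Maruyama
step map — including the derivative of the noise term, a diagonal
`eps Z'(theta_i) dW_i` contribution, and the coupling cross-terms
`Z(theta_i) a_ij g'(theta_j)` — with QR re-orthonormalization every 1 tu
(halving this interval moves exponents by under 1%) and a 100 tu
transient. Exponents are kept in nats/tu internally and divided by `ln 2`
exactly once, in the bound. `m` defaults to `0.4 N`: the positive part of
the spectrum sits well inside the first 10% of ranks at standard
parameters, and the margin certifies that the smallest computed exponent
is negative, without which the bound would be truncated (that condition
is enforced with an error). The tangent implementation is validated in
the tests against an analytic-vs-finite-difference Jacobian check and
against the divergence rate of two directly simulated nearby
trajectories.

The firing-rate level curve in the `(eta, eps)` plane is traced by
simulating a rate surface on a grid and extracting the target contour by
interpolation (`grDevices::contourLines`), parameterized with `eta`
increasing — from the fluctuation-driven excitable regime toward the
mean-driven oscillatory one — with spectra and `H_KS` evaluated along it.

## The partition check and the piecewise variant

The partition rule is exact only in the limit of small bins. The package
measures both failure directions on stored bin-start phases: spikes whose
cell was not in `gamma_1` at the bin start (violations) and `gamma_1`
occupancies without a spike (misses). A companion *piecewise* model
variant replaces `F` by the constant 2 and `Z` by 0 on `gamma_1`, making
the rule exact by construction; the integrator splits any step that
crosses into `gamma_1` so the exactness survives discretization, and the
test suite asserts exactly zero violations and misses for it. Spectra for
the piecewise variant use its piecewise derivative; single-step boundary
crossings are ignored as measure-zero events.

Two caveats from our measurements, reported by the acceptance machinery
as computed. First, for the smooth model at `dt_bin = 0.05` and
`eps = 0.5` the violation rate is a few percent, not a vanishing
fraction: the deterministic speed at the inner edge of `gamma_1` is
1.6-1.7 rather than 2, and the multiplicative noise accumulated over one
traversal displaces the phase by ~0.01 against a band of width 0.1 — an
uncoupled driven cell already shows the same rate, so this is intrinsic
to the dynamics at these parameters, and it decreases strongly (to
~0.3%) at `dt_bin = 0.01`, with the refinement monotonicity
property-tested. Second, and for the same reason, the maximal
normal-vs-piecewise spike-time discrepancy of a replayed cell measures
~0.04 tu — below one bin, but above the integrator step. The qualitative
link between the partition and spike words survives both caveats; exact
statements hold for the piecewise variant.

## Synthetic fixtures

The estimators are tested without the simulator on fixtures with exact
ground truth: iid and profile-driven Bernoulli rasters (closed-form
entropy rates), duplicated and correlated cell pairs (exact redundancy
and correlation), Poisson spike trains (exact rates), and toy Lyapunov
spectra (exact `H_KS`). These emulate the *statistical* structure of
simulator output — binary words across trials — but none of its dynamics:
no refractoriness, no input-locking, no temporal correlation beyond the
imposed profile. Estimator tests passing on fixtures therefore certify
the estimation pipeline, not the physics; the physics is tested against
quadrature, Fokker-Planck, and divergence oracles on the simulator
itself.

## Problem sizes in the shipped tests

The test suite reproduces the study's quantitative claims at a reduced
scale chosen to make a full run practical on one core: the shared
ensemble uses `N = 500`, `kappa = 20`, 500 trials, a 1000 tu analysis
window after the 100 tu transient, with `dt_int = 0.005` for this
ensemble (rate robustness to the step is separately verified); Lyapunov
comparisons use `N` between 100 and 400 with 250-350 tu of accumulation.
The study's production scale (2000 trials, 10,000 tu) sharpens the
entropy estimates — plug-in bias shrinks roughly inversely with trial
count — but does not change any qualitative outcome; all scales are
ordinary configuration parameters.

## Known limitations

* The pulse-scale calibration above makes the firing-rate surface match
  to a few percent but not to the printed `+-0.003`; quantities that are
  sensitive to the residual (notably absolute noise-entropy levels) carry
  that systematic uncertainty.
* Plug-in entropies at feasible trial counts are biased down, and
  differences of extrapolated entropies (pairwise redundancy) inherit a
  positive bias that the tests characterize but do not correct; an
  optional Miller-Madow diagnostic exists in the estimator literature but
  is deliberately not applied to headline numbers.
* The mapping from surrogate spikes to synaptic drive is a modeling
  choice (constant-velocity pulse replay), verified only through the
  reproduced firing rate of the isolated cell.
* Exponent estimates carry an `O(1/sqrt(T))` convergence error visible in
  the reported traces; bounds derived from them inherit it.
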