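---
title: "Models and methods: single-molecule FRET analysis of lateral-gate dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-molecule FRET analysis of lateral-gate dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgfret)
```

## The system and the measurement

The SecYEG channel conducts secretory proteins across the bacterial inner
membrane, driven by the SecA ATPase. The channel's lateral gate — the
interface between transmembrane helices 2/3 and 7 — opens and closes as
SecA cycles through its nucleotide states, and a donor/acceptor dye pair
placed across the gate reports that motion as a FRET efficiency: high
E (~0.76) when the gate is closed, lower E when it is partly (~0.59) or
fully (~0.45) open.

`lgfret` implements the quantitative analysis around this measurement:

* selection of valid single-molecule TIRF traces by sequential
  photobleaching and computation of per-molecule efficiencies,
* construction, averaging and constrained multi-Gaussian global fitting
  of FRET-efficiency histograms,
* model selection (how many states?) by SVD and residual comparison,
* a Gillespie simulation of the two-state open/closed kinetics with TIRF
  sampling emulation,
* ensemble tight-binding and stopped-flow fits, and geometric distance
  metrics on coordinate files.

A synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable without any experimental download.

## Trace selection and the efficiency estimator

A valid trace shows the signature of exactly one donor and one acceptor:
a single downward acceptor photobleaching step, a coincident
anti-correlated rise in the donor channel, and a later single downward
donor step. Traces in which the donor bleaches first are discarded; so
are traces with multi-step bleaching (more than one dye) and traces whose
phases are too short to average. The efficiency is the
acceptor-photobleaching estimator

$$E = 1 - \frac{I_{DA} - I_{bck}}{I_{D} - I_{bck}},$$

with $I_{DA}$ the donor mean during FRET, $I_D$ the donor mean after
acceptor bleaching and $I_{bck}$ the background after donor bleaching.
This estimator needs no quantum-yield or channel-sensitivity correction.
Values may fall slightly outside $[0,1]$ through noise and are not
clipped — the histogram fit must see that scatter.

Photobleaching steps are found by iterative binary segmentation: each
segment is split at the point minimising the piecewise-constant residual
sum of squares, and a split is kept when the level change exceeds 4 times
the robust noise SD (`mad(diff(x))/sqrt(2)`), with segments at least 5
frames long. The algorithm is deterministic and is tested against an
exhaustive single-change-point least-squares scan. The anti-correlation
criterion — donor rise at least 30% of the acceptor drop, within ±1
frame — is a tolerance choice: strict enough to exclude uncorrelated
events, loose enough to survive detector noise. Both thresholds are
arguments, not constants.

## Histograms and the staged global fit

Efficiencies are binned at 0.05 over $[-0.2, 1.2]$ (configurable); the
range keeps noise-broadened values outside the unit interval, and 0.05
matches the granularity at which peaks separated by ~0.15 are resolvable.
Replicates are averaged bin by bin with per-bin SEM.

The three-state model is fitted by the four-stage constrained protocol:

1. the high-FRET (closed) peak position and width are estimated from a
   single-Gaussian fit to the channel-alone condition, where the closed
   state dominates;
2. all condition histograms are fitted globally to three Gaussians with
   the high peak fixed, the two lower peaks' positions and widths shared
   across conditions, and per-condition amplitudes free;
3. all positions and widths are fixed and per-replicate amplitudes are
   refitted, giving the replicate-level estimates used for ANOVA errors;
4. the lower peaks are released again as an over-constraint check — the
   released parameters must agree with stage 2 within three standard
   errors, otherwise the fit is flagged.

All Gaussian widths are quoted as FWHM ($\sigma = w / (2\sqrt{2\ln 2})$).
The generator and fitter share this convention, so recovery tests are
convention-invariant.

### Numerical choices that matter

The model curve is *integrated over each bin* (differences of normal
CDFs), not point-sampled at bin centres, and amplitudes are parameterised
as non-negative areas.

Amplitudes are profiled out exactly at every objective evaluation
(variable projection): given the component shapes, the optimal amplitude
vector per histogram is a small non-negative linear least-squares (or,
under the deviance objective, Poisson-EM) problem. The nonlinear search
then runs over at most four shape parameters. Optimising counts-scale
amplitudes and FRET-scale positions jointly in one quasi-Newton search
fails on scaling grounds, and we observed exactly that failure before
adopting the projection.

Free means are parameterised as ordered gaps below the preceding
component with a minimum separation of 0.08 FRET units. Two components
with coincident means do not describe distinct conformational states, and
the gap parameterisation removes both label switching and the collapse
degeneracies that a raw mean parameterisation invites. Widths are bounded
to $\sigma \in [0.05, 0.25]$: below the bin width a component is
indistinguishable from a single-bin spike (pure noise chasing); above
$\sigma = 0.25$ (FWHM ≈ 0.6) a "state" spans most of the efficiency axis
and is no longer a state. Multi-start (five seeded jittered starts)
guards against residual local minima.

The default objective is the *Poisson deviance* of the binned counts.
Histogram bin contents are counting statistics; weighting squared
residuals by a replicate-estimated SEM (three replicates give a very
noisy variance estimate) or fitting unweighted least squares both
underprice model mass placed in nearly-empty tail bins — a squared error
of $\mu^2$ versus the deviance's $2\mu$ — and in simulation this produced
a systematic downward-and-broad drift of the open component worth
−0.03 to −0.05 in its mean. The deviance objective is unbiased in the
same simulations (|bias| < 0.001 on all three means over 24 seeded
six-condition sets). Weighted least squares with model-based, iteratively
reweighted Poisson weights remains available (`objective = "wls"`).

### What recovery tests show — and their limits

At the study's scale (three replicates of 200 events per condition), the
open component's mean is intrinsically poorly determined from a *single*
mixed condition: an event-level maximum-likelihood fit — the efficiency
bound — has a per-experiment SD of ~0.09 for that mean. The global fit
across the six-condition series (alone, AMPPNP, ADP, ATP, ATP+substrate,
high-motor+substrate), in which the amplitude pattern varies while shapes
are shared, is what identifies it: the staged fit then recovers the three
means with per-experiment SDs of about 0.004, 0.007 and 0.036. Recovery
is therefore assessed on the six-condition design, and reported values in
the acceptance analysis are averaged over 10 independently seeded
simulated experiments, which brings the Monte-Carlo error of the open
mean near 0.01.

## Model selection

Two independent answers to "how many states?":

* `svd_components()` area-normalises the condition × replicate histogram
  matrix and counts singular values above the noise edge
  $\sigma_n(\sqrt{n_\text{bins}} + \sqrt{n_\text{cols}})$ — the largest
  singular value a pure-noise matrix of that shape produces — with
  $\sigma_n$ estimated from same-condition replicate scatter. On
  three-state synthetic sets this yields three significant components.
* `compare_k_fits()` fits k-component constrained mixtures and reports
  the residual sum of squares per k. RSS is non-increasing in k by
  construction (each fit also starts from the (k−1)-solution plus a
  vanishing component); a genuine extra state drops RSS by far more than
  the ~8% that pure overfitting of four extra parameters explains.

## The two-state ratchet simulation

The ATPase cycle is reduced to an alternating renewal process: the
closed, high-FRET (ADP-bound) state is left at $k_{cat} = 0.27\,s^{-1}$
(ADP release, rate limiting) and the open, low-FRET (ATP-bound) state at
$k_{cleave} = 11.5\,s^{-1}$ (ATP hydrolysis and phosphate release).
Dwells are drawn exponentially (Gillespie), mapped to a 1 ms grid by
rounding up to at least one step, starting in the high state. The
stationary high-state occupancy is
$k_{cleave}/(k_{cat}+k_{cleave}) \approx 0.977$.

TIRF sampling is emulated by adding per-step Gaussian noise matched to
the width of the high FRET peak (FWHM 0.24) *before* boxcar-averaging
over non-overlapping 200 ms windows — noise first, then averaging, so the
post-average noise SD is $\sigma/\sqrt{200}$. Over 600 s of simulated
signal, the resulting histogram shows only a slight shift of the high
peak and no intermediate feature: fast two-state interconversion at these
rates cannot manufacture the E ≈ 0.59 peak by time averaging, which is
the argument that the part-open state is genuine. Dwell-rate recovery by
the exponential MLE (rate = 1/mean dwell, censored edge dwells excluded)
is exact to within the grid-discretisation bias of ~$dt/2$ per dwell,
well under the 10% acceptance band.

## Ensemble assays

The tight-binding (ligand-depletion) isotherm

$$F = F_0 - B_{max}\,\frac{E_0 + s + K_D - \sqrt{(E_0+s+K_D)^2 - 4E_0 s}}{2E_0}$$

is the forward model for titrations where the fixed-partner concentration
$E_0$ is comparable to $K_D$ (concentrations in nM throughout; the
quadratic root is the bound fraction). Fits float $F_0$, $B_{max}$, $K_D$
with $E_0$ fixed, via Levenberg–Marquardt with five seeded starts;
degenerate flat titrations return $B_{max}=0$ with $K_D$ flagged
unidentifiable rather than an error.

Stopped-flow decays are fitted as one or two exponentials, optionally
with a rate fixed (e.g. to the value measured for a reference complex).
Because individual rates of a double exponential are easily conflated,
the half-completion time $t_{1/2}$ — where the fitted curve has covered
half its total excursion, found by bisection on the fitted curve, not the
raw data — is reported alongside, and normalised amplitudes sum to 1.

Small conversions complete the module: the proximity ratio
$F_A/(F_D+F_A)$; ATPase turnover from the NADH-coupled assay slope
($\epsilon_{NADH} = 6220\,M^{-1} cm^{-1}$ at 340 nm); and dye separation
$r = R_0 (1/E - 1)^{1/6}$ with $R_0 = 6$ nm for this dye pair.

## Structure metrics

Geometry only: Cβ–Cβ distances between labelled sites, lateral-gate
widths over the residue pairs 124/275, 127/278, 130/282 (reported in nm),
and minimum side-chain heavy-atom distances. PDB files are parsed with
bio3d; the first model is used, alternate locations resolve to the
highest occupancy (ties to 'A'), and a Cβ request on glycine falls back
to Cα with a message. All metrics are invariant under rigid motions,
which the tests verify with random rotations. Chain and residue numbering
are arguments — nothing is hard-coded to a particular deposition.

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the analysis assumes:
piecewise-constant bleaching traces with additive Gaussian noise at
0.22 s/frame, Gaussian three-state efficiency mixtures (means 0.76, 0.59,
0.45; FWHM 0.24, 0.16, 0.31) sampled 200 events × 3 replicates per
condition, exponential dwell-time trajectories at the cycle rates,
tight-binding titrations and multi-exponential decays. The six-condition
weight series in `lateral_gate_conditions()` mirrors the qualitative
progression of the experiment: closed-only without nucleotide, mostly
closed with ADP, progressively more open with AMPPNP, ATP and substrate.

Deliberately not emulated: raw TIRF images and spot extraction, dye
photophysics (blinking, spectral cross-talk), shot-noise (the noise model
is additive Gaussian, detector-dominated — the trace noise model is an
assumption, stated as such), and liposome occupancy statistics. Passing
recovery tests on these synthetic data therefore validates the estimators
against their own model assumptions; they cannot certify robustness to
image-registration artefacts or photophysical heterogeneity in real
recordings.

## Problem sizes

Defaults were chosen as the smallest sizes at which the statistics are
stable: 10 simulated six-condition experiments for mixture recovery,
2000 s trajectories (~540 ADP-release events) for dwell-rate recovery,
600 s for simulated histograms, 50-seed batches for bias checks. All are
arguments and scale up linearly.
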