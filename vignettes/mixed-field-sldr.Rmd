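---
title: "Models and methods: survival, sublethal damage repair and DSB kinetics in mixed X-ray/alpha fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: survival, sublethal damage repair and DSB kinetics in mixed X-ray/alpha fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmix)
```

`radmix` implements the computational chain of a mixed-field radiobiology
analysis: cells exposed to X-rays (low LET), alpha particles
(LET 129.3 keV/µm), or ordered combinations of the two, assayed by
clonogenic survival and 53BP1 focus counting. The scientific question the
chain addresses is how much *sublethal damage* (SLD) — repairable lesions
that kill only by pairwise interaction — high-LET radiation induces, and
how fast it is repaired. This vignette documents the models, the estimators,
the tunable parameters with their defaults, and the choices made where the
design was genuinely open.

## 1. Survival models

**Linear-quadratic (LQ).** Single-fraction survival is
$S = e^{-\alpha D - \beta D^2}$, with $\alpha$ (Gy⁻¹) the single-track
lethality and $\beta$ (Gy⁻²) the pairwise SLD interaction. `fit_lq()` fits
$\ln S$ by bounded least squares ($\alpha, \beta \ge 0$, `nls` port
algorithm); dose-response curves are concave down on the log scale, so the
non-negativity constraint is a statement of the model, not a convenience.

**Additive mixed field.** For an alpha dose $D_A$ and X-ray dose $D_x$ with
no synergy beyond SLD pooling,
$S = \exp[-\alpha_A D_A - \alpha_x D_x - (D_A\sqrt{\beta_A} +
D_x\sqrt{\beta_x})^2]$: linear terms add, while the square root structure
means sublethal lesions from either modality interact as one pool. With one
dose zero this reduces exactly to the LQ model, a reduction the test suite
asserts.

**Two-fraction protraction.** Splitting a dose $D$ into two equal fractions
of duration $t$ separated by an interval $T$ replaces $\beta D^2$ by
$\beta G D^2$ with the two-fraction dose-protraction factor

$$G = \frac{1}{\lambda t}\left[1 - \frac{1}{\lambda t}(1 - e^{-\lambda t})
 + \frac{e^{-\lambda T}}{2\lambda t}(1 - e^{-\lambda t})^2\right],$$

where $\lambda$ is the first-order SLD repair rate. $G \to 1$ for a single
acute dose and $G \to 1/2$ for two fully separated acute fractions. The
printed form is 0/0 at $t = 0$; `g_factor()` switches to the analytic limit
$(1 + e^{-\lambda T})/2$ when $\lambda t < 10^{-8}$. A property worth
noting, used throughout the package: the $T$-dependence of $G$ is *exactly*
proportional to $e^{-\lambda T}$, so split-dose log-survival always has the
form $\ln S(T) = \ln S_\infty - \Delta e^{-\lambda T}$.

## 2. Split-dose recovery and RBE for sublethal damage

`fit_recovery_curve()` fits that exponential form directly:
$\Delta \ge 0$ is the log-survival recovery magnitude (acute minus fully
separated), $\ln 2/\lambda$ the repair half-life. A fit pinned at
$\Delta = 0$ is flagged `no_recovery` — the empirical situation for two
alpha fractions, where damage is so clustered around single tracks that
inter-track interaction is negligible and no half-life is definable.

**Shared-versus-independent half-lives.** `shared_halflife_ftest()`
compares per-condition fits (own $S_\infty$, $\Delta$, $\lambda$) against a
reduced model sharing one $\lambda$, by the extra-sum-of-squares F-test
$F = [(\mathrm{SSR}_r - \mathrm{SSR}_f)/(df_r - df_f)] /
(\mathrm{SSR}_f/df_f)$. A large p-value supports LET-independent repair
kinetics.

**Weighting.** Log-survival replicates are weighted by a *pooled* variance
estimated across dose/interval cells rather than per-cell 3-replicate
variances. Per-cell weights from so few replicates are essentially noise;
in simulation they made the F-test reject a true shared half-life 28% of
the time at nominal 5%, while pooled weights give 6.3% with 93% power
against a 3-fold rate difference. Clonogenic scatter is close to
multiplicative, hence homoscedastic in the log, which is what the pooled
estimate assumes.

**The RBE_SLD estimator.** Under the Lea–Catcheside picture the recovery
magnitude of a two-fraction exposure is proportional to the product of the
fractions' SLD yields: $\Delta_{XA} = \gamma\,\mathrm{SLD}_x\,
\mathrm{SLD}_A$ and $\Delta_{XX} = \gamma\,\mathrm{SLD}_x^2$. With the X-ray
fraction common to both conditions, $\gamma$ and $\mathrm{SLD}_x$ cancel in
the ratio, leaving

$$\mathrm{RBE}_{SLD} = \frac{\mathrm{SLD}_A}{\mathrm{SLD}_x}
\cdot \frac{D_x}{D_A} = \frac{\Delta_{XA}}{\Delta_{XX}}
\cdot \frac{D_x}{D_A},$$

the relative SLD yield per Gray. $\gamma$ is identifiable only as a product
with the yields and is never reported alone. The doses here are the study's
iso-survival fractions, 3 Gy X-rays and 0.75 Gy alpha; the X+X reference
uses 2 × 3 Gy, and the estimator assumes the 3 Gy X-ray SLD yield is the
shared factor that cancels.

`recovery_magnitude()` implements the two-point version: mean log-survival
over well-separated intervals (≥ 4 h) minus the mean over acute intervals
(≤ 15 min). Because both windows are shared between the X+X and X+A
conditions and the repair rate is common, the window attenuation factor
$\overline{e^{-\lambda T}}$ cancels *exactly* in the ratio — the estimator
is unbiased for any window choice, a property the tests verify at zero
noise.

**Bootstrap CIs.** CIs are nonparametric: replicates are resampled within
each (condition, interval) cell on the log scale and the full estimator is
re-applied (2000 resamples by default, percentile interval). With only 3
replicates per cell the plain n-out-of-n bootstrap underestimates the
cell-mean variance by a factor $(n-1)/n$, which in simulation gave ~80%
coverage at nominal 95%; the package therefore inflates resampled
deviations about the cell mean by $\sqrt{n/(n-1)}$, the standard
finite-sample correction, restoring measured coverage to 94–95% over 100
synthetic datasets per preset.

**RBE at 10% survival.** `rbe_d10()` solves $\alpha D + \beta D^2 = \ln 10$
in closed form and reports the D10 ratio, with a parametric bootstrap CI
from the LQ fit covariances (draws truncated at zero).

## 3. DSB induction surrogate

The damage model irradiates a uniformly sensitive water sphere of radius
2.5 µm. One Gray deposits mass × 1 J/kg ≈ 408.5 keV in this nucleus; at
0.41 keV per single-strand break that is ≈ 996 SSBs/Gy, matching the
canonical 1000 SSB/Gy budget. The chain is:

1. **Tracks** (`sample_tracks()`): isotropic uniform chords (direction
   uniform on the sphere, impact point uniform on the projected disc; mean
   chord $4R/3$). The track count is Poisson with mean
   dose × 408.5 keV / (LET × 4R/3); each run records its realized dose from
   the chord energies. An exact-dose mode (chords drawn until the energy
   target, last chord truncated) is available in the configuration.
2. **SSBs** (`place_ssbs()`): a Poisson line process along each chord with
   density LET/0.41 keV µm⁻¹, displaced perpendicular to the track by an
   isotropic 2D Gaussian of scale $\sigma_r$, and assigned a strand by a
   fair coin. The expected SSB total per realized Gray is LET-invariant.
   Jitter is never clipped at the nuclear surface: it is nm-scale against a
   µm-scale radius and dose bookkeeping uses chord energies.
3. **DSBs** (`pair_dsbs()`): opposite-strand SSB pairs within 3.2 nm are
   accepted greedily in order of 3D distance, each SSB used once, ties
   broken by index; counts are averaged over independent strand
   re-assignments at fixed geometry (default 100 per geometry across 12
   geometries; configurable up to 10⁴). Greedy matching is compared against
   exhaustive maximum-cardinality matching on small instances in the test
   suite and agrees on ≥ 99% of instances at the calibrated densities.

This is a deliberate *parametric surrogate* for full track-structure Monte
Carlo: the expectation of "SSB probability proportional to energy deposited
per event" at a fixed 0.41 keV/SSB collapses to exactly this line density,
and $\sigma_r$ absorbs the radial energy spread (penumbra) that a physics
code would simulate event by event.

**Calibration** (`calibrate_damage_model()`) tunes the two free parameters
by bisection under common random numbers: the reference quality's effective
electron-segment LET so the reference yield is 35 DSB/Gy, then $\sigma_r$
so the alpha yield at 129.3 keV/µm is 128.5 DSB/Gy, iterating the two
stages (≤ 5 sweeps) because the jitter feeds back on the reference yield.
The shipped defaults are the converged values at high replication:
effective reference LET 26.7 keV/µm and $\sigma_r$ = 1.88 nm. The effective
LET is far above any physical electron stopping power: it is a lumped
parameter absorbing the end-of-track clustering of the full
secondary-electron spectrum, and should be read as "the uniform line
density that reproduces reference-quality clustered-break statistics", not
as a stopping power. With these two numbers fixed, the yield-versus-LET
curve is a prediction: it is close to linear in LET (R² > 0.95 over
25–130 keV/µm), and the alpha-to-reference ratio — RBE for DSB induction —
comes out at ≈ 3.67.

## 4. Misrepair simulator and the survival map

The repair model works on break *ends*. Each DSB contributes two co-located
free ends; any two free ends may join, with rate
$k_{\text{pair}}\, e^{-r^2/2\sigma^2}$, where $r$ is the distance between
the parent breaks, $\sigma$ the proximity scale, and $k_{\text{pair}}$ the
rate constant of the *slower* complexity class of the two parents (the
conservative composition rule; the class rate coefficients exist in the
literature but the pair rule is not printed anywhere we could follow).
Breaks are simple or complex with probability 0.43, with default half-lives
25 min and 8 h — values in the range of published two-component repair
fits, exposed in the configuration and deliberately excluded from every
fitted parameter set. $\sigma$ defaults to 0.25 µm, the order of
chromatin-interaction distances in proximity-based misrepair models.

`simulate_repair()` is an exact Gillespie simulation (rate-sum sampling
with incremental updates, implemented in C++): no time discretisation, so
the single-isolated-break completion time is exactly exponential with its
class rate, a property the suite verifies by a KS test. A break whose ends
rejoin each other is correct; ends joined across breaks are misrepair —
the modelled precursor of lethal aberrations. We count misrepaired
*breaks*; each misrepair event involves ends of two breaks, so event counts
are half break counts in the fully-misrepaired limit. Ends still free at
48 h simulated time (possible only under pathological configurations) are
excluded from the denominator with a warning.

Damage geometries: X-ray breaks are uniform in a 4.32 µm nucleus
(35 DSB/Gy); alpha breaks lie along sampled track chords — count Poisson in
the *realized* dose, allocated to tracks by length, scattered 50 nm
(Gaussian) off the track — with the yield scaled by the induction model's
RBE_DSB to 128.5 DSB/Gy. Two-fraction exposures inject the second geometry
at the inter-fraction interval (`misrepair_vs_interval()`). The qualitative
structure this produces, asserted in the tests: X+X misrepair falls
substantially with interval; alpha+alpha misrepair is huge (dense
intra-track damage) and essentially interval-independent, its relative
recovery less than half the X-ray value; at long intervals misrepair equals
the sum of independent fractions.

`fit_survival_map()` connects simulation to data through
$S(T) = S_\infty e^{-k(M(T) - M_\infty)}$: surviving the extra misrepair of
closely spaced fractions is Poisson in the number of extra lethal events,
with $k$ the probability a misrepaired break is lethal, fitted with
$k \ge 0$ by least squares on the log scale. $M_\infty$ is the simulated
misrepair at the longest interval. If the misrepair table carries no
interval contrast, $k$ is unidentifiable and flagged rather than guessed.

Run counts are desk-scaled: the module defaults (50 damage geometries × 3
repair repeats per interval; 40–60 in the analysis scripts) trade the
500–1000-distribution settings of a production run for minute-scale
turnaround, and are configurable up to those values.

## 5. Foci kinetics

The descriptive model is the exponential fit
$N(t) = (N_0 - P)e^{-kt} + P$ per condition. The mechanistic *cluster*
model explains why alpha foci decay slowly even if every DSB repairs at the
same rate: a focus is a damage cluster that stays visible until *all* its
DSBs are repaired. With per-DSB unrepaired probability

$$q(t) = p_{\text{per}} + (1 - p_{\text{per}})\left[(1 - c)e^{-k_f t}
+ c\, e^{-k_s t}\right],\qquad c = 0.43,$$

X-ray foci (one DSB each) decay as $N_0\, q(t)$, while Poisson($\mu$)-sized
alpha clusters stay visible with the void probability complement
$1 - e^{-\mu q(t)}$, so expected alpha foci are
$N(1 - e^{-\mu q(t)})$ — initially $N(1 - e^{-\mu})$, not $N$, since empty
clusters are never visible. Persistence is per-DSB (probability
$p_{\text{per}}$ of never repairing), matching the per-break way residual
damage rates are quoted. `fit_foci_cluster()` fits exactly three free
parameters — $N_0^{(x)}$, $p_{\text{per}}$, $N$ — jointly to both
modalities, with the total alpha DSB budget *fixed* at
RBE_DSB × 35 × dose (= 257 DSBs at 2 Gy), so $\mu = \text{budget}/N$; the
class rates stay at their configured values. The per-cluster DSB count is
plain Poisson by default; a chord-weighted mode (cluster size proportional
to track path length) is available but not the default, because the fit
only exposes the cluster count. `simulate_foci_mc()` is the Monte Carlo
twin used to validate the closed form.

## 6. Synthetic data and ground truth

Every fitter in the package has a generator that is its exact forward
model, so zero-noise generate→fit is the identity (asserted to 10⁻⁶).
`ground_truth_preset()` bundles self-consistent parameter sets for the two
cell lines studied with this source:

| quantity | PC-3-like | U2OS-like |
|---|---|---|
| X-ray $\alpha$, $\beta$ | 0.20, 0.08 | 0.10, 0.08 |
| RBE$_{D10}$ (sets alpha-particle $\alpha$, $\beta=0$) | 3.0 | 4.9 |
| shared repair half-life | 44 min | 34 min |
| RBE$_{SLD}$ | 2.8 | 3.7 |
| foci: $N_0^{(x)}$ / clusters / $p_{\text{per}}$ | 62 / 9.9 / 0.040 | 42 / 10.2 / 0.044 |

The LQ coefficients are package choices (no published values exist for
these exact fits); they are pinned down by the RBE$_{D10}$ targets, the
4–5× X-ray split-dose recovery (which fixes $\beta_x \approx 0.08$ via
$\Delta_{XX} \approx 2\beta_x D^2/2$), and the linear alpha response.
The stored $\Delta_{XX}$ is the *actual* acute-minus-separated log-survival
gap at the real X-ray delivery time (5.1 min at 0.59 Gy/min), i.e.
$\beta_x D^2 (G(0) - G(\infty))$, and
$\Delta_{XA} = \mathrm{RBE}_{SLD}\,\Delta_{XX} D_A/D_x$, which makes the
stored RBE_SLD exactly what the estimator returns at zero noise — the
invariant is checked to 10⁻¹².

Noise defaults emulate typical clonogenic scatter: median-preserving
lognormal on SF with 15% CV (so log-survival estimators see zero-mean
Gaussian noise), or optionally Poisson colony counting; foci noise is
Gaussian on the experiment mean with SE $= 1.5\sqrt{\bar N}/\sqrt{50}$
for 50 scored cells, three experiments. What the generator does *not*
emulate: plating-density artifacts, delayed-plating potentially lethal
damage (the slight order asymmetry real data show at late time points),
cell-cycle redistribution over long intervals, and focus
merging/splitting dynamics. Passing recovery tests therefore demonstrate
estimator correctness under the stated noise model, not robustness to
those biologies.

## 7. Numerical choices and limitations

- All stochastic entry points take an explicit integer seed; runs record
  seed and a configuration hash. Doses are Gy, inference-layer times
  minutes, foci times hours, lengths µm internally (nm accepted at config
  boundaries).
- Bounded fits use `nls(algorithm = "port")` with analytic-free gradients;
  recovery fits flag, rather than error on, boundary solutions.
- Bisection in the calibrator runs on a log scale with common random
  numbers, widening its bracket twice before declaring failure.
- The problem sizes in the tests and analysis scripts (10²–10⁴ Monte Carlo
  repetitions depending on the statistic) were chosen so that the Monte
  Carlo error of each *check* is small against the tolerance being
  checked; all are configurable upwards.
- Known limitations: the surrogate cannot resolve particle-type effects at
  equal LET beyond its two calibrated parameters; the misrepair model has
  no break-end motion; the foci model ignores optical-resolution merging of
  nearby clusters; and the ~9-alpha-tracks-per-Gy figure sometimes quoted
  for flattened attached cells is not reproduced by (and not a target of)
  the spherical-nucleus energy balance, which gives ~0.9–2.8 tracks/Gy
  depending on the radius.
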