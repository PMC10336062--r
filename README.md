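# radmix

Models and inference for cell survival and DNA damage after **mixed
X-ray / alpha-particle exposures**. The package is aimed at radiobiologists
and modellers who want to quantify *sublethal damage* (SLD) — repairable
lesions that kill only by pairwise interaction — for high-LET radiation,
where single-field experiments hide it: alpha damage is so clustered around
individual tracks that two alpha fractions barely interact, yet an alpha
fraction combined with an X-ray fraction reveals large, rapidly repaired
SLD yields.

## What it computes

**Survival layer.** The linear-quadratic model
S = exp(−αD − βD²), its additive mixed-field extension
S = exp(−α_A D_A − α_x D_x − (D_A√β_A + D_x√β_x)²), and the two-fraction
Lea–Catcheside dose-protraction factor G(λ, t, T), which multiplies the
quadratic term when a dose is split into two fractions separated by an
interval T. Fitting: bounded least squares on log survival, plus RBE_D10
(ratio of doses giving 10% survival) with parametric bootstrap CIs.

**SLD inference layer.** Split-dose recovery curves
ln S(T) = ln S∞ − Δ·e^(−λT) per exposure condition, a shared-versus-
independent repair half-life F-test (extra sum of squares), and the RBE
estimator for sublethal damage yield

> RBE_SLD = (Δ_XA / Δ_XX) · (D_x / D_A),

the relative SLD yield per Gray of alpha particles against X-rays, with
nonparametric bootstrap CIs over replicates.

**Mechanistic layer.** A Monte Carlo surrogate of DSB induction (SSBs as a
Poisson process along particle tracks through a 2.5 µm spherical nucleus,
opposite-strand pairs within 3.2 nm clustered into DSBs, calibrated to
35 DSB/Gy at reference quality and 128.5 DSB/Gy for 129.3 keV/µm alphas);
an exact Gillespie simulator of break-end misrepair with proximity-dependent
joining rates ζ ∝ exp(−r²/2σ²) and a misrepair-to-survival map
S(T) = S∞·exp(−k(M(T) − M∞)); and a cluster model of 53BP1 focus kinetics
in which a focus clears only when every DSB in its cluster has repaired.

**Synthetic data.** `ground_truth_preset()` / `gen_survival_dataset()` /
`gen_foci_dataset()` generate datasets with the full statistical structure
the inference assumes and known ground truth (presets echo the two studied
cell lines: shared half-lives 44/34 min, RBE_SLD 2.8/3.7), so every
estimator is testable as parameter recovery.

## Worked example

```r
library(radmix)

truth <- ground_truth_preset("pc3")          # known ground truth
surv  <- gen_survival_dataset(truth, seed = 42)

two  <- surv[surv$dose_2_Gy > 0, ]
cond <- paste0(substr(two$modality_1, 1, 1), substr(two$modality_2, 1, 1))
by   <- split(two, cond)

fit_recovery_curve(by$xx)                    # X+X split-dose recovery
shared_halflife_ftest(by[c("xx", "xa", "ax")])
estimate_rbe_sld(recovery_magnitude(by$xa), recovery_magnitude(by$xx),
                 dose_x_Gy = 3, dose_a_Gy = 0.75,
                 bootstrap_inputs = list(xx = by$xx, xa = by$xa),
                 n_boot = 2000, seed = 1)
```

prints (for this seed):

```
X+X repair half-life: 33.2 min (Delta = 1.31)
shared half-life: 36.0 min, F = 1.40, p = 0.26
RBE_SLD = 2.62, 95% CI [2.13, 3.24]
```

The X+X fit recovers the 44-min half-life within its (wide, 3-replicate)
uncertainty; the F-test does not reject a single repair half-life across
X+X, X+A and A+X — the headline mechanistic claim — and the RBE_SLD CI
covers the generating value 2.8: alpha particles made ~2.6–2.8× more
sublethal damage per Gray than X-rays in this dataset.

## Analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data and write tables under `results/`:

| script | writes |
|---|---|
| `01_synthesize_data.R` | survival/foci CSVs + ground truth per preset |
| `02_survival_models.R` | LQ fits, RBE_D10, additive mixed-field predictions |
| `03_sldr_inference.R` | recovery fits, shared-λ and order F-tests, RBE_SLD |
| `04_dsb_induction.R` | calibration + DSB-yield-vs-LET curve, RBE_DSB |
| `05_misrepair_simulation.R` | misrepair vs interval per schedule, survival map |
| `06_foci_kinetics.R` | exponential and cluster foci fits |

`run_pipeline()` composes the same stages programmatically and writes
`report.json`. The methods vignette
(`vignettes/mixed-field-sldr.Rmd`) documents every model, parameter and
design choice.

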