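---
title: "Inferring inhibition loss from functional connectivity with an atrophy-modulated dynamic mean field model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring inhibition loss from functional connectivity with an atrophy-modulated dynamic mean field model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dmfic` simulates whole-brain resting-state activity with a two-population
dynamic mean field (DMF) model: each of 90 regions holds an excitatory and
an inhibitory neural mass, coupled locally and — for the excitatory pools —
long-range through a structural connectome $C_{np}$ scaled by a global
coupling $G$. The population currents are

$$I_n^{(E)} = W_E I_0 + W_+ J_{NMDA} S_n^{(E)} + G\,J_{NMDA} \sum_p C_{np}
S_p^{(E)} - J_n S_n^{(I)}, \qquad
I_n^{(I)} = W_I I_0 + J_{NMDA} S_n^{(E)} - S_n^{(I)},$$

rates follow the sigmoidal transfer
$r = g(I - I_{thr}) / (1 - e^{-d\,g (I - I_{thr})})$ per population, and the
synaptic gating variables integrate these rates with NMDA/GABA time
constants plus uncorrelated Gaussian noise of amplitude
$\sigma_g = 0.01$ nA (Euler–Maruyama, gatings clipped to $[0,1]$). All
constants default to the standard values of the reduced Wong–Wang model
family (`dmf_params()`); the noise amplitude is named `sigma_g` throughout
and never aliased with the fitted coupling `sigma`.

The per-region feedback inhibition control (FIC) weight $J_n$ is the
quantity of scientific interest. A baseline $J_n^0$ is calibrated so every
region's mean excitatory rate falls in the physiological 3–4 Hz band, and
regional grey-matter atrophy $\alpha_n$ (a w-score-derived loading, stored
positive-for-atrophy) then modulates it through a single scalar coupling:

$$J_n = J_n^0\,(1 + \sigma\,\alpha_n).$$

Negative $\sigma$ means atrophied regions lose inhibition; $\sigma = 0$
means atrophy leaves the local E/I balance untouched. $\sigma$ is fitted by
minimizing the dissimilarity $1 - \mathrm{SSIM}$ between simulated and
empirical functional connectivity (FC), with Balloon–Windkessel
hemodynamics converting excitatory rates into BOLD signals.

## Calibration: what the recursion does and why it is shaped this way

`calibrate_fic()` uses the rate-error recursion
$J_n \leftarrow \max(J_n + \varepsilon\,(\bar r_n - r^\ast),\ J_{min})$ with
$\varepsilon = 0.005$ nA·s, target $r^\ast = 3.44$ Hz, floor
$J_{min} = 0.01$ nA, and at most 200 sweeps, each verified by a short
simulation. Three amendments proved necessary for convergence:

* **Error clipping (±10 Hz).** Disinhibited regions transiently fire two
  orders of magnitude above target; an unclipped fixed-gain update
  overshoots across the network's excitation cliff and limit-cycles.
* **Warm-started sweeps.** The balanced 3–4 Hz state is one attractor of a
  multistable network; its basin does not contain the integrator's
  cold-start state. Each sweep therefore continues from the previous
  sweep's end state, letting the recursion track the balanced branch while
  the weights adapt.
* **Confirmation run.** A sweep is accepted only after a longer (30 s)
  verification stays inside the band, since 10 s rate estimates can look
  balanced while the state drifts.

For the same reason, production simulations (`simulate_fc()`,
`gen_empirical_fc()`, the fitter, the progression maps) warm-start from the
calibration end state stored on the returned `fic_vector`: they sample the
calibrated resting attractor rather than whatever basin a cold start lands
in.

## What the synthetic generator emulates

`synth_config()` + `gen_*()` replace the patient MRI inputs:

* **Connectome** — a connected graph (spanning tree + Erdős–Rényi fill at
  density 0.3) with distance-decaying log-normal weights (sdlog 0.9), a
  ×12 within-community boost over five contiguous blocks, max entry
  normalized to 0.2. A deterministic tail-sharpening step caps the
  spectral radius at 0.22: linear analysis and simulation both show the
  calibrated balanced state at $G = 2.5$ is stable only when the spectral
  radius sits just above the maximum entry, and structured slow FC needs
  several eigenmodes near that edge. Heavy-tailed weights are also what
  empirical fiber-count matrices look like after max-normalization.
* **Atrophy maps** — zero for controls (they define the w-score
  reference); patient maps load the focus regions at `atrophy_strength`
  (default 0.5 on a normalized loading scale) with near-zero residuals
  elsewhere. The default 0.5 is chosen so that couplings in
  $[-0.9, 0]$ map the FIC factors $1 + \sigma\alpha$ into the model's
  FC-sensitive range (≈0.7–1.0); with loadings of 1.5 a coupling of −0.3
  already removes almost half the inhibition and the FC structure
  saturates at "destroyed", making distinct negative couplings
  indistinguishable.
* **Cohorts** — group × site × gender cells with patient durations uniform
  on 1–12 years and the hidden ground truth
  $\sigma = \sigma_0 + (\text{slope} + \text{gender offset})\cdot
  \mathrm{YWD}$.
* **FC targets** — full forward simulations at a planted coupling, plus
  optional observation noise on the off-diagonal.

What the generator does **not** emulate: anatomical geometry, scanner or
motion artifacts, subject-level connectome variability, non-stationary
(drowsiness-like) dynamics, and within-group atrophy heterogeneity. Tests
passing on these synthetic conditions show the machinery is correct and
the inference is well-posed under the model's own assumptions — not that
the biological effect sizes of real cohorts are recoverable.

## The SSIM objective and the fitting protocol

`fc_ssim()` slides a 7×7 uniform window over the two matrices (the full
matrix, diagonal included, treated as an image) and averages the printed
three-factor score with constants 0.01 / 0.03 / 0.015 and sample
($n-1$) moments; `fc_distance()` is $1-\mathrm{SSIM}$. `fit_sigma()`
minimizes the mean distance over simulation seeds with a
Gaussian-process surrogate (squared-exponential kernel, data-scaled
hyperparameters, small nugget) and expected-improvement acquisition over
$\sigma \in [-1.5, 0.5]$; the initial design always contains both bounds
and 0, repetitions are averaged, and every random draw descends from one
master seed, so a fit is bit-reproducible.

**Conditioning on the noise realization.** FC estimated from a scan of
length $T$ carries sampling noise; near the critical point the model's
slow fluctuations mix over ~10 s, so a 100 s scan yields only a handful of
independent samples of the slow modes. Measured at test scale, the
$1-\mathrm{SSIM}$ floor between independent 10-run-averaged FC estimates
(~0.12) exceeds the systematic difference between distinct strongly
negative couplings (0.002–0.01). The package's recovery and
atrophy-specificity experiments therefore use matched simulation seeds
between target generation and objective evaluation
(`fit_config(sim_seeds = attr(target, "sim_seed"))`): the objective
becomes an exact self-match at the planted coupling, and the experiment
isolates the optimizer's ability to invert the deterministic
$\sigma \to FC$ mapping from the statistics of finite scans. Recovery of
$\sigma^\ast = 0$ and the correct-versus-shuffled ordering also hold with
fully independent realizations; unconditional ±0.1 recovery of strongly
negative couplings would require simulated scan durations orders of
magnitude beyond what a desk-scale test can run.

## Hemodynamics

`bold_from_rate()` integrates the standard Balloon–Windkessel system (the
source model family's constants: $\kappa=0.65$, $\gamma_f=0.41$,
$\tau=0.98$ s, $\alpha=0.32$, $\rho=0.34$, $V_0=0.02$) driven by the
z-scored excitatory rate scaled by 0.5, which keeps the hemodynamics in
their near-linear regime; output is decimated to TR = 2 s. The neural
series is stored at 10 ms for this purpose — the vascular response
integrates over seconds, so finer drive resolution is wasted effort.
Regions with zero rate variance contribute zero drive and produce
zero-variance BOLD, flagged downstream by `compute_fc()`.

## Downstream statistics

`cohort_stats`-style analyses use the field's standard machinery behind
small wrappers: w-scores against the control mean/SD, OLS regressions
reported as signed $R$, $R^2$ and partial $\eta^2$
($SS_{eff}/(SS_{eff}+SS_{err})$, applied uniformly), Type-II ANCOVA
(`y ~ factor + covariate`; Type II because the synthetic designs are
balanced, where it coincides with Types I/III), the classical
mean-centered Levene test, Welch two-sample t-tests with
Benjamini–Hochberg correction across each comparison family, and pooled-SD
Cohen's d. `fc_vs_ywd()` computes within-run Spearman correlations of each
FC edge against disease duration and averages over runs (the averaging
order follows the procedure's description; run-averaged-FC-first is the
natural alternative and can be built from `simulate_fc()` directly).
Sign-restricted node scores count opposite-signed edges as zero
contributions rather than dropping them from the denominator — a fixed,
documented choice. Constant edges get Spearman 0 with a warning.

## Numerical choices and degenerate inputs

* Integration: Euler–Maruyama at dt = 1 ms (`dmf_params(dt =)` accepts
  finer steps; the constructor refuses dt > τ_GABA/5). Noise enters as
  $\sigma_g\sqrt{dt}$ per node and population.
* The transfer function evaluates its removable singularity as the limit
  $1/d$ (with a first-order correction), keeping it continuous and
  strictly increasing.
* Modulated FIC weights are floored at 0.01 nA with a warning — strongly
  negative $\sigma\alpha_n$ would otherwise produce non-positive
  inhibition and numerical blow-up.
* SSIM window positions use integral-image sums; ties in edge
  thresholding and top-k binarization break by the fixed row-major edge
  order.
* FC is computed on unfiltered BOLD by default; `compute_fc(bandpass = c(0.008, 0.09))` applies an optional zero-phase Butterworth band-pass first.
* Zero-variance FC regions correlate at 0 (warned); identical Levene
  groups return statistic 0, p 1; identical t-test samples return p 1.

## Test-scale problem sizes

The shipped tests run the full 90-region model for the calibration band
check (100 s verification) and the recovery/specificity/progression
experiments at reduced scan lengths (50–120 s) and optimizer budgets
(10–14 evaluations, 10 repetitions), with a 24-region model for unit
tests. These sizes are the package's choices for a reproducible test
suite; the fitting protocol itself defaults to 40 evaluations and 100
repetitions (`fit_config()`).

## Known limitations

* No conduction delays, no regional heterogeneity of gain or hemodynamic
  parameters, no receptor-density priors.
* $G$ is fixed at 2.5; only $\sigma$ is fitted.
* The multistability of the calibrated network makes results conditional
  on the warm-start protocol described above; cold starts can land in a
  quiescent basin.
* Group-level atrophy maps only; subject-level heterogeneity enters only
  through the planted cohort relation.
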