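---
title: "Weighing correlated evidence: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighing correlated evidence: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrddm)
```

## The problem

In a two-alternative perceptual decision, the normative weight of evidence
carried by an observation is its log-likelihood ratio (logLR). When
observations arrive as *pairs* of correlated Gaussian samples — two stars
whose horizontal positions share a correlation $\rho$ that changes from
trial to trial — the logLR of a pair $(x_1, x_2)$ from sources with means
$\pm\mu_g$ and SDs $\sigma_g$ is

$$\mathrm{logLR} = \frac{2\mu_g}{\sigma_g^2 (1+\rho)}\,(x_1 + x_2).$$

The pair is informative only through its sum, and the correlation enters
through the scale factor $1/(1+\rho)$: negatively correlated pairs are
synergistic (each pair is worth more), positively correlated pairs are
redundant (worth less). `loglr_pair()`, `expected_evidence_strength()` and
`correlation_scale_factor()` implement these quantities; natural logarithms
are used throughout.

A decision-maker who accumulates this logLR to a fixed threshold behaves
identically across correlation conditions *provided* the generative means
are calibrated so the expected logLR per pair,
$4\mu_g^2/(\sigma_g^2(1+\rho))$, is constant: $\mu_\rho = \mu_0\sqrt{1+\rho}$
(`calibrated_mean()`). Deviations from that invariance — slower responses
for negative correlations, faster for positive — are the behavioral
signature of misestimating or ignoring the correlation, and the
drift-diffusion machinery in this package exists to measure exactly that.

## The task generator

`task_config()` fixes the design constants: sessions of 4 blocks of 192
trials; 12 crossed conditions (2 sources x 2 evidence strengths x 3
correlation conditions $\rho_-, 0, \rho_+$), balanced within 16 sets of 12
per block so every condition appears once before any repeats; pairs drawn
every 0.2 s with $\sigma_g = 0.1$ (window-height units) and clipped at
$|x| \le 0.7$. Clipping (not resampling) models the display constraint; the
ideal-observer analysis ignores it, which is benign because at task-scale
means the clipped tail mass is below $10^{-5}$ (quantified in the test
suite).

Evidence strengths are individually calibrated with a 3-down-1-up staircase
(`run_staircase()`) on fixed-duration (1.4 s), zero-correlation trials. The
rule converges where $p^3 = 1/2$, i.e. 79.4% correct. Under-specified
staircase mechanics were fixed once as: initial mean 0.2, multiplicative
steps of $10^{0.05}$ shrinking to $10^{0.02}$ after 4 reversals, stop after
12 reversals, threshold = mean of reversals 3–12 — standard psychophysics
practice; only the converged accuracy is theory-constrained. Two caveats,
both visible in the tests: reversal averaging has a small (~1 point)
positive bias even asymptotically, and 12-reversal staircases started well
above threshold carry an additional transient bias. The calibration target
is recovered to within 2 points by longer (2000-trial) staircases; for
synthetic cohorts the short-staircase bias merely shifts each observer's
reference mean, which the fits absorb.

The low/high evidence levels are 0.4 and 2.5 times the threshold *evidence
strength* (expected logLR), so the generative mean scales with the square
root of the multiplier (`condition_mean()`). Two readings were possible
here: the multiplier could act on the strength or directly on the mean, and
the printed pairing of "high and low" with "0.4 and 2.5" could be read as
mapping high to 0.4. We fixed low = 0.4 and high = 2.5 on the strength
scale — the only reading in which "low" is the weaker condition — and left
`multiplier_scale = "mean"` available in the config for the other reading.

`simulate_observer_dataset()` turns a DDM specification into a complete
behavioral session (choices, RTs, optional stimulus streams), and is the
package's synthetic stand-in for a human participant. What it emulates:
condition-balanced designs, staircase-calibrated strengths, diffusion
choice/RT covariation, lapses, non-decision time. What it does not: sequential
dependencies, learning or fatigue drifts, RT quantization, or any
deviation from the DDM family itself — so passing recovery tests shows the
pipeline is consistent, not that real behavior is this well-behaved.

## The DDM family

All variants share drift sensitivity $k_0$, bound $B_0$, linear collapse
rate $t_B$, non-decision time $ndt$, and lapse rate $\lambda$ (uniform
mixture). The diffusion coefficient is 1; $\sigma_g$ is absorbed into $k_0$
and $B_0$. Correlation enters twice: through the noise of the internal
observation distribution (encoding, $\hat\rho_{SD}$) and through the
conversion of observations into evidence (weighing, $\hat\rho_B$):

$$\textit{drift}(\rho) = \frac{k_0}{\sqrt{1+\hat\rho_{SD}}}\,\mu_0\sqrt{1+\rho},
\qquad
B_\rho^t = \frac{(1+\hat\rho_B)}{\sqrt{1+\rho}\,\sqrt{1+\hat\rho_{SD}}}\,(B_0 - t_B t).$$

The six variants (`ddm_variants()`) differ in which of these terms are
free: `base` (neither; $\hat\rho_{SD}=\rho$ absorbed, no bound scaling),
`drift` (free per-correlation $k$), `bound_rho` ($\hat\rho_{SD}=\rho$, free
$\hat\rho_B$ — suboptimal weighing), `full_rho`
($\hat\rho_B=\hat\rho_{SD}=\hat\rho$ — suboptimal encoding, normative
weighing), `scaled_rho` (both free), and `bound_rho_plus_drift`. Collapse
applies to the instantaneous bound, i.e. the correlation scaling multiplies
$(B_0 - t_B t)$. Subjective correlations are fit separately for the
negative and positive conditions; the zero-correlation condition always uses
$\hat\rho = 0$.

Two predictions organize the analyses. For `full_rho`, choices depend on
the drift-bound product, in which the subjective terms cancel — so
misestimating $\rho$ shifts RTs (underestimation: slow at $\rho_-$, fast at
$\rho_+$) but not accuracy. That cancellation is exact for fixed bounds;
with a collapsing bound it is approximate, because rescaling time also
rescales the collapse rate — numerically a few parts in $10^3$ of accuracy
at the default parameters, largest for slow (low-evidence) conditions. For
`bound_rho`, misweighing changes the speed-accuracy trade-off itself and
moves accuracy and RT together. A naive weigher ($\hat\rho_B = 0$)
under-weights synergistic negative-correlation evidence — effectively a
higher bound: slower but *more* accurate there — and over-weights redundant
positive-correlation evidence: faster and less accurate
(`ideal_vs_naive_projection()`).

## First-passage numerics

`solve_first_passage()` integrates the Fokker-Planck equation of the
unit-diffusion process between symmetric absorbing bounds
$\pm\,\textit{scale}\,(B_0 - t_B t)$ by a theta-weighted implicit
finite-difference scheme (Crank-Nicolson in the interior of time). Defaults:
$dt = 5$ ms, $dx = 5\times10^{-3}$ evidence units, horizon 15 s (the RT
exclusion ceiling), with early exit once survival mass falls below
`mass_tol`. Two numerical details matter:

* **Startup and collapse steps are fully implicit.** Crank-Nicolson
  oscillates on non-smooth data; the delta initial condition (first four
  steps) and every step at which the discretized bound moves inward by a
  cell re-introduce such data. Treating exactly those steps with the
  backward-Euler weight removes the oscillation (and, before this fix,
  a factor-of-three inflation of error-bound mass at particular grids).
* **Mass accounting.** Per-step interior mass loss is split between the
  two bounds in proportion to the diffusive boundary fluxes
  ($\tfrac12 p_{\pm}/dx$); mass swept by a collapsing bound is absorbed on
  the side matching the sign of the decision variable. The bound is floored
  one cell above zero; absorption at the floor then empties the remaining
  mass within a few steps.

Against the constant-bound closed forms ($p = 1/(1+e^{-2\mu B})$,
$E[T] = (B/\mu)\tanh(\mu B)$) the defaults are accurate to ~0.1-0.3%, and
refinement converges monotonically. The Euler-Maruyama sampler
(`sample_paths()`, step 1 ms) applies the Brownian-bridge within-step
crossing correction, without which discrete crossing tests bias RTs long
(sampler-solver KS distance ~0.014 instead of ~0.003 at $10^5$ paths).
Predicted RT distributions shift decision times by $ndt$ and mix the lapse
uniform over $[0, 15]$ s split equally between choices; lapse RTs are not
shifted by $ndt$.

## Fitting

`ddm_negative_log_likelihood()` evaluates each trial's (choice, RT) under
the predicted defective densities (one cached solution per condition), with
a density floor of $10^{-10}$/s. Fits use a coarser grid
($dt = dx = 10^{-2}$) than the reporting solver: the induced likelihood
offset is nearly constant in the parameters and immaterial to the argmax,
and it buys a ~4x speedup. RT exclusions drop trials below 0.3 s or above
15 s, retaining the boundaries.

Two further economies keep global optimization affordable without touching
the reported science: the fitting solver's horizon stops just past the
dataset's slowest trial (densities are only evaluated at observed RTs,
and the lapse support stays fixed at 15 s so the lapse density is
unaffected), and its spatial grid is capped at 250 cells per half-domain,
which stretches `dx` only for implausibly tall bounds visited during
optimizer exploration.

`fit_participant()` minimizes the negative log-likelihood by differential
evolution (best/1/bin, reflection at the box bounds, $F = 0.8$,
$CR = 0.9$) — implemented in the package, deterministic given a seed. Box
constraints: $k \in (0, 50]$, $B_0 \in (0, 10]$, $t_B \in [0, 2]$,
$ndt \in [0, 1]$, $\lambda \in [0, 0.1]$, $\hat\rho \in (-0.95, 0.95)$.
Parameter corners whose collapse rate outruns the solver grid receive an
infinite objective. Recovery at session scale (768 trials) returns the
subjective correlations to within a few hundredths of truth with modest
budgets (population ~35, ~55 generations); the test suite checks the
median over ten simulated observers against the 0.15 tolerance.

The psychometric model $P(R) = \lambda + (1-2\lambda)/(1+e^{-(\beta_0 +
\beta_e E)})$ is fit by L-BFGS-B on the signed expected logLR, jointly or
separately per correlation condition (`fit_psychometric()`).

## Model comparison

`random_effects_bms()` treats each participant's best model as a draw from
a population frequency vector with a uniform Dirichlet prior, estimated
variationally from $-\mathrm{AIC}/2$ log-evidences. Exceedance
probabilities come from $10^5$ Monte-Carlo draws of the Dirichlet
posterior; the Bayes omnibus risk compares the variational free energy of
the alternative against the exact evidence of the equal-frequency null, and
protects the summary: $PEP_k = BOR/K + (1-BOR)\,EP_k$.

A finding from validation worth knowing: against exact enumeration of the
assignment posterior (feasible for small cohorts), the mean-field EP is
accurate when the evidence is informative but over-concentrates when it is
weak (e.g. exact EP 0.54 vs variational 0.80 on a pure-noise 6x4
instance). The protection is what restores calibration there — BOR rises
toward 1 and the PEP falls back toward $1/K$ — which is precisely why PEP,
not EP, is the reported quantity.

## The synthetic cohort pipeline

`run_cohort()` chains the pieces: draw observer parameters (independent
truncated normals around $k_0 = 8$, $B_0 = 1.2$, $t_B = 0.05$,
$ndt = 0.35$ s, $\lambda = 0.02$ — chosen once as typical of fitted human
parameters in this task family, and labeled synthetic), attenuate
subjective correlations on the Fisher-z scale
($z(\hat\rho) = a\,z(\rho) + \varepsilon$, default $a = 0.7$,
$\mathrm{sd}(\varepsilon) = 0.15$, emulating the systematic underestimation
human observers show), calibrate each observer by staircase against its own
fixed-duration accuracy $\Phi(k_0 m \sqrt{T})$, simulate the session, apply
RT exclusions, fit the configured variants, and compare models. Summaries
follow the field's conventions: correlations are averaged and regressed on
the Fisher-z scale, and deviations $\hat\rho - \rho$ are sign-flipped for
negative conditions before averaging so under-estimation has one sign.

The default profile is desk-scale — one group at $|\rho| = 0.6$, 8
participants, one 192-trial block, reduced optimizer budget — chosen so a
full end-to-end run stays in the minutes range while exercising every code
path; the full study scale (4 groups x 25 participants x 768 trials) is a
configuration change, not a code change. `rt_difference_summary()`
evaluates its fixed-bound reference curves (unscaled / naive / true /
0.9-underestimate weighing) from the constant-bound closed forms, with the
effective signal-to-noise and zero-correlation bound exposed as arguments.

## Known limitations

* The choice-invariance of `full_rho` is exact only for fixed bounds; with
  collapse it holds to a few parts in $10^3$ at typical parameters.
* Reversal-mean staircase estimates are slightly high; short staircases
  more so. Both are properties of the procedure, not bugs, and are
  documented by the tests.
* The variational EP is trustworthy only jointly with its protection; raw
  EPs from weak-evidence cohorts overstate certainty.
* No starting-point bias, across-trial parameter variability, temporal
  stimulus correlations, or hierarchical estimation: deliberately outside
  the model family studied here.
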