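---
title: "Free-energy landscapes and kink analysis for rigid-base DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes and kink analysis for rigid-base DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnakink)
```

## The problem

Double-stranded DNA is usually modelled as a smoothly bendable elastic rod,
but strongly deformed DNA — in protein complexes such as IHF, in minicircles,
in supercoiled plectonemes — bends by forming localized *kinks* at single
base-pair steps. At the step level the relevant coordinates are tilt
($\tau$), roll ($\rho$) and excess twist ($\Omega$, the deviation from the
intrinsic ~34° helical twist), all in degrees. Tilt is much stiffer than
roll, so sharp bending is carried almost entirely by roll, and a positive
twist–roll coupling ties large roll to twist changes.

`dnakink` implements the full inference chain used to quantify kinkability
from biased simulations, at desk scale:

1. **Energy models** (`eval_harmonic()`, `eval_anharmonic()`,
   `eval_bend1d()`): the quadratic rigid-base step energy
   $\beta\varepsilon = \tfrac12\left[A^\tau \tau^2 + A^\rho \rho^2 +
   C\,\Omega^2 + 2G\,\Omega\rho\right]$, its anharmonic extension with all
   cubic terms and the quartic terms $\rho^4$, $\Omega^4$, $\rho^2\Omega^2$
   (the mixed quartics $\rho^3\Omega$, $\rho\Omega^3$ are excluded — they do
   not improve such fits), and a zoo of 1D phenomenological bending models
   (harmonic, linear subelastic, hinge, fluctuating two-state).
2. **Umbrella protocol** (`build_window_grid()`, `bias_energy()`): harmonic
   restraints $V = \tfrac{K}{2}\left[(\rho-\bar\rho)^2 +
   (\Omega-\gamma\bar\rho)^2\right]$ on a symmetric grid of roll targets
   crossed with slopes $\gamma$, the twist target tied to the roll target.
3. **Surrogate sampler** (`sample_window()`, `run_protocol()`): Metropolis
   Monte Carlo in $(\rho, \Omega)$ emulating the statistics of biased
   all-atom trajectories.
4. **2D WHAM** (`build_histograms()`, `wham_solve()`): the self-consistent
   weighted-histogram estimator merging the window histograms into an
   unbiased $\Delta F(\rho, \Omega)$ in $k_BT$, referenced to its minimum
   bin.
5. **Stepwise anharmonic fit and kink taxonomy** (`fit_quadratic()`,
   `fit_anharmonic()`, `detect_flattening()`, `classify_kink()`,
   `asymmetry_metric()`).

Off-site couplings between neighbouring steps (e.g. $\tau_n\tau_{n+1}$) are
known to be weak, especially for roll, and are not modelled.

## Units and conventions

* Angles are **degrees** everywhere internally; radians are accepted at
  configuration boundaries with explicit `rad` suffixes (`parse_angle()`),
  because silent unit mix-ups are the main practical hazard in this
  pipeline.
* Energies are in $k_BT$; $k_BT = 0.0083145\,T$ kJ/mol, default $T = 300$ K.
* Restraint stiffness $K$ is in kJ/mol per squared **radian** (the
  convention of biasing engines); `bias_stiffness_deg()` converts to
  $k_BT/\mathrm{deg}^2$. The same $K$ applies to the roll and twist terms;
  the defaults are 100 kJ/mol for soft (all-atom-like) runs and
  1000 kJ/mol for runs on stiff quadratic surfaces, which need a stronger
  restraint to be pushed far from equilibrium.
* Published step-stiffness tables print the quadratic block scaled by
  $10^{-2}$, the cubic by $10^{-4}$ and the quartic by $10^{-5}$ (fitting
  angles in degrees). Scale factors are applied when coefficient files are
  read (`read_coefficients()`); stored coefficients are always on natural
  scale, and display re-applies the factors.
* Step-parameter tables (3DNA-style) carry **absolute** twist; it is
  converted to excess twist by subtracting a configured intrinsic twist
  (default 34.3°/step, a convention recorded in every output).

The bundled reference coefficient set (`ddd_coefficients()`) describes the
central AT step of the Drew–Dickerson dodecamer; on the printed scales its
quadratic block is (5.6, 9.7, 1.6), the cubic block (0.2, 10.5, −2.5, −1.6)
and the quartic block (−4.3, −4.3, −8.7). Its strong positive $\Omega^3$
coefficient suppresses overtwisting and favours undertwisting — a signature
of the right-handed helix — and its negative quartics soften the surface at
large deformations.

## The two-state (fluctuating melt) model

The two-state 1D model carries a Boolean melt state: intact
($g = a\theta^2$) or locally melted ($g = a'\theta^2 + \mu$, with
$a' \le a$). Because the state fluctuates, the default evaluation is the
free-energy marginalization $-\ln\left(e^{-a\theta^2} +
e^{-a'\theta^2-\mu}\right)$, shifted so $g(0) = 0$ (keeping every model
exactly zero at the undeformed step); a ground-state evaluation
($\min$ over branches) is available through `ground_state = TRUE`.

## The surrogate sampler

The sampler is plain Metropolis in $(\rho, \Omega)$ with symmetric uniform
square proposals, stationary density $\propto e^{-\beta[\varepsilon + V]}$.
Design choices:

* **Proposal width**: auto-tuned toward 30–50% acceptance from a default
  3° half-width; pilot samples are discarded.
* **Thinning**: every 10th sweep is kept (default). Kept samples are then
  nearly uncorrelated, which is the statistical structure the surrogate is
  meant to emulate — frames of a nanosecond-scale biased trajectory written
  at a picosecond-scale stride — rather than raw random-walk sweeps, whose
  integrated autocorrelation time is itself about ten sweeps.
* **Burn-in**: 10% of the kept length by default, configurable per run
  (biased trajectories occasionally relax slowly).
* **Determinism**: each window's seed is derived from the master seed and
  the window id by a small string hash, so partial grids re-run
  identically.
* **Hard wall**: proposals outside a square domain are rejected. The wall
  is needed because anharmonic surfaces with negative quartic coefficients
  are *non-confining*: beyond roughly 30° the reference surface turns over
  (its energy at $\rho = 35°$ is below that at $\rho = 30°$) and a chain
  would escape to infinity. The default wall for the reference surface is
  25°; harmonic models run unbounded.

### The breakage surrogate

In biased all-atom simulations, restraints beyond a sequence-dependent
threshold disrupt the central base pairs, and such data are excluded from
free-energy estimation. The polynomial surface has a precise analogue: past
its confinement ridge the energy decreases outward and the model no longer
describes intact conformations. `breakage_rule_radial()` therefore flags a
sample as broken when the outward radial derivative
$\hat{x}\cdot\nabla\varepsilon$ is negative at its position — a
model-intrinsic rule with no adjustable threshold. `mark_broken()` applies
any such predicate, and `build_histograms()` excludes flagged samples (and
counts them out of the window totals, which keeps the WHAM equations
consistent on the restricted manifold).

This exclusion matters: with a square 25° wall, the reference surface opens
a spurious runaway basin near the $(+25°, -25°)$ corner whose energy drops
below the undeformed state. Without the exclusion the landscape reference
(the minimum bin) lands in that corner and the low-$\Delta F$ fit region
selects the wrong basin entirely.

## WHAM

`wham_solve()` iterates the standard self-consistent equations
$$P(b) = \frac{\sum_i n_i(b)}{\sum_j N_j\, e^{f_j - V_j(b)}},
\qquad f_j = -\ln \sum_b P(b)\, e^{-V_j(b)}$$
(energies in $k_BT$), with the bias evaluated at bin centers. Numerical
choices, all configurable:

* bins 1° × 1° on $[-95°, 95°]^2$ by default (covering the ±1.6 rad
  protocol range); half-open bins, the top edge right-closed;
* convergence when $\max_j |\Delta f_j| < 10^{-6}\,k_BT$, cap $10^5$
  iterations (non-convergence returns a flagged result with a warning);
* bins with fewer than 5 total counts are masked (guarding the logarithm
  of small counts); the iteration itself runs only over occupied bins;
* the reference of $\Delta F = -k_BT \ln P/P_{\min}$ is the argmin bin,
  ties broken toward the smallest $(|\rho|, |\Omega|)$;
* poor histogram overlap (occupied bins not forming a single connected
  component across windows) triggers a warning naming the component count.

A single unbiased window collapses exactly to the shifted log-histogram,
and two windows under identical biases are exactly equivalent to pooling
their samples — both are unit tests.

One caveat worth knowing: $-\ln$ of a small count is a noisy, slightly
biased estimator, so bins near the mask floor carry $\sigma(\Delta F)
\approx 1/\sqrt{n}\,k_BT$ of counting noise (0.1 $k_BT$ at 100 counts) plus
a small upward Jensen bias. Any sup-norm statement about landscape accuracy
must be read against that floor: the maximum deviation over hundreds of
shell bins at a 100-count floor is ~0.25–0.33 $k_BT$ *for any number of
samples*, while bins holding ≥1000 counts agree with closed-form surfaces
to better than 0.15 $k_BT$ in the bundled tests.

## The stepwise fit

`stepwise_fit()` follows the successive-fit protocol used for published
coefficient tables:

1. **quadratic** on bins with $\Delta F \le 3\,k_BT$ (the harmonic model
   describes these surfaces well only up to about 3 $k_BT$), unweighted
   linear least squares on $\{\rho^2, \Omega^2, \rho\Omega\}$;
2. **cubic_only** on $\Delta F \le 7\,k_BT$ with the quadratic block
   frozen, basis $\{\rho^3, \Omega^3, \rho^2\Omega, \rho\Omega^2\}$;
3. **full** on $\Delta F \le 7\,k_BT$ with the quadratic frozen and the
   cubic block refit jointly with $\{\rho^4, \Omega^4, \rho^2\Omega^2\}$.

Whether the final stage refits or freezes the cubic block is genuinely
ambiguous in the successive-fit tradition, so both conventions are
implemented (`refit_cubic`). The default (joint refit) was chosen by a
deterministic criterion: applying both variants to the *exact* reference
surface evaluated on the fit grid, the joint refit reproduces the
generating quartic cross-term with materially smaller bias (−31% vs −44%).
A free intercept is included by default to absorb the reference-bin shift
of the landscape (the WHAM minimum bin need not coincide with the surface
origin). Weighting is uniform over bins; a count-weighted option exists for
exploration but is not the default since the published procedure states
none.

The stepwise protocol is *biased by construction*: within $\Delta F \le 3$
the cubic/quartic terms are small but not zero, so the stage-1 quadratic
absorbs part of them, and the frozen quadratic propagates that error to the
higher stages. `recovery_experiment()` therefore always computes a no-noise
oracle — the same stepwise fit applied to the exact generating surface on
the same grid and domain — which isolates this protocol bias from Monte
Carlo noise. On the reference surface the oracle biases are about −9%
(roll stiffness), −7% (twist stiffness), +2% (coupling and $\Omega^3$), and
−31% for the quartic cross term, which is determined only by the thin
high-energy shell of the fit region.

## Flattening detection and the kink taxonomy

Tentative kinks appear as regions where a 1D profile of the landscape
flattens. `detect_flattening()` estimates the local curvature
$d^2\Delta F/d\rho^2$ by quadratic smoothing over a window of
$2h+1$ points ($h = 5$ by default) and reports contiguous runs of
curvature below a threshold, with the full curvature trace. Candidates are
reported for inspection, never auto-promoted to kink calls — flattening is
judged against the trace, not a hard rule.

`classify_kink()` applies the two-pathway taxonomy seen in strongly bent
DNA: **twist-bend (TB)** kinks combine large positive roll with
undertwisting (roll ≥ 20° and excess twist ≤ −2° by default), as at
protein-induced kinks; **pure-bend (PB)** kinks combine large negative roll
with little excess twist (roll ≤ −20°, |excess twist| ≤ 5°), as in
minicircle simulations and torsionally constrained DNA. The thresholds are
conventions — no measured values exist for them — so they are configurable
and recorded with every call. `asymmetry_metric()` quantifies the
positive/negative-roll asymmetry of a landscape along two guide lines
(slopes −0.6 and −0.1 by default), the signature of the odd (cubic) terms.

## The recovery experiment

`recovery_experiment()` is the package's benchmark: windows every 2.5° over
±25° of roll for the five standard slopes (−0.1 … −0.9), $K = 100$ kJ/mol,
a 25° hard wall, the radial breakage rule, $2\times10^4$ kept samples per
window (100 windows, $2\times10^6$ samples), WHAM on 1° bins, stepwise fit.
It returns truth, oracle and recovered coefficients side by side with fit
standard errors. These problem sizes complete in a few seconds and already
place the Monte Carlo scatter of the recovered coefficients well below the
protocol's own deterministic bias, so larger runs sharpen nothing
qualitative.

What the synthetic data do **not** emulate: sequence dependence, the tilt
degree of freedom (carried but frozen at zero), slow conformational
relaxation and polymorphic twist states of real trajectories, correlated
neighbouring steps, and any structural realism in the breakage rule (the
real criterion is a base-pairing geometry, not a gradient condition). A
passing recovery therefore validates the estimator chain — sampling, WHAM,
stepwise fitting — not the molecular model.

## Known limitations

* No MBAR-style estimator and no uncertainty bands on $\Delta F$; fit
  standard errors ignore correlation between WHAM bins and are best read
  as lower bounds.
* The quartic cross-term is recovered with a systematic protocol bias
  (about −31% on the reference surface) inherited from the 3/7 $k_BT$
  staged cutoffs; the oracle column makes this visible rather than hiding
  it.
* Landscape accuracy at the mask floor is counting-noise limited (see the
  WHAM section).
* Crystal-table twist conventions differ between sources; the package
  exposes raw absolute twist plus the configured intrinsic-twist
  conversion and does not attempt to reconcile conventions.
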