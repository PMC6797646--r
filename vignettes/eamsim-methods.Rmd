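---
title: "Simulating evidence accumulation models with look-up-table noise"
author: "eamsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating evidence accumulation models with look-up-table noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eamsim)
```

## Why this package exists

Evidence accumulation models (EAMs) explain rapid decisions as noisy
evidence racing to a threshold. The linear ballistic accumulator (LBA) and
the Wiener diffusion model have tractable or cheaply computable densities,
but the process-oriented variants — the leaky competing accumulator (LCA),
the urgency-gating model (UGM), piecewise drift changes, per-time-step
drift inputs, collapsing thresholds — generally do not. Those models are
fitted by *mass simulation*: simulate tens of thousands of trials per
candidate parameter set, smooth the simulated response times into an
approximate density, and treat that as a likelihood (probability density
approximation, PDA). The practical bottleneck is that an Euler–Maruyama
simulator spends almost all of its time drawing standard normal variates —
one per accumulator per millisecond time-step per trial.

`eamsim` removes that bottleneck with a look-up-table approximation to
inverse-CDF sampling (LUT-iCDF), implements the simulators themselves in
compiled code behind plain R wrappers, and ships a PDA pseudo-likelihood so
that any optimiser or sampler can consume the simulators.

## The LUT-iCDF sampler

Inverse-CDF sampling maps a uniform variate $u \in (0,1)$ to
$\Phi^{-1}(u)$. The look-up table precomputes $\Phi^{-1}$ on the symmetric,
equally spaced probability grid $x, 2x, \dots, 1-x$ with *granularity* $x$,
giving $N = (1-x)/x$ table entries (the endpoints 0 and 1 are excluded:
they map to $\pm\infty$). Because the grid is uniform and symmetric about
$0.5$, a uniform integer index $k \sim U\{0, \dots, N-1\}$ is an unbiased
discretisation of $u$, and `values[k]` is an approximate standard normal
draw. No search is performed; sampling is one integer draw and one array
read.

The cost of the approximation is exactly quantifiable: the sampled
distribution is discrete with atoms at $\Phi^{-1}(kx)$, and the sup
distance between its CDF and the standard normal CDF equals the granularity
$x$ (the test suite verifies this by enumeration). Coarse tables therefore
truncate the tails — at $x = 0.1$ every draw is one of nine values — while
at the package default $x = 10^{-4}$ (9999 entries) a two-sample
Kolmogorov–Smirnov test cannot distinguish $10^6$ table draws from $10^6$
exact normal draws (KS $\approx 0.001$, the pure sampling-noise level, $p >
0.05$). `validate_granularity()` reproduces this assessment for the normal
distribution and for whole-model simulations, pooling the two alternatives
on a signed response-time axis.

Two further design points:

* **Halved table.** The table is antisymmetric, so `halve_lut()` keeps only
  the non-negative half. `draw_halved()` draws the *full-range* uniform
  integer and maps it onto the half table by reflection, avoiding a
  per-draw sign branch; its draw distribution is identical to the
  full-table sampler, which the tests check with a two-sample KS.
* **Randomness.** All draws — R-level and inside the compiled loops — come
  from R's global RNG (`unif_rand`/`norm_rand`), so a single `set.seed()`
  call makes entire simulations bitwise reproducible. We deliberately use
  the R convention of seeding via `set.seed()` rather than threading seed
  arguments through every function; only `validate_granularity()` and the
  command-line interface expose an explicit seed, because both are
  self-contained reproducibility harnesses.

## The simulators

All simulators return a `trial_set`: per-trial chosen alternative (`resp`,
with 0 marking a trial that never reached threshold), response time in
seconds, and a count of non-terminated trials.

**LBA** (`simulate_lba`). Two independent noiseless accumulators; start
points $k_i \sim U(0, A)$, drifts $d_i \sim N(v_i, s)$ truncated to
positive values (rejection sampling), crossing times $(b - k_i)/d_i$, and
$rt = t_0 + \min_i$. `s` defaults to 1 (the conventional scaling
constraint) and `s = 0` is allowed as a degenerate point mass for
deterministic checks. A flag restores the untruncated drift distribution,
in which case trials whose drifts are all non-positive are flagged
non-terminated.

**Piecewise LBA** (`simulate_plba`). The race runs normally until decision
time $T^* = \mathrm{swaptime} + \mathrm{tdelay}$; surviving trials keep
their accumulated evidence and continue with freshly drawn stage-2 drifts.
Two genuinely open choices are resolved as follows, and matter to users:

* *The switch clock runs in decision time* (excluding $t_0$), treating
  non-decision time as pre-decisional encoding. If your design measures
  the evidence change from stimulus onset, subtract your estimate of
  $t_0$ from `swaptime`.
* *Stage-2 drifts are independent redraws*, the simplest reading of the
  piecewise proposal. A consequence worth knowing: because LBA drift
  persists within a trial, setting the stage-2 drift distribution equal to
  the stage-1 distribution does **not** recover the standard LBA — trials
  that survive to $T^*$ have systematically shallow drifts, and an
  independent redraw resets that selection (with typical parameters the
  signed-RT KS against the standard LBA is ~0.03). The null reductions
  that do hold exactly, and that the tests assert, are a switch beyond the
  response-time support (bitwise, matched seeds) and degenerate $s = 0$
  drifts. For the stochastic models a null drift switch *is* an exact
  reduction, because their within-trial drift is a constant of the
  process, not a per-trial random variable.

**Diffusion** (`simulate_diffusion`). Euler–Maruyama on the relative
evidence: $x \leftarrow x + v\,h + \sigma \sqrt{h}\,\varepsilon$, absorbing
boundaries at $a$ (response 1) and 0 (response 2), start $z$, within-trial
noise fixed at $\sigma = 0.1$ by convention. Between-trial variability
follows the usual full-diffusion scheme: normal drift variability `sv`,
uniform start-point width `sz` centred on `z`, uniform non-decision-time
width `ster` centred on `ter`. Boundaries are checked *after* each update
with inclusive crossings and no overshoot interpolation — the plain
C-loop semantics. Time-varying drifts and boundaries are per-step profile
vectors; a piecewise change is a (`swap_time`, `t_delay`, `v2`) triple.

**LCA** (`simulate_lca`). $K \ge 2$ accumulators starting at 0 with
leakage `lam`, a single lateral inhibition/excitation balance `beta`
(positive = net inhibition), and a reflecting floor at zero applied after
the full update including noise — the model's defining non-linearity.
Threshold crossings are checked after each step in accumulator order, so
simultaneous crossings resolve to the lowest index. Per-alternative
time-varying drifts and thresholds are `max_steps x K` matrices.

**UGM** (`simulate_ugm`). The momentary input
$r = v + \sigma\varepsilon/\sqrt{h}$ is low-pass filtered with a first-order
Euler step, $E \leftarrow E + (h/\tau)(r - E)$, and the decision variable
$y = E \cdot (u_0 + u_1 \cdot 1000t)$ is compared against symmetric
thresholds $\pm a$. The filter discretisation, the linear-in-milliseconds
urgency with optional intercept ($u_0 = 0$, $u_1 = 1$ by default, i.e.
urgency equals elapsed milliseconds), and the symmetric threshold geometry
are our documented choices; the literature defers these details to
individual applications, and all three are plain parameters or profiles
here. Note the filter time constant is conventionally kept under 0.25 s.

**Collapsing thresholds.** There is no consensus functional form for
dynamic thresholds, so the simulators accept arbitrary per-step profiles
and the package only ships generators for the two common families:
`linear_collapse()` and the three-parameter Weibull relaxation
`weibull_collapse()` ($a(t) = a_\infty + (a_0 - a_\infty)
e^{-(t/\lambda)^k}$).

## Numerical choices that matter

* **Time step.** `h` is in seconds, default 1 ms, with `max_steps`
  bounding the decision horizon. Non-terminated trials are reported, not
  hidden; when comparing choice probabilities against analytic results,
  use a horizon long enough that the non-terminated mass is negligible.
* **Discretisation bias.** Checking boundaries only at step ends biases
  first-passage simulation as if the boundaries sat about
  $0.5826\,\sigma\sqrt{h}$ further out (the standard continuity
  correction). At $h = 1$ ms and $\sigma = 0.1$ this shifts diffusion
  choice probabilities by up to ~0.02 for off-centre start points. The
  test suite verifies the simulator against the closed-form Wiener
  absorption probability *with* this correction at tight tolerance, and
  against the uncorrected form with the correspondingly sized
  $O(\sqrt{h})$ allowance. Users who need smaller bias should reduce `h`,
  paying time linearly.
* **Piecewise step mapping.** A switch at decision time $T^*$ applies from
  the first step whose start time reaches $T^*$ (step $s$ spans
  $[sh, (s+1)h)$).
* **Between-trial draws.** Trial-level variabilities (`sv`, `sz`, `ster`)
  are drawn in the R wrapper before the compiled loop runs, in a fixed
  order, so matched-seed comparisons across schedule variants are
  meaningful; degenerate widths still consume their draws, keeping the
  noise stream aligned across nested model variants.

## The PDA pseudo-likelihood

`log_dens_like()` evaluates, per condition: simulate `n_sim` trials
(default $10^4$; raise it for final fits), split by response alternative,
smooth each alternative's simulated response times with a Gaussian kernel
(`stats::density`) on a 512-point grid spanning the simulated range
extended by three bandwidths, evaluate the observed response times on that
grid by linear interpolation (`stats::approx`), and sum the log densities.

Design decisions, each overridable:

* **Defective scaling.** Each alternative's density is multiplied by its
  simulated response proportion (computed against *all* simulated trials,
  non-terminated included), so the densities jointly integrate to the
  terminated fraction and choice probabilities enter the likelihood. The
  smoothing-only behaviour is available with `defective = FALSE`, but
  without the scaling a model could fit response-time shape while
  predicting the wrong choice rates unpunished.
* **Bandwidth.** Silverman's rule of thumb,
  $0.9 \min(\mathrm{SD}, \mathrm{IQR}/1.34)\, n^{-1/5}$, computed on each
  alternative's *simulated* sample (the PDA convention), with a fixed
  user bandwidth as an option.
* **Floor.** Interpolated densities below $10^{-10}$ — including observed
  times outside the simulated support — are floored there, so the
  log-likelihood is always finite. The floor is far below any plausible
  kernel density at the simulation sizes involved, so it acts only as an
  outlier guard.
* **Non-terminated trials** are counted and attached as an attribute; no
  penalty is added by default because there is no canonical penalty form.
  Parameter regions producing many unabsorbed trials already lose
  likelihood through the defective weights.

The simulation noise in the likelihood surface is controlled by the seed:
re-seeding identically before two evaluations at different parameters
compares them on common random numbers, which the recovery tests exploit.

## What the tests do and do not show

The suite is built on synthetic data only — data simulated by these same
model families. That is the appropriate oracle for a simulation framework
(every generating process is known exactly), and the independent checks
are chosen so implementation errors cannot self-cancel: a numeric
integration oracle for LBA choice probabilities, the closed-form Wiener
absorption probability, a plain-R independent-race simulation for the
frictionless LCA, direct recursion for the noise-free UGM, and
paired LUT-versus-exact-normal runs for every model variant. The
problem sizes are fixed in the tests themselves: $10^6$ draws for the
granularity assessment, $10^5$ trials for distributional comparisons,
$2{,}000$ observations with $10^4$–$10^5$ simulated trials per likelihood
evaluation for the recovery checks.

What passing does *not* show: that any of these models fits real
behavioural data, that parameters estimated from real data are
well-identified (the LCA in particular is known to recover poorly in some
designs), or that the PDA surface is smooth enough for gradient-based
optimisers (it is noisy by construction; use common random numbers or
derivative-free methods). The framework also deliberately excludes exact
(non-discretised) first-passage samplers, analytic LBA densities, and any
MCMC or optimisation driver — the pseudo-likelihood is the product, and
fitting machinery is the consumer's choice.

## Known limitations

* Two response alternatives for the LBA, diffusion, and UGM; the LCA
  supports any $K \ge 2$.
* The direct-mapping table variant (nearest-neighbour search over an
  uneven grid) is intentionally absent: searching costs more than it
  saves unless the table is shrunk drastically.
* Timing comparisons (`benchmark` subcommand) are informational only;
  relative speed-ups depend on hardware and BLAS/RNG details.
* The KS p-values use the asymptotic two-sample distribution, appropriate
  at the $n \ge 10^4$ sizes the harness enforces.
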