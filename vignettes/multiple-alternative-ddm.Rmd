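---
title: "Multiple-alternative drift-diffusion models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-alternative drift-diffusion models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiddm)
```

# The model family

`multiddm` simulates perceptual decision making among $n$ alternatives at
three levels of description, and the exact reductions that connect them.

## Competition basis

All reductions use one coordinate system. Population-rate space
$\mathbb{R}^n$ splits into the all-ones ("common") direction and its
orthogonal complement, the zero-sum subspace where competition happens. We
span that subspace with the $n-1$ orthogonal vectors

$$ e_k = (\underbrace{1,\dots,1}_{k}, -k, 0, \dots, 0), \qquad
   e_k \cdot e_k = k + k^2 , $$

so $e_1 = (1,-1,0,\dots)$ contrasts the first two alternatives,
$e_2 = (1,1,-2,0,\dots)$ contrasts the first two against the third, and so
on. The decision variables are the normalized projections
$X_k = e_k \cdot r / (k+k^2)$ and the common mode is $m_C = \bar r$. The
choice of basis is what makes every construction below closed-form for
arbitrary $n$: because each $e_k$ is orthogonal to the ones vector, global
inhibition, common input and - in the Bayesian test - the log-normalizer all
drop out of the decision-variable dynamics. `competition_basis()`,
`project_modes()` and `reconstruct_rates()` implement the coordinate system;
the reconstruction has the closed form
$r_i = -(i-1)X_{i-1} + \sum_{l \ge i} X_l + m_C$, which is also the decision
rule evaluated by every simulator ("population $i$ wins when its
reconstructed coordinate reaches the threshold").

## Rate networks

The mechanistic level is a firing-rate network of $n$ excitatory populations
with self-coupling $s$ and a single global inhibitory population
(`network_params()`, `simulate_linear()`, `simulate_nonlinear()`):

$$ \tau \dot r_i = -r_i + \phi(s r_i - c r_I + I_i) + \xi_i(t), \qquad
   \tau_I \dot r_I = -r_I + \phi_I\Big(\tfrac{g}{n}\textstyle\sum_j r_j +
   I_I\Big) + \xi_I(t). $$

Two conventions matter for everything downstream:

* **Noise.** The white-noise terms sit inside $\tau \dot r$ and are additive
  on the rates (they model firing-rate fluctuations, not input fluctuations),
  so an Euler-Maruyama step perturbs each rate by $\sigma \sqrt{dt}/\tau$.
  Reaction-time scales depend on this; it is stated on every simulator.
  Rates are not clipped at zero: the transfer function's zero branch handles
  non-negativity of the drive, and additive noise may push rates transiently
  negative.
* **Integration.** All stochastic simulators use Euler-Maruyama, default
  $dt = 0.1$ ms for networks (halving $dt$ changes first-passage statistics
  by less than the Monte-Carlo error at the default noise levels). Decisions
  are detected at the first post-step crossing with no sub-step
  interpolation, which is what makes the exact shared-noise equivalence
  tests possible (interpolation would break them); the cost is a small
  $O(\sqrt{dt})$ first-passage bias, common to all models compared.

For the linear network ($\phi$ the identity) at the balanced point $s = 1$,
the projections $X_k$ are exactly drift-diffusion processes - zero leak,
drift $e_k \cdot I/(k+k^2)$, projected noise - while the common and
inhibitory modes form a damped 2-by-2 subsystem
(`linear_mode_eigenvalues()`, `mode_steady_state()`). The package treats the
inhibitory population as a separate scalar throughout; the competition basis
lives in excitatory-rate space only.

For nonlinear $\phi$, `find_fixed_point()` solves the symmetric state,
`nonlinear_eigenvalues()` gives the closed-form spectrum (the competition
eigenvalue $-(1-s\phi')/\tau$ with multiplicity $n-1$), and
`find_bifurcation()` locates the common input at which $s\phi' = 1$ and the
winner-take-all instability appears.

The reference nonlinear configuration used in tests and examples is the
expansive-saturating transfer function $\phi(x) = 0$ for $x<0$, $x^2$ on
$[0,1]$, $2\sqrt{x - 3/4}$ for $x>1$ (`transfer_piecewise_sqrt()`), with
$\tau = 20$ ms, $\tau_I = 10$ ms, $s = c = g = 1$. The inhibitory
nonlinearity and input are not uniquely determined by that configuration's
published operating point; we take $\phi_I$ = identity and $I_I = 0$, the
completion under which the symmetric rate is exactly $R = 1/4$ and the
bifurcation sits exactly at $I_0 = 1/2$ (the alternative completion
$\phi_I = \phi$, $I_I = 1/4$ is also self-consistent but is not used). The
piecewise $\phi$ has one-sided second and third derivatives at its knots
(the quadratic piece owns both knots); normal-form coefficients should only
be evaluated away from the knots.

## Linear DDM and Hick's law

`ddm_params()` / `simulate_ddm_trial()` simulate the reduced
$(n-1)$-dimensional DDM directly. Noise is always generated in population
space ($n$ independent streams) and projected - never drawn independently
per decision variable - so the cross-correlations of the $X_k$ are exact for
any $n$ and the network-equivalence test is exact rather than statistical.
A trial ends at the first step where any reconstructed coordinate reaches
$\theta$ (ties: largest overshoot, then lowest index); for $n = 3$ the three
boundaries form a triangle in the $(X_1, X_2)$ plane. "Correct" means the
argmax of the input vector; tied inputs leave correctness undefined and such
trials are excluded from accuracy. Trials still undecided at `t_max` are
excluded from accuracy and RT statistics and counted separately.

`hicks_experiment()` holds accuracy fixed while increasing $n$: it
recalibrates $\theta$ per $n$ by bisection (accuracy is monotone in
$\theta$; common random numbers across evaluations), simulates a block, and
fits $RT = a + b\ln(c + n)$ by nonlinear least squares
(`minpack.lm::nlsLM`), alongside a linear-in-$n$ fit for comparison and a
regression of RT variance on mean RT. The absolute drift magnitude behind
the published version of this experiment is not recoverable, so the drift is
an explicit parameter; the logarithmic law and the variance-mean
proportionality are properties of the mechanism, not of a particular drift.
Defaults used by the test suite: $\sigma = 1$, $\tau = 20$ ms, $\theta = 3$
at $n = 2$ (which yields 80% accuracy with drift $I_1 = 0.0116$), $dt = 1$-$2$
ms, 2,000 trials per block - sizes chosen to keep Monte-Carlo error well
below the effects under test. Because each $n$ is recalibrated from finite
blocks, achieved accuracies carry $\pm 0.015$ jitter; trend statements about
RT versus $n$ are therefore made on ranks, not element-wise.

## Bayesian MSPRT and the moving threshold

For the statistical level (`msprt_params()` and friends), evidence for
alternative $i$ accrues as $dy_i = I_i\,dt + \sigma\sqrt{dt}\,N(0,1)$
($\tau = 1$ units). With equal priors, the normalized log-posterior is
exactly $L_i = y_i - \operatorname{logsumexp}(y)$, and its common mode obeys

$$ \dot M_C = \tfrac{1}{n}\textstyle\sum_j z_j -
   \frac{\sum_k z_k e^{y_k}}{\sum_k e^{y_k}} . $$

The test reports alternative $i$ when the competition part of the
log-posterior exceeds $\theta - M_C(t)$: a drift-diffusion model in the same
competition coordinates, with a *moving* threshold. Because the
moving-threshold DDM route (`simulate_mt_ddm_trial()`) accumulates the
projected increments and the Bayesian route (`simulate_bayesian_trial()`)
integrates the log-posteriors, and both subtract the same common mode, the
two are algebraically identical and produce the same choice and reaction
time on every shared-noise trial - an exact identity the test suite asserts
trial by trial, not a statistical one. `simulate_fixed_ddm_trial()` replaces
the moving bound by a constant for comparison, and
`calibrate_fixed_threshold()` matches its zero-coherence mean RT to the
Bayesian model's by bisection on common random numbers (per-trial seeded
streams, so mean RT is exactly monotone in the threshold and the root is
stable).

**The threshold convention deserves care, and the package implements two.**
The printed rule "decide when $L_i > \theta$" cannot apply literally to the
normalized log-posterior, which is bounded above by 0 while $\theta > 0$.
Everything hinges on how $M_C$, integrated from $M_C(0) = 0$, is computed:

* `update = "euler"` (default): $M_C$ is advanced by an Euler-Maruyama step
  of its ODE, $\Delta M_C = \overline{\Delta y} - \sum_k w_k \Delta y_k$
  with softmax weights $w = \operatorname{softmax}(y)$ at the pre-step
  state. This linear-in-$\Delta y$ step omits the Ito correction of
  $\operatorname{logsumexp}$, about
  $\tfrac{1}{2}\sigma^2\big(1 - \sum_k w_k^2\big)$ per unit time, so at zero
  coherence $M_C$ stays near zero instead of drifting downward, and the
  moving bound stays near $\theta$. This is the behavior of a direct
  Euler-Maruyama implementation of the published equations, and it is the
  convention under which the published calibration is reproduced: with
  $n = 3$, $\sigma = 0.03$, $\theta = 1.05$, the matched fixed threshold
  comes out at $\approx 1.07$-$1.08$.
* `update = "exact"`: $M_C = \bar y - \operatorname{logsumexp}(y) + \ln n$,
  the exact continuum integral. The decision rule is then precisely the
  posterior criterion $\exp(L_i) \ge e^{\theta}/n$, which is satisfiable
  only for $\theta < \ln n$ (validated with a warning). This variant is
  cleaner as a statistical test but substantially more conservative at the
  same $\theta$: the accumulated Ito term makes the bound grow without
  bound, zero-coherence reaction times are roughly four times longer at the
  parameters above, and the matched fixed threshold is then near 2.4 rather
  than 1.07. Both variants are implemented and tested; the identity between
  the Bayesian and moving-threshold routes, the long-time common-mode drift
  $\langle\dot M_C\rangle \to -\tfrac{1}{n}\sum_j |I_j - I_l|$, and the
  slower-errors signature hold under either.

In both variants the *reported* posterior state is the exactly normalized
one, so $\sum_i e^{L_i} = 1$ holds to machine precision at every step, and
`posterior_at_decision` is a true posterior probability.

## Nonlinear DDMs (stochastic normal forms)

Near the winner-take-all bifurcation the network collapses onto the
competition subspace. For $n = 2$ the reflection symmetry of the two-way
competition forbids quadratic terms and the reduction is the cubic
(pitchfork) normal form with coefficients
$\eta = \phi'/2$, $\mu = s^2\phi''/(cg\phi_I')$,
$\gamma = \frac{s^3(\phi'')^2}{2cg\phi'\phi_I'}(s - cg\phi_I') +
\frac{s^3\phi'''}{6}$ (`nf_coefficients_2afc()`; $\gamma < 0$ supercritical,
$\gamma > 0$ subcritical and multi-stable). For $n \ge 3$ there is no such
symmetry, the leading nonlinearity is quadratic, and the $k$-th decision
variable obeys

$$ \tau \dot X_k = a\,\frac{e_k \cdot \bar I}{k+k^2}
   + \frac{b}{2(k+k^2)}\Big( \sum_{j<k}(j+j^2)X_j^2 - k(k^2-1)X_k^2
   + 2(k+k^2)X_k \sum_{j>k} X_j \Big)
   + \frac{e_k \cdot \xi}{k+k^2}, $$

with $a = \phi'$ and $b = s^2\phi''$ for the network family above
(`potential_model()`, `nf_drift()`). The two reductions are genuinely
different objects (different small-parameter scalings), so the package
dispatches on $n$ rather than treating one as a special case of the other.
The whole quadratic drift field is the scaled negative gradient of a single
potential (`nf_potential()`),

$$ f(X) = -a\sum_j (e_j \cdot \bar I) X_j - \frac{b}{2}\Big(
   \sum_{j=1}^{n-2}(j+j^2)X_j^2 \sum_{i>j} X_i -
   \sum_{j=1}^{n-1}\frac{j(j^2-1)}{3}X_j^3 \Big), \qquad
   \tau\dot X_k = -\frac{1}{k+k^2}\frac{\partial f}{\partial X_k} + \dots $$

so noise-free decision dynamics is potential descent ($\dot f \le 0$, an
asserted invariant) and noisy dynamics is diffusion on that landscape. One
printed expansion of the component equations contains a final line (the
$X_{n-1}$ row) whose self-quadratic coefficient is inconsistent with the
general-$k$ formula; we implement the general formula, which is exactly the
gradient of the potential (verified symbolically for $n = 3$ and by finite
differences for $n$ up to 7) and reduces term by term to the printed $n = 3$
system. The noise on the quadratic normal form is not printed in the source
material beyond $n = 3$; we use the same projected population noise as the
linear DDM, $e_k \cdot \xi/(k+k^2)$, which matches the printed $n = 3$
terms.

Because the quadratic flow is globally unstable ($X \to \pm\infty$), every
normal-form trial carries a divergence cap (default $10\,\theta/\epsilon$);
hitting the cap without a decision is recorded as a capped trial, not an
error. Decisions use the same reconstruction rule as the linear DDM, by
default on the rate scale $R_0 + \epsilon\,\mathrm{recon}_i(X) \ge \theta$
(matching thresholds stated on firing rates); a pure $X$-space mode is also
provided.

`track_network()` is the consistency harness: it simulates the full
nonlinear network at its bifurcation and the quadratic normal form from
matched initial conditions and *shared* population-noise streams (the normal
form's noise is the projection of the same draws), and reports winner
agreement, reaction-time differences, and the sup-norm deviation between
network rates and the reconstruction $R + \epsilon\sum_k e_k X_k$. At the
reference configuration ($\sigma = 0.01$, threshold $1/2$ on the rates) the
winner agreement exceeds 90% over shared-noise trials; deterministic runs
with a small input advantage agree on the winner and show the expected
shrinking of the deviation as the perturbation shrinks.

# Experiment harnesses and reproducibility

`experiment_config()` / `run_experiment()` wrap the three standing
experiments (`hicks`, `fig2`, `fig3`) behind a validated, YAML-serializable
configuration with a master seed; outputs are CSV trial tables, JSON
summaries and a provenance record, and identical configurations produce
byte-identical outputs. Per-trial seeds are derived from the master seed by
a counter scheme so any single trial is reproducible in isolation. Times are
reported in milliseconds for the network-time models ($\tau = 20$ ms) and in
dimensionless $\tau = 1$ units for the MSPRT; the unit is part of the column
name or documentation, never implicit. A thin command-line wrapper lives at
`inst/scripts/multiddm.R`.

# What the simulations do and do not establish

All inputs here are synthetic by construction - the package's subject matter
is the model family itself, not data fitting. Passing tests establish the
internal mathematics (exact reductions, gradient structure, closed-form
spectra, first-passage statistics against standard closed forms) and the
qualitative signatures those models predict (Hick's logarithmic law at fixed
accuracy, variance proportional to mean RT, slower errors for the Bayesian
test). They do not establish that any of these models fit behavioral or
neural data; across-trial drift variability, non-Gaussian evidence, unequal
priors, input (as opposed to rate) noise, and spiking or conductance-based
dynamics are all out of scope.

# Numerical choices, in one place

* Euler-Maruyama everywhere; network $dt = 0.1$ ms, MSPRT $dt = 0.05$
  ($\tau = 1$), MSPRT `t_max` $= 10^4$; first-crossing detection without
  interpolation.
* Noise increments $\sigma\sqrt{dt}/\tau$ on rates, $\sigma\sqrt{dt}$ on
  evidence; population-space noise projected onto the basis, never drawn in
  $X$-space.
* Root finding: `uniroot` at tolerance $10^{-10}$-$10^{-12}$ (fixed points,
  bifurcations); bisection with common random numbers for the two
  calibrations (accuracy-vs-threshold, RT-vs-threshold).
* Thresholds: reconstruction rule with ties broken by largest overshoot,
  then lowest index; undecided-at-`t_max` is a recorded outcome, never an
  error; capped normal-form trials likewise.
* Monte-Carlo problem sizes in the test suite (chosen so the sampling error
  sits well below each effect under test): 20,000 trials for the
  first-passage closed-form checks, 10,000 for the threshold calibration and
  the error-RT comparisons, 2,000 per block for the Hick's sweep over
  $n = 2..10$, 3,000 for winner-symmetry checks, 100-200 draws for
  property-style algebraic checks.
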