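---
title: "Fast and slow learning in parallel pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast and slow learning in parallel pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twopathway)
```

# The model

`twopathway` simulates a downstream population of `N_z` binary readout units
(in the motor-circuit interpretation: sensorimotor striatum) driven by two
input pathways with different plasticity:

* a **fast pathway** (cortical; `N_x` inputs, weights `W`) trained by a
  one-step supervised margin rule, and
* a **slow pathway** (thalamic; `N_y` inputs, weights `V`) trained by a
  Hebbian rule with weight decay.

Inputs are i.i.d. standard-normal patterns `x`, `y` with random binary targets
`zhat`; the readout is `z = sgn(W x + V y)`.

**Fast pathway.** When pattern `mu` is presented and the total current
`u = m + h` (with `m = W x`, `h = V y`) fails the margin condition
`u * zhat >= kappa`, the weights jump so that the new current sits on the
correct side of the boundary with margin `kappa`:

    dW_i = (kappa * zhat_i - u_i) x^T / D,

with `D = N_x` in the canonical form or `D = |x|^2` in the exact-margin form.
Because `kappa` can be absorbed into the weight norm, `kappa = 1` throughout.

**Slow pathway.** Each presentation applies

    dV = -(alpha * n_mu / (N_y * nbar)) V
         + sqrt(2) * (beta * n_mu / (N_y * nbar)) zhat y^T,

a Hebbian increment along the (pre x post) outer product plus a decay that
keeps `|V|` bounded. `n_mu` is the number of times pattern `mu` is repeated
when trained and `nbar` the schedule mean of `n_mu`. The supervised step runs
before the Hebbian step within a presentation (fast learning is fast), and
the rule uses the target rather than the realized output, which is justified
while performance is high — see the habit-formation discussion below for the
one protocol where the distinction matters.

The slow pathway has no error signal. Its computational role emerges across
repetitions: a pattern repeated `n` times accumulates a slow-pathway current
of about `sqrt(2) * beta * n / nbar` along the target, which (i) makes the
memory resistant to overwriting by later learning, (ii) aligns the two
pathways' currents (**input alignment**), and (iii) shifts the drive of the
readout from the fast to the slow pathway (**control transfer**).

# Forgetting theory

Under sequential training (each pattern trained once, never revisited),
recall of pattern `nu` after `P - nu` further patterns degrades with the
normalized lag `tau = (P - nu) / N_x` only. `theoretical_error_single()` and
`theoretical_error_two_pathway()` evaluate the curves semi-analytically by a
mean-field drift-diffusion argument:

1. **Stationary statistics.** For a fresh random pattern the total current is
   Gaussian with variance `sigma_u^2 = sigma_w^2 + sigma_h^2`. The
   slow-pathway part is an Ornstein-Uhlenbeck balance of Hebbian kicks
   against decay, `sigma_h^2 = beta^2 / alpha`. The fast-pathway part is
   fixed by requiring that margin updates neither grow nor shrink `|W|` on
   average, which reduces to the scalar root-finding problem

       (kappa^2 + 2 sigma_h^2 - sigma_u^2) * Phi(kappa / sigma_u)
         + kappa * sigma_u * phi(kappa / sigma_u) = 0,

   solved by `stationary_input_stats()`. A random pattern then triggers an
   update with probability `q = Phi(kappa / sigma_u)`.
2. **Post-training dynamics.** The stored pattern's fast current decays by
   `exp(-q tau)` while diffusing back to variance `sigma_w^2`; its slow
   current decays by `exp(-alpha tau / (N_y/N_x))` while diffusing back to
   `sigma_h^2`. The initial condition mixes "update fired, current jumped to
   the margin" with "margin already satisfied" branches, and `n` consecutive
   repetitions add `sqrt(2) beta n / nbar` to the slow current.
3. **Error.** The recall error is the Gaussian probability that the decayed
   signal has crossed zero, computed by nested adaptive quadrature
   (relative tolerance `1e-6`).

The evaluator is validated against the Monte-Carlo simulators in the test
suite; at `N_x = 1000` the mean-field bias is below ~0.01 everywhere we
measured, well inside Monte-Carlo noise at the run counts used. Useful
consequences of the theory, all covered by tests: curves collapse across
`N_x`; practice shifts curves in parallel (horizontal shifts agree across
error levels to a few percent); and the repetitions needed to keep error
below a threshold grow exponentially — hence supralinearly — with the
training–testing interval.

```{r theory-example}
theory_curve(c(0.25, 0.5, 1, 2), beta = 1, n_ratio = 10)
```

# What the generator emulates

`generate_patterns()` draws the study conditions used throughout: i.i.d.
standard-normal inputs and fair binary targets, with a repetition schedule
(`make_repetition_schedule()`) that can repeat chosen patterns consecutively
or with interleaved gaps (spaced repetition). These are the idealized
conditions the theory averages over. Real sensory or motor representations
are correlated, low-dimensional, and non-stationary; none of that is
modeled, so passing tests demonstrate the mechanisms (palimpsest forgetting,
repetition-driven protection, control transfer), not quantitative fits to
biological data.

Monte-Carlo forgetting estimators prepend a burn-in of `4 * N_x` extra
patterns (trained, never tested) so that tested patterns see the stationary
weight regime; weights start at zero. States for the population-level
and reinforcement-learning experiments default instead to random
initialization with O(1) currents per unit (`init = "random"`), emulating an
untrained but active network — with zero initialization the two pathways of
the RL+RL control degenerate to exactly proportional currents and the
contrast with RL+HL cannot be probed.

# Key parameters

| parameter | meaning | default |
|---|---|---|
| `kappa` | classification margin (unitless) | 1 |
| `alpha` | slow-pathway decay rate per `N_y * nbar` presentations | 1 |
| `beta`  | slow-pathway Hebbian rate (current `sqrt(2) beta` per repetition) | 1 |
| `n_mu`, `nbar` | repetitions of a pattern; schedule mean | 1 |
| `eta` | REINFORCE rate of the fast pathway | 1 |
| `beta` (RL+HL) / `eta2` (RL+RL) | slow-pathway rate in the RL variants | 0.01 |
| `tau_R` | reward-baseline time constant (trials) | 10 |
| `eta_SL`, `eta_HL` | reaching-task learning rates | 1e-3, 1e-6 |

# Numerical and design choices

* **`sgn(0) = +1`** everywhere, for determinism (a measure-zero event).
* **Cycled-training convergence.** The exact-projection margin update leaves
  freshly updated patterns *on* the margin, so other patterns' margins can
  hover an infinitesimal distance below `kappa` indefinitely and a strict
  "no updates in a pass" test never fires even far below capacity.
  `train_cycled()` therefore declares convergence when no pattern violates
  the margin by more than `tol = 1e-6` in a full pass; the update rule is
  unchanged. With this criterion the converged fraction at `N_x = 200`
  crosses 1/2 near a load of 2 patterns per synapse.
* **Gradient-descent variant.** The incremental-learning loss is the hinge
  `max(0, kappa - u * zhat)`, whose minimum reproduces the margin condition.
* **Hebbian application mode.** `per_repetition` (default) applies the rule
  once per presentation with `n_mu = 1`, matching protocols that track
  alignment per repetition; `aggregated` applies one combined update with
  the full `n_mu`. The two agree closely for small `beta` (tested).
* **Habit experiments use the realized output.** After the reward target is
  switched, the slow pathway has no access to the new target; writing the
  Hebbian rule with the *realized* activity makes it reinforce whatever the
  population actually does, so a practiced association becomes
  self-sustaining and harder to unlearn the more it was practiced. With the
  target-based form the slow pathway would be silently supervised onto the
  new target and would dissolve the habit on a fixed timescale `N_y/alpha`
  independent of practice — inverting the phenomenon. `train_rl()` keeps the
  target-based form as its default (the two coincide while performance is
  high); `habit_experiment()` defaults to the realized-output form.
* **Reaching-task feedback.** The input populations receive fixed random
  projections of the network readout of the previous timestep (the velocity
  command), plus a tonic target cue. A position-feedback variant is
  provided. The velocity form produces strong interference between targets
  trained in sequence, and with it the clear retention contrast between the
  SL-only and SL+HL conditions; with position feedback the cue-dominated
  inputs barely overlap across targets and sequential forgetting itself is
  weak.
* **Reaching-task gradient.** Per-trial batch gradient descent on the summed
  per-step squared velocity errors, truncated at the feedback loop (no
  backpropagation through time); the reported loss is the mean squared
  error per step and output dimension. Trials per block are not dictated by
  the model; the defaults (2000 for the practiced target, 500 for the
  others) let the first block's loss plateau at `eta_SL = 1e-3` while the
  Hebbian current accumulates to O(1) per hidden unit.
* **Readout/hidden details.** Hidden units are `tanh` (a saturating odd
  nonlinearity; a hard sign is not differentiable), the 2-D linear readout is
  fixed at construction, `W` starts at fan-in-scaled random values and `V`
  at zero.

# Problem sizes

Full experiment presets use the figure-scale dimensions
(`N_x = N_y = N_z = 1000`, `alpha = beta = 1`); the test suite and the
`"desk"` preset run the same protocols at reduced scale (dimensions 250-1000,
tens to a few hundred Monte-Carlo runs), chosen so the whole suite completes
in minutes while every directional comparison retains a 3-standard-error
margin. The acceptance script estimates the perceptron capacity at
`N_x = 200` with 20 seeds per load and verifies exact margin attainment on
10^3 random cases.

# Known limitations

* The drift-diffusion evaluator is mean-field: it neglects correlations
  between successive updates and the O(1/sqrt(N)) fluctuations of
  `|x|^2/N_x`, so it is biased at small `N_x` (visibly below ~100).
* The two-pathway theory assumes repeated patterns are a vanishing fraction
  of the schedule (`nbar` near 1) and repetitions are consecutive; spaced
  schedules are simulated, not evaluated analytically.
* Inputs are uncorrelated Gaussians; structured or correlated inputs, plastic
  slow-pathway representations, and recurrent readout dynamics are out of
  scope.
* Reinforcement learning covers single-step actions on fixed patterns;
  action sequences and temporal-difference learning are not modeled.
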