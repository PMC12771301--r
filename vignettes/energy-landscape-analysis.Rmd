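---
title: "Energy landscape analysis of binarized brain activity states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscape analysis of binarized brain activity states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elascape)
```

## The model

Energy landscape analysis treats multichannel brain activity as motion over
a discrete landscape. Given $N$ regions of interest (ROIs), each time point
of a recording is reduced to an *activity state*
$\sigma = (\sigma_1, \dots, \sigma_N) \in \{-1, +1\}^N$ — active or
inactive per region — so $2^N$ states exist. The least-structured
distribution over states that matches the data's first moments
$\langle\sigma_i\rangle$ and second moments
$\langle\sigma_i\sigma_j\rangle$ is the pairwise maximum-entropy (Ising)
model

$$P(\sigma \mid h, J) = \frac{e^{-E(\sigma)}}{\sum_{\sigma'} e^{-E(\sigma')}},
\qquad
E(\sigma) = -\sum_i h_i \sigma_i
            - \tfrac{1}{2}\sum_i \sum_{j \ne i} J_{ij}\sigma_i\sigma_j,$$

with per-region biases $h_i$ and symmetric, zero-diagonal pairwise
couplings $J_{ij}$ (all dimensionless; an inverse temperature would be
absorbed into the parameters). Low energy means high probability. The
landscape's *local minima* — states strictly below all $N$ single-flip
neighbours — are attractors; the *barriers* between them govern how easily
the system moves from one attractor to another.

All computations here enumerate the full state space exactly, which caps
$N$ at 15 ($2^{15} = 32768$ states). That bound is intrinsic to the method:
it is why ROI selection matters in practice, and why this package is aimed
at small, hypothesis-driven ROI sets (the bundled defaults use a 7-ROI set:
STG, toITG, Vis.Primary, AUD, Cerebellum, BSL, THL).

## Binarization and state indexing

`binarize()` thresholds each region at its own time average: strictly above
the mean is $+1$, otherwise $-1$. Two choices are fixed deliberately:

* **Tie rule.** A sample exactly equal to the mean maps to $-1$. Ties have
  measure zero for real-valued signals, but a fixed rule makes the
  degenerate cases (e.g. a constant region, which also warns)
  reproducible.
* **Bit order.** `state_index()` reads a pattern as a binary word with
  $-1 \mapsto 0$, $+1 \mapsto 1$ and the *first-listed region as the most
  significant bit*, plus one: the all-inactive state is 1 and the
  all-active state is $2^N$. Any fixed convention works — occupancy
  statistics and the landscape are invariant under consistent relabelling
  (this is property-tested) — but published state labels are only
  comparable under the same convention, so ours is stated explicitly.

## Fitting: exact maximum likelihood by moment matching

`fit_mem()` maximises the exact log-likelihood
$\sum_t \log P(\sigma(t) \mid h, J)$. Its gradient is the gap between
empirical and model moments, with model moments computed by exact
enumeration, so convergence is declared when
$\max\bigl(|\langle\sigma_i\rangle_{data} - \langle\sigma_i\rangle_{model}|,
|\langle\sigma_i\sigma_j\rangle_{data} -
\langle\sigma_i\sigma_j\rangle_{model}|\bigr) \le$ `tol` (default
$10^{-5}$) — the defining property of the maximum-entropy solution, and the
quantity every fit is tested on.

The default ascent is damped Newton: the Hessian of the log-likelihood is
the model covariance of the sufficient statistics, available in closed form
from the same enumeration, and the objective is concave with at most
$N + N(N-1)/2 \le 120$ parameters. Newton therefore converges in a handful
of iterations, which matters because a cohort analysis performs one fit per
subject plus group-level fits. A plain gradient ascent with backtracking
line search is available (`method = "gradient"`); a test asserts the two
agree. Both schemes only accept steps that do not decrease the objective.

Numerical details worth knowing:

* Initialisation is $h_i = \mathrm{atanh}(\langle\sigma_i\rangle)$
  (clipped at $\pm 0.999$), $J = 0$ — the exact solution of the
  independent model.
* Boltzmann probabilities are computed after subtracting the minimum
  energy; the distribution is invariant under constant energy shifts, so
  this is pure overflow protection.
* Pure maximum likelihood is the default. If a moment sits on its boundary
  (a region that never changes sign, or a pair in perfect lockstep) the
  optimum lies at infinity; the moment-gap rule then halts at an extreme
  but finite parameter (e.g. $h \approx 6.1$ for a constant region at
  `tol = 1e-5`). An optional ridge penalty (`l2`) keeps such estimates
  moderate and is recorded in the fit report; convergence is then judged
  on the penalised gradient.
* `converged = FALSE` is reported — never silently — when the iteration
  cap is reached.
* Each report carries $KL(\hat p \,\|\, p_{model})$ and its ratio to
  $KL(\hat p \,\|\, p_{indep})$ as a fit-quality diagnostic
  (`fit_accuracy` near 1 means the pairwise model captures nearly all the
  structure the independent model misses).

## Landscape topology

Given an exact energy table:

* **Minima** (`find_local_minima()`) use the *strict* definition. Plateau
  states with an equal-energy neighbour are not minima: with continuously
  fitted parameters exact ties have measure zero, and strictness gives a
  unique, testable definition.
* **Basins** (`assign_basins()`) follow steepest descent to the
  lowest-energy neighbour, ties broken by smallest state index, until a
  minimum is reached. The tie-break is arbitrary but fixed and portable.
* **Barriers** (`barrier()`) use the minimax objective: the barrier
  between $a$ and $b$ is the minimum over hypercube paths of the maximum
  energy along the path, endpoints included — computed exactly by a
  Dijkstra-style label-setting search with the max-along-path cost. This
  is the standard reading of Dijkstra-based disconnectivity construction
  in the energy-landscape literature; no basin-saddle interpolation is
  applied.
* **The disconnectivity tree** (`build_disconnectivity_tree()`) merges
  minima by ascending pairwise barrier (single linkage). Because the
  minimax barrier is an ultrametric, merge heights are non-decreasing
  toward the root, so the tree draws as the familiar disconnectivity
  graph: leaves at their minima energies, joins at their barrier heights.
  Trees serialise to nested JSON and to Newick (branch length = parent
  height minus child height), so standard phylogenetics tooling can render
  them.

Minima, basins and barriers are all validated against independent
brute-force oracles (exhaustive neighbour checks, recursive descent,
exhaustive simple-path search) on random 4-region landscapes.

## Temporal dynamics

`summarize_dynamics()` reduces a state sequence to occupancy (time points
per state), dwell episodes (maximal runs; their lengths are dwell times,
measured in time points — no TR conversion is attempted), per-state maximum
dwell, and non-self transition counts (entries and exits; consecutive
repeats are dwelling, not transitions). Sequence boundaries count toward
occupancy and dwell but need no entry/exit. Conservation identities
(occupancy sums to $t_{max}$, episode lengths sum to occupancy,
$|$entries$-$exits$| \le 1$ per state) are property-tested on random
sequences.

`aggregate_group_dynamics()` reports, per state and group: the maximum of
per-subject maximum dwells, the *total visit count as occupancy* (time
points in state summed over subjects — the reading under which the
transition and visit tables of a cohort are mutually consistent), an
episode-count variant (`total_episode_count`) for the alternative reading,
and summed non-self transitions from/to each state.

## Two-group comparison and signature states

Each subject's fitted model is evaluated on all $2^N$ states
(`per_subject_energy_matrix()`); per state, the two groups' energies are
compared with a two-sided two-sample $t$-test — pooled variance by default,
Welch by flag (`state_ttests()`). Bonferroni correction is per-state and
strict: significant means $p < \alpha / 2^N$ (for 7 ROIs,
$0.05/128 = 3.90625\times10^{-4}$); a $p$-value exactly at the threshold is
excluded.

A significant state only becomes a *signature state* if it is also a local
minimum of a group landscape — otherwise it may merely be a neighbour
visited while descending into an attractor. Group landscapes are fitted on
each group's concatenated binarized data; the filter uses the **union** of
the two groups' minima, the most inclusive reading, and records per state
which group's landscape contributed (`in_minima_a` / `in_minima_b`).
Per-subject landscapes would be too noisy at typical scan lengths, and a
pooled two-group landscape would blur exactly the difference under test.
Subjects with unconverged fits are excluded (with a warning) unless
explicitly overridden.

## The synthetic cohort generator

Restricted clinical data cannot ship with a package, so every stage is
exercised by `generate_cohort()`, which draws per-subject state sequences
from known ground-truth models and wraps them in a continuous signal. What
it emulates, and the defaults chosen once as the package's study
conditions:

* **Two groups over 7 named ROIs.** Baseline truth: $h = 0$; couplings
  AUD–STG $+0.5$, Cerebellum–Vis.Primary $+0.5$, Cerebellum–toITG $+0.8$.
  The default contrast sign-flips Cerebellum–toITG to $-0.8$
  (`delta = -1.6` via `perturb_couplings()`), so one group's attractors
  anti-align that pair — a localised, interpretable group difference.
* **Temporal persistence.** The default sampler is a single-spin-flip
  Metropolis chain (uniform proposal over the $N$ flips, rejection =
  self-transition, burn-in 1000 steps, discarded). Its stationary law is
  exactly the Boltzmann distribution (verified analytically for small
  $N$), and rejections create dwell episodes longer than one time point,
  which iid sampling cannot produce. An exact iid sampler is available
  when independence is wanted.
* **Scan length** `t_max = 300` time points, a typical resting-state run;
  configurable.
* **BOLD-like emission:** signal $= a\,\sigma_i(t) + \varepsilon$,
  $\varepsilon \sim N(0, s^2)$, per-region baseline 0 so the time-average
  threshold is unbiased. Defaults $a = 1$, $s = 0.5$ give a per-entry
  sign-flip rate of $\Phi(-2) \approx 2.3\%$ — enough to exercise the
  binarizer without swamping the structure.
* **Reproducibility.** Subject $k$ of group $g$ uses the seed
  $(\text{seed}\cdot 1000003 + g\cdot 10007 + k\cdot 101) \bmod
  2147483629$; equal specs give bit-identical cohorts.

What it does **not** emulate: hemodynamic-response convolution,
autocorrelated scanner noise, motion artifacts, physiological confounds, or
inter-subject parameter variability beyond sampling noise. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* is correct and
adequately powered under clean conditions — not that any particular real
dataset satisfies the model's assumptions.

## Validation scale and runtime choices

The shipped studies use sizes chosen to make the statistical behaviour
visible while keeping a full run fast on one core: 50 synthetic subjects
for the moment-matching sweep ($N = 3..7$, 400 time points), $10^4$ iid
samples for 5-region parameter recovery (coupling and bias correlations
with truth $\ge 0.99$ in practice), 100 random 4-region landscapes against
brute-force oracles, 20 null cohorts (20 subjects/group, 300 time points)
for specificity — at family-wise $\alpha = 0.05$ the expected number of
false signature states per cohort is well below 1, and at least 19 of 20
null cohorts come out empty — and one injected-effect cohort (40
subjects/group, 500 time points, `delta = -1.6`) for sensitivity, which
reliably yields several signature states anti-aligning the perturbed pair.

## Known limitations

* Exact enumeration caps $N$ at 15; no pseudo-likelihood or mean-field
  approximations are provided for larger sets.
* The model is stationary and second-order: no third-order interactions,
  no time-varying parameters.
* Dwell times are in sampling units; interpreting them in seconds requires
  the acquisition TR, which the package does not model.
* Published state labels depend on the ROI-to-bit order; compare labels
  only under the documented convention.
* The two-group test assumes independent subjects and (by default) equal
  variances; covariate adjustment is out of scope.
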