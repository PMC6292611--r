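---
title: "Designing binary composite endpoints with cesize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing binary composite endpoints with cesize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesize)
```

## The design problem

A binary composite endpoint (CE) fires when any of its component outcomes
occurs in a patient. Combining outcomes raises the event rate, which usually
lowers the per-group sample size requirement (SSR) of a two-arm trial — but
the gain is governed by how strongly the components are associated. If two
outcomes almost always co-occur, their union adds hardly any events; if they
are mutually exclusive, the union rate is the sum of the rates. `cesize`
formalises this trade-off: given up to ten candidate outcomes with assumed
control-arm rates, treatment effects, and pairwise association assumptions,
it finds the combination minimising the SSR and quantifies how sensitive
that choice is to the association assumptions.

## Model and assumptions

Let $\pi_{ik}$ be the event probability of outcome $k$ in arm $i$
($i = 1$ control, $i = 2$ treatment), with effects given as risk ratios
$RR_k = \pi_{2k}/\pi_{1k}$. The model assumes:

* two arms with equal allocation ($n_1 = n_2$);
* outcomes observed over a common fixed follow-up window (binary, not
  time-to-event);
* effects and rates known (assumed) constants, not estimates with sampling
  error — robustness to either is explored by sensitivity analysis, not
  modelled.

The union of outcomes $A$ and $B$ has per-arm rate
$\pi_{CE} = \pi_A + \pi_B - \pi_{AB}$. The joint probability $\pi_{AB}$ is
the package's measure of association; for fixed marginals it can only lie
within the Fréchet bounds
$$\max(0, \pi_A + \pi_B - 1) \le \pi_{AB} \le \min(\pi_A, \pi_B).$$

### The nine association scenarios

Exact joint probabilities are rarely known, so `impute_joint()` supports
nine qualitative scenarios. Writing $I = \pi_A \pi_B$ for the independence
product and $L, U$ for the bounds, the imputed joint is

$$\pi_{AB} = I + \tfrac{\theta}{4}(U - I) \quad (\theta = 1, 2, 3, 4
\text{ for low/moderate/strong/highest positive}),$$
$$\pi_{AB} = I - \tfrac{\theta}{4}(I - L) \quad (\theta = 1, 2, 3, 4
\text{ for low/moderate/strong/lowest negative}),$$

and $I$ itself for `none`. The quarter-step interpolation was chosen
because it is the unique linear scheme under which the package's
nine-scenario sensitivity sweep reproduces, exactly, a published sensitivity
table for the ischemic worked example used throughout the test suite (all
nine SSRs, composite rates and risk ratios); a thirds-based scheme does not.
The imputed joint always lies within the bounds, is exactly $I$ at
$\theta = 0$, and is monotone in $\theta$ — all property-tested.

Scenarios are applied *per arm*: each arm's joint is imputed from that arm's
own marginals. Copying the control-arm joint value into the treatment arm
can violate the treatment arm's Fréchet bounds outright, and per-arm
application is again the convention that reproduces the published treatment
rates. Exact user-supplied joints, by contrast, are interpreted on the
control scale and applied to both arms, with the automatic correction
(below) enforcing each arm's bounds.

### Input correction

A user-supplied joint outside the bounds is replaced by the independence
product, with a warning naming the pair (`correct_joint()`). Replacement —
rather than clamping to the nearest bound — deliberately falls back to the
neutral "no information" value instead of silently asserting an extreme
association the user did not state. The correction is idempotent.

### Growing beyond two components

When a composite $\{A, B\}$ considers absorbing $C$, the joint between
composite and candidate is
$\pi_{(A\cup B)C} = \pi_{AC} + \pi_{BC} - \pi_{ABC}$, with the unobservable
third-order term imputed as the product $\pi_{AC}\pi_{BC}$
(`composite_candidate_joint()`). This is an approximation: it can drift
slightly outside the Fréchet bounds of (composite rate, candidate rate) in
extreme corners. The engine clamps it back into bounds and counts the events
(`clamp_events` on every result; a single summary warning per run) rather
than failing, since the drift is a property of the approximation, not a user
error. A consequence worth knowing: the composite rate depends mildly on
the *order* in which members are absorbed. The greedy path defines the order
for `greedy_select()`; `build_composite()` exposes the order explicitly.

## Sample-size kernels

`ssr_two_proportions()` implements five conventions; all square a sum of
normal quantiles over the squared rate difference and round up. The default,
`normal_mixed`, uses the pooled variance under the null for the $\alpha$
term and unpooled variance under the alternative for the $\beta$ term:

$$n = \frac{\left(z_{\alpha/2}\sqrt{2\bar p(1-\bar p)} +
z_\beta\sqrt{p_1(1-p_1) + p_2(1-p_2)}\right)^2}{(p_1-p_2)^2},
\qquad \bar p = \frac{p_1 + p_2}{2}.$$

This is the standard textbook formula for the pooled two-proportion z-test
and the convention under which the package reproduces every published SSR in
its acceptance tests. `normal_pooled` and `normal_unpooled` use a single
variance throughout; the arcsine variants work on the variance-stabilised
scale $2\arcsin\sqrt p$, with the corrected form
$2\arcsin\sqrt{(np + 3/8)/(n + 3/4)}$ solved to a fixed point in $n$
(tolerance $10^{-9}$, 100-iteration cap, error on non-convergence — in
practice it converges in a handful of iterations). Defaults are
$\alpha = 0.05$ two-sided and power $0.80$, the conventional pair for
superiority trials. Monte-Carlo validation (`empirical_power()`) confirms
the mixed-variant sizes deliver power within $\pm 0.02$ of target for the
worked-example composites at $10^5$ replicates.

Zero-effect inputs ($p_1 = p_2$) are an error in the kernels; inside the
selection engine a degenerate provisional composite is treated as infinitely
expensive (never selected), and in `pair_range_table()` it yields an `NA`
entry rather than aborting the table.

## The greedy selection and its oracle

`greedy_select()` starts from the relevant endpoint (RE): the user-flagged
outcome, else the one with the smallest single-outcome SSR (ties to the
lowest index; `which.min` semantics, applied consistently everywhere). At
each step every remaining candidate is evaluated — including
harm-increasing ones with $RR \ge 1$, which are legitimate panel members
and simply never win — and the best is absorbed only if its SSR is
*strictly* below the incumbent's. A tie does not grow the composite:
smaller endpoints are easier to interpret, so parsimony wins. The trace
records rates, risk ratio, SSR and percent-of-reference per step.

`exhaustive_search()` is the package's own optimality oracle. It enumerates
every subset containing the RE *and every insertion order of each subset*.
Order enumeration matters: because the third-order recursion is
order-dependent, an oracle that builds each subset in one fixed order is not
a valid lower bound — in roughly 1% of random panels the greedy path lands
one subject *below* such an oracle after ceiling rounding. With all orders
enumerated, the greedy result is by construction one of the evaluated
candidates, so `greedy ≥ exhaustive` is a theorem; the suite verifies it on
200 random panels and verifies equality on both worked-example panels. The
cost is factorial in panel size — fine for the $K \le 7$ panels where an
exhaustive check is interesting.

## Sensitivity analyses

`sweep_associations()` overwrites *every* pairwise association with each of
the nine scenarios in turn and reruns the selection, reporting the final
composite per scenario (component sets may differ across rows). A global
overwrite, rather than per-pair grids, matches how the question is asked in
practice — "what if everything is more associated than we hope?" — and
keeps the output to nine interpretable rows. For panels where every outcome
is protective, the SSR column is non-decreasing from `lowest` to `highest`,
and the `highest` row collapses to the RE alone whenever the RE has the
largest rate. `effect_sensitivity()` varies one outcome's risk ratio over a
grid, continuing past inadmissible grid points with per-point error records,
for the common case where a component's effect estimate rests on a handful
of events.

`pair_range_table()` answers the prior question — is an association
assumption even worth arguing about? — by computing each pair's SSR at both
Fréchet extremes before any scenario is chosen.

## Monte-Carlo validation and the panel generator

`sample_pair()` draws subject-level outcome pairs from the exact four-cell
multinomial implied by (marginals, joint); at $n = 10^6$ the empirical union
rate matches the inclusion-exclusion formula within three standard errors in
the suite. Simulation is deliberately pairwise-only: the model specifies
only pairwise associations, so a K-variate generator would require exactly
the higher-order assumptions the engine approximates away; three-plus
component rates are validated against published values instead.

`generate_panel()` produces reproducible random panels for property tests:
control rates uniform on 0.005–0.15 and risk ratios on 0.1–1.4 (the
rare-event, mostly-protective regime typical of cardiovascular endpoint
panels, spanning both arms of the worked examples), with independently
random scenarios per pair. What passing property tests on such panels shows
is internal consistency of the engine under realistic rare-event inputs —
not that any real trial's outcomes follow the quarter-step scenarios, nor
that the third-order product imputation holds in a given dataset.

## Problem sizes used in the test suite

The suite exercises the full published worked example (two panels of 4 and
5 outcomes, all nine scenarios), 200 random panels of 2–6 outcomes for the
greedy-versus-exhaustive bound, $10^5$ replicates for the power check and
$10^6$ subjects for the union-rate check — sizes at which Monte-Carlo error
is well below the asserted tolerances while the whole suite stays fast.

## Known limitations

* Results for composites of three or more components inherit the
  third-order product approximation; published multi-component values are
  matched to within a few subjects, not exactly (the residual is consistent
  with rounding conventions inside the original analyses, which are not
  recoverable).
* The greedy stopping rule is strict improvement, so it may stop one step
  short of an equally sized larger composite.
* No multiplicity adjustment, unequal allocation, more than two arms, or
  time-to-event structure; clinical relevance of a composite is the
  researcher's judgement, not the optimiser's.
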