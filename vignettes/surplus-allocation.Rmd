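---
title: "Modelling the Italian continuous-strip allocation of surplus lungs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Italian continuous-strip allocation of surplus lungs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripalloc)
```

## The protocol

When a donor lung in Italy is not claimed through the national urgency
programme and is not used in the donor's own region, it becomes a *surplus*
organ and enters a national redistribution protocol. The country is split
into two macroareas (Center-North and Center-South). Within each macroarea
the regional transplant centres (CRTs) are arranged in an ordered list — the
*continuous strip*. A surplus organ is offered to the centres of the donor's
macroarea in strip order, skipping the centre of the region that produced
the organ (a producer cannot also be required to use it). If every centre of
the donor's macroarea refuses, the cascade continues down the other
macroarea's strip; if every eligible centre refuses, the organ is lost.

After an acceptance, the strip of the macroarea in which the acceptance
occurred rotates: the acceptor and every centre that refused before it move
to the end of the strip, in their original relative order. If nobody
accepts, no strip changes. The rotation is the protocol's equity mechanism:
centres that have recently obtained (or passed on) an organ yield priority.

`stripalloc` turns this mechanism into an executable probability engine. The
whole topology — macroareas, strips, regions with and without centres,
per-centre acceptance rates, per-region surplus production counts — lives in
a declarative configuration (`nation_config()`, YAML/JSON via
`load_config()`/`write_config()`). The Italian lung setting ships as
`italy_fixture()`; the engine itself is organ-agnostic.

Two readings of the protocol text conflict: the general rule offers a
refused organ to the whole strip of the other macroarea, while a worked
example stops after that strip's head. We follow the general rule (it also
matches the protocol flowchart); the literal head-only behaviour is
available as the `head_only_fallback` configuration flag, off by default.
A second open point is whether a cross-macroarea acceptance should also
rotate the donor macroarea's strip. We rotate only the accepting strip: the
rotation rule is stated per strip, and the "no acceptance, no change" rule
then applies to the donor strip, which accepted nothing.

"Simultaneous" offers with an indicated strip position are modelled as
sequential queries in strip order, since acceptance priority follows the
position. A centre occupying several strip slots is queried once, at its
earliest slot, and only that triggering slot moves on rotation; the default
Italian configuration has multiplicity one everywhere, so results there are
unaffected.

## First model: who obtains the t-th organ

Donor regions are modelled as i.i.d. draws from the production-weighted
donor distribution \(P^x = S_x / \sum_y S_y\), and each queried centre
accepts independently with its acceptance rate \(P_c\). Conditional on the
current strip arrangement and the donor, the probability that centre \(c\)
obtains the organ is the cascade product

\[
P_{c}\;[\,\text{donor} \notin c\,]\; \prod_{c' \prec c} (1 - P_{c'}),
\]

the product running over centres queried before \(c\) in the full offer
order (`position_conditional_probability()`). One published form of this
quantity multiplies instead by the *marginal* probability that the organ is
not produced in the centre's own regions; that variant is exposed as
`variant = "marginal"`, but the engine conditions on the donor exactly,
because only exact conditioning makes the per-organ probabilities and the
loss probability sum to one.

Because the strip evolves with every allocation, the arrangement at organ
\(t\) is random. The engine therefore evolves a Markov chain over *joint
strip states* (one arrangement per macroarea): `evolve()` marginalises each
state over donors and cascade outcomes. The state space is finite (at most
the product of the two strips' multiset permutations — 48 states for the
Italian fixture), so `nth_probability()` computes, exactly,

* \(P_c^t\): the probability that centre \(c\) obtains organ \(t\),
* the loss probability (constant in \(t\): for a fixed donor, loss happens
  exactly when every eligible centre refuses, regardless of order),
* the strip-position distribution \(T_c^{t,j}\) and position-conditional
  probabilities \(P_{c,j}^t\), with
  \(P_c^t = \sum_j T_c^{t,j} P_{c,j}^t\) holding by construction.

The chain converges geometrically to its stationary distribution, which is
why the per-organ curves plateau after a handful of organs:

```{r plateau}
fit <- strip_model(italy_fixture(), n_organs = 12)
fit
```

`overall_use_probability()` returns \(1 - P_\text{lost}\);
`use_probability_decomposition()` recomputes it from an independent
macroarea-level closed form (summing over donor types the probability that
at least one eligible centre accepts) and the two agree to machine
precision — a standing cross-check in the test suite, which also contains a
brute-force oracle that enumerates every (donor, decision) path at small
sizes and matches the chain to 1e-12.

## Second model: at least k of M organs

Let \(X_t\) indicate that the target centre obtains organ \(t\). The
cumulative model asks for \(\Pr(\sum_t X_t \ge k)\). Three engines are
provided:

* **exact** (default): a dynamic programme over (joint strip state, organs
  obtained so far), evolved \(M\) steps. This is exact because the joint
  state is a sufficient statistic for the future of the process.
* **independent**: treats the \(X_t\) as independent with marginals
  \(p_t = P_c^t\) and returns the Poisson-binomial tail (convolution, not
  \(2^M\) enumeration). This evaluates the literal product-sum form in
  which the cumulative model is usually printed.
* **bahadur**: the second-order Bahadur expansion. The rotation induces
  dependence between organs (obtaining organ \(t\) pushes the centre to the
  back of the strip), so the joint law is written as the independence
  product times \(1 + \sum_{s<t} r_{st} z_s z_t\), with \(z_t\) the
  standardised indicators and \(r_{st}\) the pairwise correlations derived
  from the chain (`law_from_chain()` computes marginals and pairwise joints
  by a conditioned forward pass). Truncation at pairwise terms is the
  standard second-order choice; higher-order correlations are set to zero.

A truncated Bahadur density can go negative. We clip negative count masses
to zero, renormalise, and report the clipped mass (`clipped_mass` in the
result); silent negativity would break the guarantee that the at-least
curve is non-increasing. With all correlations zero the Bahadur engine is
bit-for-bit the independence engine (no clipping, same convolution).
Degenerate indicators (\(p_t \in \{0, 1\}\)) get correlation 0 by
convention. In a single-centre nation the exact engine reduces to the
binomial tail, which the tests verify at rates 26%, 90% and 100%.

```{r atleast}
at_least(italy_fixture(), "NITp", M = 10)
```

## Monte Carlo engine and validation

`simulate_season()` replays the mechanics stochastically: donors i.i.d.
from the donor distribution, independent acceptance draws, strip state
carried across the season and reset between seasons. `estimate()`
aggregates many seasons; it is vectorised across replicates (the joint
state space and every cascade are precomputed into lookup tables, so
200,000 seasons of 10 organs take about a second) and is deterministic
given `(config, M, n_reps, seed)`. We deliberately use one vectorised
stream keyed on the global seed rather than per-replicate substreams:
single traces remain individually reproducible through
`simulate_season(config, M, seed)`, while the estimator's contract is
reproducibility of the aggregate, and the vectorised form keeps the
validation loop fast in pure R.

`cross_validate()` compares every analytic per-organ and at-least-k
probability with the empirical frequency in units of the binomial standard
error \(\sqrt{f(1-f)/n}\) (evaluated at the analytic probability when the
empirical frequency is exactly 0 or 1, so the degenerate cases never divide
by zero), passing at 4 standard errors. The acceptance suite runs this at
200,000 seasons on the Italian fixture, and smaller versions on random
configurations drawn by `random_config()`.

## Study conditions and defaults

* **Acceptance rate 26%** for every centre: the historical mean acceptance
  rate of the period the protocol was evaluated on; `italy_fixture()`
  applies it uniformly. Exploratory settings of 90% and 100% are a
  parameter away. At 100% the at-least curve of a centre drops to zero
  beyond the number of organs the rotation can route to it — with two
  certain centres and six organs, each can obtain exactly three.
* **Production weights**: per-region national donor counts (121 Piemonte,
  142 Emilia Romagna, 167 Toscana, 130 Veneto, 226 Lombardia, 50 Sicilia,
  117 Lazio) are the shipped default. They are a documented proxy for
  period-specific surplus counts, which are not publicly available at
  per-region resolution; analyses of a specific season should supply their
  own counts (`production` argument, or the config file). With the proxy
  weights the southern centres' per-organ probabilities stay near 10% while
  the northern strip shares the rest — the north-south asymmetry is driven
  almost entirely by where organs are produced.
* **Problem sizes**: the shipped validation uses 40 organs for plateau
  curves, M = 10 with 200,000 seasons for Monte Carlo cross-validation, and
  M ≤ 4 with ≤ 3 strip slots for the brute-force enumeration oracle; these
  sizes make every exact-vs-oracle comparison feasible at machine precision
  while keeping the whole suite quick on a laptop.

## What the synthetic settings do and do not show

The generator emulates the structural mechanics: topology, rotation,
production-weighted donors, Bernoulli acceptance. It does not model
donor-recipient clinical matching, the 45-minute evaluation window,
cold-ischemia geography, urgency or restitution protocols, or acceptance
rates that differ across centres or over time (all centres share one rate
by default, as the evaluated scenario did). Passing tests therefore
establish that the engine computes the stated model exactly — not that the
model captures every force acting on the real allocation system.

## Numerical notes

* Chain states are stored sparsely (reachable arrangements only) with a cap
  of \(10^5\) states; beyond it the engines error and point to Monte Carlo.
* Exact tail probabilities can round to tiny negatives (order \(10^{-18}\));
  consumers clamp to \([0,1]\) before square roots.
* `at_least_value()` fixes the boundary conventions: \(k \le 0 \mapsto 1\),
  \(k > M \mapsto 0\).
* Ties never arise in the cascade: the strip order is a strict order by
  construction, and multi-slot centres are resolved to their earliest slot.
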