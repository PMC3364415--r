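---
title: "The hierarchical ephemeral speciation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hierarchical ephemeral speciation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Speciation rates measured over short time scales (young radiations,
population-genetic models of speciation) come out orders of magnitude higher
than rates measured over long time scales (time-calibrated phylogenies, the
fossil record). A hierarchical model of *ephemeral speciation* reconciles
the two: incipient species form constantly and quickly, but almost never
persist, and a "full" species is a bundle of incipient lineages rather than
an atom.

`ephemsim` simulates that model exactly. The state is a set of living
incipient lineages, each belonging to one full species. Three rates, all
per incipient lineage per million years (Myr), drive the process:

* `lambda_i` — **incipient speciation**: the lineage buds off a new
  incipient lineage inside the same species;
* `mu_i` — **incipient loss**: the lineage dies, either by extinction or by
  reabsorption (e.g. hybridizing back) into its parental species;
* `lambda_f` — **full-species formation**: the lineage is promoted to a new
  full species.

The simulation is an exact Gillespie algorithm: with $n$ lineages alive,
the waiting time to the next event is exponential with rate
$n(\lambda_i + \mu_i + \lambda_f)$, the affected lineage is chosen
uniformly, and the event kind with probabilities proportional to
$(\lambda_i, \mu_i, \lambda_f)$. Time is continuous; there is no
discretization, and ties cannot occur (events carry a sequence number for
deterministic ordering of the log). Rates are homogeneous across lineages
and time — there is no diversity dependence, trait dependence or geography —
because the model has exactly three parameters by construction.

Everything starts from a single incipient lineage in a single species at
$t = 0$; the root species needs no formation event. The run stops at the
horizon `t_max` (Myr), when the last lineage dies, or when the lineage
count exceeds `max_lineages` (default 50,000) — the last case stops the
simulation with a classed warning (`ephemsim_capped_growth`) and a
`capped = TRUE` flag in the result, never by silent truncation.

### Consequences the package operationalizes

Because a species persists as long as *any* of its incipient lineages
does, whole-species extinction is an emergent event, not a parameter:
a species disappears exactly when a loss event removes its last member
(labelled `species_extinction` in the event log; every other loss is a
`reabsorption`). Membership across species becomes strongly uneven — most
species hold one incipient form, a few hold many — which in turn makes
effective speciation and extinction rates uneven across species:
`effective_rates()` reports conversions per lineage-Myr of exposure, and an
extinction exposure $\mu_i / H_k$ (the reciprocal of the expected time for
all $k$ members to be lost under the loss rate alone), a decreasing
function of membership. Finally, whole clades usually die; the survivors
over-represent clades that diversified early, which the summaries quantify
with lineage-through-time curves and the $\gamma$ statistic.

## Semantics the model statement leaves open

Three points are not determined by the verbal model, so the package fixes
them explicitly:

**What a conversion carries.** A converting lineage founds a new species
containing only itself; incipient lineages it spawned *earlier* stay in the
old species. This is the simplest per-lineage reading of a "rate of
formation of full species" and matches the convention of protracted
speciation models, where completion of speciation applies to a lineage, not
to a subtree. The alternative (the lineage takes its descendants along) is
defensible but makes the promotion event a subtree operation with no extra
parameter to justify it.

**A species never goes extinct by promotion.** Under the chosen semantics
a conversion drawn for a lineage that is its species' *only* member would
leave the old species empty — an "extinction" caused by a speciation event.
We treat such draws as recorded no-ops (the event appears in the log with
`new_species_id == species_id`): promoting the only representative of a
species changes nothing observable about the species-level system. This
keeps two invariants exact: a living species always has at least one
member, and species disappear only at `species_extinction` loss events.
The no-op draws are excluded from effective speciation rates.

**Node times of the species tree.** When species $S$ splits from its
parent, the split can be dated at the *conversion time* (when the founder
lineage was promoted — the default) or at the *incipient origin time* (when
the founder lineage was born, i.e. when divergence actually began).
`collapse_to_species_tree()` implements both; they coincide when promotion
is instantaneous. The choice matters scientifically, see *The early-burst
prediction* below.

A useful reduction follows from the conversion semantics: promotions never
change the lineage count, so the incipient-lineage process is exactly a
constant-rate birth–death process in $(\lambda_i, \mu_i)$, whatever
$\lambda_f$ is. With $\mu_i = \lambda_f = 0$ it is a Yule process with
$E[N(t)] = e^{\lambda_i t}$. The test suite checks both limits against
`simulate_bd()`, the flat "high-turnover" baseline that shares the same
result container (every lineage its own species, no conversions).

## Parameters and defaults

| parameter | default | unit | why |
|---|---|---|---|
| `lambda_i` | 1.0 | /lineage/Myr | incipient (subspecies-level) turnover on the order of one event per lineage-Myr |
| `mu_i` | 0.5 | /lineage/Myr | moderate incipient loss; net incipient growth 0.5/Myr |
| `lambda_f` | 0.03 | /lineage/Myr | keeps `lambda_i/lambda_f` ≈ 33, inside the 30–40× ratio reported for avian subspeciation relative to speciation |
| `t_max` | 10 | Myr | a typical crown age for a young genus-level clade |
| `max_lineages` | 50,000 | — | memory guard, flagged when hit |

The shipped configuration (`inst/extdata/default_config.yaml`) uses these
values with `condition_on_survival: true`, since any empirical clade is by
definition a survivor. `condition_on_survival()` rejection-samples whole
replicates; when a seed is set it is consumed once so the result is
reproducible. In batches, replicate $r$ is seeded with `seed + r` and
depends only on $(\mathrm{seed}, r)$, never on execution order.

## The early-burst prediction

Survivorship is the model's explanation for apparent early bursts of
speciation. How it shows up in $\gamma$ depends on how species-tree nodes
are dated:

* Under **conversion-time** dating, reconstructed extant species trees at
  high incipient turnover ($\lambda_i = 1$, $\mu_i = 0.9$,
  $\lambda_f = 0.1$, `t_max` 15 Myr) have *positive* mean $\gamma$: young
  species are mostly single-lineage and short-lived, so the recent part of
  the tree is crowded with nodes — the pull of the present dominates.
* Under **incipient-origin** dating, the same simulations give a
  significantly *negative* mean $\gamma$: a species observed today usually
  began diverging long before it was promoted, and recently initiated
  lineages have not yet completed speciation, so apparent branching
  concentrates early. This is the same mechanism by which protracted
  speciation models explain observed diversification slowdowns.

The package therefore tests the early-burst prediction on origin-dated
trees (the acceptance suite uses 400 survival-conditioned replicates with
at least three extant species each, one-sided $t$-test at $\alpha = 0.05$),
while keeping conversion-time dating as the default convention for the
species tree itself. Note also that the $E[\gamma] = 0$ pure-birth null
holds for trees of fixed tip count; selecting fixed-duration replicates by
a minimum tip count biases $\gamma$ negative, so the null check in the test
suite uses fixed-$n$ Yule trees.

## Estimators

Four speciation-rate estimators cover the cross-time-scale comparison:

* `richness_age_rate(n, t)` $= \ln(n)/t$, the pure-birth expectation from
  one ancestor. Extinct and reabsorbed lineages are invisible to it, so it
  behaves as a minimum bound (the suite verifies it sits below the
  birth–death MLE on simulations with extinction). Applied to ~450 species
  in ~0.015 Myr it gives 407.3, i.e. 400 to one significant figure — the
  headline short-time-scale number, reported to one significant figure
  because the inputs have one.
* `waiting_time_to_rate(g, y)` $= 10^6/(g\,y)$ converts a speciation
  waiting time in generations to events per lineage per Myr: 5,000
  generations at 1 yr/generation gives 200. The conversion is exact; note
  that an often-quoted lower figure of 2 corresponds to a waiting time
  above 200,000 generations (200,000 generations give exactly 5).
* `fit_yule(bt)` is the closed-form crown MLE $(n-2)/E$, with $E$ the
  lineage-time exposure from the crown to the present. Its log-likelihood
  is evaluated as the birth–death likelihood at $\mu = 0$ so the two fits
  are nested and directly comparable.
* `fit_birth_death(bt)` maximizes the reconstructed-process birth–death
  likelihood conditioned on survival of both crown lineages (the
  supercritical regime $0 \le \mu < \lambda$; published variants of the
  conditioning differ, so this one is stated). Optimization is bounded
  L-BFGS-B in $(r, a) = (\lambda - \mu, \mu/\lambda)$ from two starts (the
  Yule MLE with $a \approx 0$, and $a = 0.5$), with tolerance $10^{-8}$ on
  the log-likelihood; ages are rescaled to unit crown age internally so
  estimates are exactly equivariant under changes of time unit.
  Non-convergence of every start is raised, not swallowed. On
  extinction-free data the maximum-likelihood $\hat\mu$ sits on the
  boundary about half the time and is upward-biased in small trees; the
  consistency check with the Yule MLE is run at $n = 120$ where the
  medians are stable.

All estimators sort branching times internally, so input order is
irrelevant.

## Numerical choices

* The Gillespie state lives in preallocated vectors grown geometrically;
  the alive-set uses swap-removal so every event is $O(1)$.
* Ultrametricity for $\gamma$ is required to $10^{-9}$ × tree height;
  polytomies are accepted by the LTT (a step equal to out-degree minus
  one) and rejected by the Colless index rather than randomly resolved
  (the simulator itself cannot produce them, since simultaneous events
  have probability zero in continuous time).
* A basal trichotomy is how `ape` represents unrooted trees, so a
  binary-shaped tree with one is rejected as unrooted; a three-tip star is
  accepted as a rooted star.
* Branch lengths are written with 15 significant digits; Newick round
  trips preserve topology exactly and lengths to $10^{-12}$ relative
  tolerance, with per-node annotations carried in NHX-style comments.
* Sample skewness of the membership histogram is the adjusted
  Fisher–Pearson estimator $G_1$, reported as `NA` below three species.
* "Log-linear LTT" for the baseline is assessed per replicate (regression
  of $\log N(t)$ on $t$, mean $R^2$ across replicates): pooling raw points
  across replicates would mix the between-tree variance of $\log N$
  (≈ $\pi^2/6$ under Yule) into the residual and cap $R^2$ near 0.4 for
  any perfectly log-linear process.

## What the generator does and does not emulate

The simulator realizes the model's own study conditions: homogeneous
rates, complete observation of every incipient lineage, and exact event
times. Real data differ in ways the passing tests therefore say nothing
about: rates vary across lineages and time; incipient forms are sampled
incompletely and recognized inconsistently; empirical trees carry
estimation error in both topology and branch lengths; and reabsorption in
nature depends on geography and gene flow rather than acting as a constant
hazard. Inference of $(\lambda_i, \mu_i, \lambda_f)$ from real trees is
out of scope — the estimators fit the *baseline* birth–death and Yule
models precisely because that is how rates are obtained in the literature
the model addresses.

## Problem sizes

The test and acceptance workloads are sized to what the questions need:
1,000 replicates for Monte-Carlo means checked at ±3 SE; 500 surviving
replicates (≈ 6,500 species) for the membership histogram; 400 usable
survival-conditioned trees for the $\gamma$ test; 200 Yule trees of 100
tips and 100 birth–death trees of ≥ 50 tips for recovery checks. A full
suite run is a few minutes on one core.
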