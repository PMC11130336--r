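---
title: "Hidden rate-class models of trait gain and loss: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden rate-class models of trait gain and loss: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiddenrates)
```

## The problem

Root nodule symbiosis (RNS) — the housing of nitrogen-fixing bacteria in
plant root nodules — occurs patchily across one large clade of flowering
plants, the nitrogen-fixing clade (NFC: Fabales, Rosales, Fagales,
Cucurbitales).  Whether that pattern reflects a single ancient gain with
many losses or many independent gains is a model-selection and
ancestral-reconstruction problem on a time-calibrated phylogeny.  This
package implements the full inferential machinery for that question:
continuous-time Markov models of a binary (or three-state) character whose
gain and loss rates are modulated by unobserved *rate classes*, maximum
likelihood fitting, AIC comparison, ancestral reconstruction, transition
counting, constrained-ancestor tests, and gain/loss rate-grid scans —
together with a forward simulator that provides event-level ground truth, so
every stage can be validated without external data.

## The model

Let the observed character have states $O$ (binary: absent/present) and let
$R = \{R_1,\dots,R_k\}$ be hidden rate classes, $k \le 5$.  The chain runs
on the composite space $S = O \times R$ with generator $Q$; an entry
$q_{ij} \ge 0$ (events/Myr) is free wherever the transition changes *either*
the observed state within a class (gain or loss) *or* the class within an
observed state.  Simultaneous ("dual") changes of both axes are forbidden —
the standard hidden-rates convention — so $Q$ is structurally sparse.  All
allowed transitions carry their own parameter ("unequal rates"); with
$n_{obs}=2$ and $k$ classes that is $2k + 2k(k-1)$ free rates.  Naming a
*no-gain class* zeroes the gain entry in that class, encoding the prior
knowledge that the trait cannot arise in part of the state space; with
$k=3$ that gives the 17-parameter structure used throughout the examples.

Two special structures are first-class citizens:

* `build_precursor_model()` — the classical two-class precursor model:
  non-precursor absent $\leftrightarrow$ precursor absent $\to$ present,
  with loss back to the precursor class (4 rates).
* `build_three_state_pathway_model()` — absent / actinorhizal / rhizobial
  with stepwise gains (actinorhizal only from a precursor-absent class,
  rhizobial only from actinorhizal) and no direct absent $\to$ rhizobial
  transition (6 rates).

The best-supported three-class structure can be expressed two ways: as a
free $k=3$ fit whose third class converges to an absorbing absent state, or
as the a-priori no-gain-class variant.  Both are constructible here and
neither is hard-coded as "the" model; `label_rate_classes()` names the
fitted classes (*non-precursor*, *precursor*, *intermediary*) from their
rate signature with a configurable negligibility threshold (default
$10^{-6}$/Myr).

## Likelihood

`tree_loglik()` computes the exact likelihood by Felsenstein pruning.
Branch transition probabilities $P(t) = e^{Qt}$ come from an
eigendecomposition of $Q$ (one decomposition per likelihood evaluation,
two small matrix products per branch), falling back to scaling-and-squaring
when the eigenvector matrix is ill-conditioned; rows are clamped to
$[0,1]$ and renormalised, and $t=0$ short-circuits to the identity, so
zero-length branches in calibrated supertrees are transmitted exactly.
Underflow on large trees is controlled by per-node rescaling with
accumulated log factors rather than extended precision.  Unknown tips enter
as all-ones partials; a `node_constraint()` zeroes disallowed composite
states at any node before its partial is combined, which is how
fixed-ancestor analyses are expressed.  Impossible data return a $-\infty$
sentinel with a flag instead of an error inside optimisation loops.

The root is handled by a selectable prior — flat over composite states
(default), stationary, FitzJohn observed-conditional, or a user vector —
and every result records which was used.  The published analyses this
package follows do not state their root treatment; on our synthetic
fixtures the ingroup-ancestor call is insensitive to the choice, but the
option is surfaced rather than assumed, and reports carry it.

## Fitting and uncertainty

`fit_model()` optimises $\log_{10}$ rates with bounded derivative-free
search (Nelder–Mead; Brent when there is a single parameter) from random
log-uniform starts.  Restart seeds derive from the master seed by a
counter, so runs are exactly reproducible, restart trajectories are all
recorded, and adding restarts can only improve the reported optimum.  Hard
bounds default to $[10^{-9}, 100]$ events/Myr — wide enough to act as
infinity and zero on a $\sim$100-Myr-deep tree — while random starts are
drawn from the narrower window $[10^{-5}, 1]$, the biologically plausible
range for traits that change at all on such trees; starts far outside it
waste restarts in flat regions of the surface.  Convergence uses a relative
log-likelihood tolerance of $10^{-10}$ per restart with a final polish
from the best start.

The $\Delta 2$ confidence region (`sample_confidence_region()`) accepts
parameter vectors whose log-likelihood is within 2 units of the maximum.
The sampler first *profiles each parameter to the boundary* by doubling
and bisection (25 halvings, i.e. boundary location to machine-level
precision along each axis), then runs a random walk whose per-parameter
step is set from those half-widths to pick up likelihood ridges from
covarying parameters; the accepted-sample covariance is reported for that
purpose.  A plain fixed-step walk systematically underestimates the region
on large trees — the region is narrow, so ill-scaled proposals rarely reach
its boundary — which is why the profiling stage is part of the design.

Model comparison is by AIC ($2k - 2\ln L$), matching standard practice for
this model family; AICc is reported alongside.  Ties order by fewer
parameters.

## Reconstruction and transition counting

`marginal_reconstruct()` implements the up-down algorithm: node posteriors
are the normalised product of tipward (pruning) and rootward partials,
with sibling contributions combined by exclusion products rather than
division, so zero partials cannot poison the pass.
`joint_reconstruct()` is the max-product dynamic program with
back-pointers, generalised to polytomies, root prior included in the final
maximisation.  Ties are broken deterministically to the lowest composite
state index and logged per node.  Both collapse to observed states with
`collapse_to_observed()` (classes summed or mapped away).

`count_transitions()` compares parent and child observed states edge by
edge under the joint reconstruction: a differing pair is one event.  These
are deliberately *minimum-change* counts — a change and reversal inside one
edge is invisible — and the summary flags this.  Clade tallies assign each
event to the smallest named clade containing the edge's parent node, with
a catch-all row so totals are conserved.

`rate_grid_scan()` re-examines a focal ancestor across rate regimes: a
one-class model anchors the maximum-likelihood (gain, loss) pair, and a
grid of 100 pairs, even on the $\log_{10}$ scale across $\pm 2$ decades,
sweeps gain up as loss comes down so the loss/gain ratio spans eight
orders of magnitude; the exact MLE pair is forced into the grid.  "Even"
spacing is taken on the log scale because rates are scale parameters; a
linear/factorial lattice is available via `layout = "factorial"`.  Each
record carries the data log-likelihood and the focal node's marginal
observed-state probabilities, ready for `autoplot()`.

## The synthetic generator

`make_nfc_like_fixture()` emulates the statistical structure of the
empirical problem, not its taxonomy: an ultrametric birth–death tree
(default $\lambda = 0.1$, $\mu = 0.025$ per Myr, giving realistic
extinction and a crown age of order 10$^2$ Myr at 1000 tips), an ingroup
of roughly half the tips whose ancestor is seeded with the *precursor*
state while the rest of the tree starts in the absorbing *non-precursor*
state, and a two-step rate profile with the qualitative orderings of the
fitted empirical model: gain from the intermediary class 10× faster than
the precursor $\to$ intermediary shift, trait loss 150× slower than gain,
lability more easily lost than gained, and the intermediary equally likely
to fall back as to gain the trait (`nfc_rate_profile()`; the absolute
anchor, 0.02 gains/Myr from the intermediary, makes a handful to a dozen
independent gains typical on a 1000-tip tree — the regime the empirical
analyses report).  Trait histories are simulated exactly (exponential
waiting times, destinations by relative rates) with every event recorded,
so reconstruction and counting can be scored against the truth.  A
configurable fraction of tips (default 5%) is masked to unknown, emulating
unscorable genera.  Fixtures whose truth contains fewer than two observed
gains are regenerated with an incremented seed (count logged) so the
multiple-gain regime is always exercised.

What the generator does *not* emulate: genus-level collapsing of species
tips, phylogenetic error, non-random placement of unknowns (real unscored
genera cluster in hotspots of trait lability), and rate variation beyond
three classes.  Green tests therefore certify the inferential machinery on
clean histories of realistic size and shape, not robustness to
tree-estimation error.

## Numerical choices and test scales

Enumeration oracles (exhaustive sums/argmaxes over internal-node
assignments, with tips handled analytically) back the likelihood, marginal
and joint reconstructions on trees of up to 6 tips and 6 composite states;
agreement is required to $10^{-8}$ (likelihoods, posteriors) and
$10^{-10}$ (joint scores).  Calibration experiments use the sizes the
methods are meant for: $\Delta 2$ coverage of true rates on 2000-tip
trees (20 replicates, $\ge 80\%$ expected), and multiple-gain recovery on
1000-tip three-class fixtures (10 seeds, $\ge 90\%$ expected, two random
restarts per fit).  Those scales keep the full suite in the tens of
minutes on one CPU while leaving the statistical claims meaningful.

Other degenerate inputs with defined behaviour: polytomies everywhere
(including the root), zero-length branches (identity transition; joint
reconstruction then forces parent and child equal), monomorphic data
(change rates collapse to the lower bound), and constraints that
contradict the data (explicit error from `fit_with_fixed_node()`, $-\infty$
from `tree_loglik()`).

## Known limitations

* Transition counts are minima by construction; stochastic character
  mapping, which can detect within-edge reversals, is future work.
* AIC model selection over hidden-class counts is honest only up to the
  optimiser: with 17+ free rates and two restarts, fits on synthetic
  fixtures land close to — but not provably at — the global optimum.  The
  published empirical analyses used 100 restarts; `n_restarts` is the
  knob.
* The grid scan's upper loss/gain ratio is a design choice ($10^{4}$ by
  default); conclusions about "how much more likely loss must be" are
  relative to that span.
* No Bayesian machinery, no correlated characters, no branch-specific
  rates.
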