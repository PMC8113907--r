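---
title: "Models and methods for correlated binary-trait evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for correlated binary-trait evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagelion)
```

## The scientific problem

Male butterflies of the tribe Eumaeini carry a remarkable arsenal of
secondary sexual organs — abdominal brush organs, wing scent pads and scent
patches, and several positional androconia.  Maintaining several of these
signalling structures at once is presumably costly, which raises a
comparative question: do pairs of organs evolve independently across the
tribe, or does possessing one organ change the probability of gaining or
losing another?  `pagelion` implements the full inferential chain used to
answer this class of question on a time-calibrated phylogeny with binary
presence/absence codings: Mk model fitting, Pagel's correlated-evolution
test replicated over bootstrap tree sets, ancestral-state reconstruction by
stochastic character mapping, and Bayesian model comparison through
reversible-jump MCMC and stepping-stone marginal likelihoods.

## The models

A single binary character evolves by a continuous-time Markov chain with
generator

$$Q_\text{ARD} = \begin{pmatrix} -q_{01} & q_{01} \\ q_{10} & -q_{10} \end{pmatrix},$$

the equal-rates (ER) model being the one-parameter restriction
$q_{01} = q_{10}$.  For a pair of characters $(X, Y)$ the chain runs over
the four joint states, ordered **1 = (0,0), 2 = (0,1), 3 = (1,0),
4 = (1,1)**.  Simultaneous transitions in both characters
($1 \leftrightarrow 4$, $2 \leftrightarrow 3$) are structural zeros, which
leaves eight rates $q_{12}, q_{13}, q_{21}, q_{24}, q_{31}, q_{34}, q_{42},
q_{43}$ in the dependent model.  Under independent evolution they collapse
pairwise onto the four marginal rates ($q_{13} = q_{24}$, $q_{31} = q_{42}$,
$q_{12} = q_{34}$, $q_{21} = q_{43}$), so the test of correlated evolution
is a likelihood-ratio test with $8 - 4 = 4$ degrees of freedom; its 0.05
line is $\chi^2_{0.95}(4) \approx 9.49$.  With this state ordering $q_{24}$
is the gain of $X$ when $Y$ is present and $q_{34}$ the gain of $Y$ when $X$
is present — the two rates that vanish under an evolutionary trade-off in
which a lineage already possessing one organ effectively never regains the
other.  The one-way conditional models (6 rates each) are also available,
since "independent vs fully dependent" is only one of the possible contrasts;
the default workflow, however, compares independent against fully dependent.

Likelihoods are computed by Felsenstein's pruning algorithm with per-node
rescaling, so they are exact log values even deep in the underflow regime.
Multifurcations are handled natively because collapsing weakly supported
nodes is routine for bootstrap backbones.  Missing codings enter as partial
likelihood 1 for every compatible state; a species scored for $X$ but not
$Y$ therefore still informs the pair model through its $X$ margin.
Transition matrices $e^{Qt}$ come from an eigendecomposition of $Q$, with a
scaling-and-squaring fallback whenever the eigenvector matrix is
ill-conditioned (the accuracy contract, checked in the tests, is $10^{-10}$
against a truncated-series oracle).  Zero-length branches yield identity
transitions; negative lengths are rejected.

### Root prior

The root state weighting is a genuinely open choice in this family of
methods, and published analyses frequently leave it unstated.  The package
defaults to **equal** weights — the common default of the tools this
workflow descends from, and the choice that keeps nested-model comparisons
internally consistent — and offers stationary, FitzJohn and fixed options.
Every fit, reconstruction and trace records the prior used, because
root-state probabilities (e.g. the probability that the tribe's common
ancestor carried brush organs) can depend on it.

## Maximum-likelihood fitting

Rates are optimised in log space within $[10^{-8}, 10^3]$ per rate, by
box-constrained quasi-Newton search from multiple starts: a data-informed
first start (changes per unit tree length), and log-uniform random restarts
with per-start sub-seeds, ties broken by the lowest start index.  The
independent pair model factorises exactly into its two margins, so it is
optimised trait-by-trait (two 2-parameter problems instead of one
4-parameter problem) and its joint log-likelihood is then recomputed through
the 4-state engine; the factorisation identity itself is a tested property,
not an assumption.  The dependent fit always includes a start mapped from
the independent estimate, which enforces the nesting inequality
$\log L_\text{dep} \ge \log L_\text{indep}$ up to optimiser tolerance.
Estimated rates of effectively forbidden transitions end up at the lower
bound ($10^{-8}$), which is how "rates close to zero" manifests in ML.

Phylogenetic uncertainty is propagated by refitting both models on every
tree of a bootstrap set (`fit_over_tree_set()`), reporting per-tree
statistics, the fraction of trees significant at $\alpha$, and the rate
distributions across trees.

## Stochastic character mapping

`ancestral_marginal()` gives exact marginal (re-rooting) probabilities by
the standard two-pass message algorithm.  `simmap_sample()` draws full
histories under the empirical-Q convention (rate matrix fixed at its ML
estimate, matching the default of the mapping tools in common use): node
states by backward filtering / forward sampling, then each branch bridged
conditional on its endpoints.  Branch bridges use rejection sampling — with
the first jump forced when the endpoints differ — and switch to exact
uniformization sampling after 1000 failed draws, so endpoint combinations
that rejection reaches too rarely are never silently biased.  Summaries
report per-node state frequencies, expected transition counts by type and
dwell-time fractions.  Tests confirm that map frequencies reproduce the
marginal probabilities within Monte-Carlo error and that expected transition
counts dominate the parsimony minimum.

## Bayesian machinery

`rjmcmc_run()` samples rate posteriors under an exponential prior whose
mean is itself uniform on $(0, 30)$ — the "exponential hyperprior"
convention of the reversible-jump discrete-trait literature, which we adopt
explicitly since the phrase "exponential (0–30)" is ambiguous.  The
reversible-jump state is a rate-class structure: rates may share a class
value or sit in a zero bin (pinned to 0), the mechanism by which
conditional gain rates can vanish with positive posterior probability.  One
move type reassigns a rate among existing classes, a fresh class, or the
zero bin; because fresh class values are proposed from their exponential
prior and the candidate-set size is symmetric, the acceptance probability
reduces to the likelihood ratio under a uniform prior over structures.
Proposal widths adapt during burn-in only, keeping the post-burn-in kernel
fixed.  Convergence is monitored by autocorrelation-based effective sample
size (Geyer initial-positive-sequence truncation; a constant trace has ESS
1 by convention).

`stepping_stone()` estimates log marginal likelihoods on a power ladder
$\beta_k = (k/K)^{1/0.3}$ (quantiles of Beta(0.3, 1), concentrating stones
near the prior), one warm-started Metropolis chain per stone and the usual
log-sum-exp estimator.  Bayes factors are reported on the $2\Delta\log$
scale, with 2 and 5 as the positive/strong evidence bands; a plain-ratio
scale is available by flag.  Desk defaults (30 stones × 1000 iterations,
$10^5$ generations) keep a full run in the minutes range; production-scale
settings ($2000 \times 50\,000$ stones, $10^8$ generations, burn-in $10^6$,
thinning 5000) are plain configuration values.

Correctness anchors, all in the test suite: a one-free-rate model's
stepping-stone estimate agrees with 1-D quadrature to 0.1 nats; a
prior-only run reproduces the hyperprior's marginal mean; the binned
posterior of a one-rate toy matches quadrature with total variation < 0.02;
a fully fixed model returns exactly its log-likelihood; and the Bayes factor
is antisymmetric with $\Delta\log ML = 4.2905$ mapping to 8.581.

## Synthetic data

The simulators exist so that every stage is testable without any external
data.  `simulate_bd_tree()` draws constant-rate birth-death trees
conditioned on the number of extant tips (defaults: birth 0.2, death 0.05)
and rescales them to root height 30 — the crown age, in Ma, of the clade
this workflow was built around — so simulated rates are interpretable
per-Ma.  `simulate_traits()` runs the forward CTMC down the tree;
`perturb_tree_set()` emulates a bootstrap cloud by lognormal branch-length
jitter (unit mean, chosen CV) plus optional NNI moves.  The default
trade-off regime sets $q_{24} = q_{34} = 0$ with the remaining rates in
0.05–0.2 per Ma.

What the generator does *not* emulate: non-ultrametric rate variation,
asymmetric taxon sampling, character-state misscoring, and the correlation
structure of real bootstrap replicates (which share one alignment).  Passing
calibration tests on these synthetics therefore demonstrates the
correctness of the machinery and its frequentist calibration under the
model, not robustness to the ways real data violate it.

## Survey tallies

`tally_organ_counts()` summarises a species × organ presence table into the
distribution of organ counts per species.  Percentages are rounded half
away from zero to two decimals.  Partially missing species are counted with
missing entries as absences by default (dropped only when every column is
missing); both alternatives (`"drop"`, `"zero"`) are recorded in the output,
since published totals rarely state this choice.  The packaged fixture
carries the published five-class distribution (75, 405, 232, 95, 11 over
818 species); note that its honestly recomputed percentages differ from
some of the published ones by up to 0.08 percentage points, an internal
inconsistency of the published table that the package reproduces rather
than masks.

## Numerical choices and limitations

* Rate bounds $[10^{-8}, 10^3]$; a rate at the lower bound reads "zero".
* Equal root prior by default everywhere; recorded in all outputs.
* Ultrametricity tolerance $10^{-6}$ relative depth spread.
* Likelihood-ratio statistics floored at 0; `-Inf` log-likelihoods are
  propagated, never floored.
* Desk problem sizes (used by the test suite and chosen to keep the full
  suite in the ~10-minute range): 200 null replicates on 100-tip trees for
  type-I calibration, 40 replicates on 200-tip trees for power, 10 000 maps
  for mapping consistency, 30 × 1500 stepping-stone iterations for the
  quadrature toy.
* Not implemented (out of scope): hidden-rate/covarion models, >2-state
  characters, threshold-model alternatives, joint (MAP) ancestral
  reconstruction, network phylogenies, and sequence-level inference.
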