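---
title: "Modelling household food security with discrete Bayesian belief networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling household food security with discrete Bayesian belief networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsbn)
```

## The model

`fsbn` models a household survey as a discrete Bayesian belief network: a
directed acyclic graph over ordinal variables with one conditional
probability table (CPT) per variable,

$$\theta_i^{jk} = \Pr(A_i = j \mid pa(A_i) = k),$$

so the joint distribution factorises as
$P(x_1,\dots,x_n)=\prod_i \theta_i^{jk}$. The intended application is
household food security: fourteen ordinal household characteristics plus a
binary outcome `FS`, with state 0 meaning *food secure* and state 1 *food
insecure*. Everything in the package — learning, validation, intervention —
operates on this representation.

Two structural assumptions run through the whole design:

* **Causal ordering.** Domain knowledge supplies a level-wise ordering of
  the variables: a variable can only cause variables in later levels, and
  the outcome sits alone in the last level (it causes nothing). The
  ordering is what turns an undirected skeleton into a DAG — every learned
  edge is directed from the earlier to the later variable — and it is the
  reason learned structures are acyclic by construction. Within a level,
  the listed position breaks ties, mirroring the order in which variables
  are presented to experts during elicitation.
* **Ordinality.** All variables are coded as 0-based integer states with a
  meaningful order. This is what justifies a trend test (rather than a
  generic chi-squared-type test) as the conditional-independence oracle,
  and it is what the synthetic generator emulates.

## The conditional-independence test

`jt_ci_test()` tests $X \perp Y \mid C$ with the Jonckheere–Terpstra
statistic, which targets monotone ordered alternatives of $Y$ across the
ordered groups of $X$. Within each configuration (stratum) of $C$, the
tie-corrected statistic is computed from the $X \times Y$ contingency
table:

* $T$ counts, over all pairs of observations in different $X$-groups, how
  often the higher-$X$ observation also has higher $Y$ (ties count one
  half);
* under the null, $E[T] = (N^2 - \sum_i n_i^2)/4$ with $n_i$ the group
  sizes, and $\mathrm{Var}[T]$ is the standard three-term
  Hollander–Wolfe expression combining the tie corrections for the
  $X$-margin and the $Y$-margin.

Strata with fewer than `min_stratum` rows (default 5; the variance is
undefined below 3 rows regardless) are excluded, and their rows do not
count toward the test's effective sample size. The per-stratum $T$,
$E[T]$ and $\mathrm{Var}[T]$ are summed and referred to the asymptotic
normal, $z = (T - E[T])/\sqrt{\mathrm{Var}[T]}$, with a **two-sided**
p-value — the direction of association is not pre-specified per pair.
Strata in which $X$ or $Y$ is constant carry no trend information and
contribute zero to all three totals; if no stratum carries information the
test reports statistic 0 and p-value 1 with a `degenerate` flag rather
than failing.

The test suite checks the statistic against a brute-force pairwise count,
the null moments against the permutation distribution, and the empirical
type-I error at $\alpha = 0.05$ against the nominal level (1000 replicates
at $n = 500$).

## Structure learning

`mmpc_skeleton()` implements Max-Min Parents and Children. For each target
variable the *forward* phase repeatedly adds the candidate with the
largest min-association — association is $1 - p$, minimised over all
subsets of the current candidate set up to `max_conditioning` — provided
that minimum is still significant at `alpha`; because the minimum can only
shrink as the set grows, a candidate that ever becomes non-significant is
discarded permanently. The *backward* phase removes any member rendered
independent of the target given some subset of the others. Skeleton edges
then require membership in both endpoints' sets (the conservative AND
rule).

The causal ordering enters the search itself in one place: the outcome is
*disallowed from the start* as a candidate cause of any other variable.
An edge incident to the outcome is therefore judged by the outcome's own
neighbour search alone, since the reverse membership test is forbidden by
design. All remaining direction decisions are deferred to
`orient_edges()`.

Defaults: `alpha = 0.05` per test with no multiple-testing correction
(the algorithm's standard form), `max_conditioning = 3` for tractability,
`min_stratum = 5`. Learning is invariant to row order; all edge lists are
canonically sorted.

### The expert network as a prior

When an expert-elicited structure is supplied to `learn_structure()` or
`fsbn()`, its edges (taken as undirected) are tested at a laxer level
`alpha_keep` (default 0.20) in both phases, while data-discovered edges
must pass the stricter `alpha`. An expert edge is therefore retained
whenever the data reject independence at the 20% level, and dropped when
they cannot — edges with no support at all in the data do get removed.
This is one defensible reading of "using the expert network as a prior"
for a constraint-based learner; the mechanism is deliberately isolated
behind the `alpha_keep` parameter so it can be revisited, and outputs
under it should not be presented as replications of any published
expert-prior network. Note the retention probability of a spurious expert
edge under exact independence is roughly `alpha_keep` itself.

## Parameter estimation

`fit_cpts()` estimates every CPT by maximum a posteriori under a
multinomial likelihood with a Dirichlet prior equivalent to add-one
smoothing:

$$\hat\theta_i^{jk} = \frac{n_{jk} + c}{n_k + r_i c}, \qquad c = 1
\text{ by default},$$

which keeps every entry strictly positive even for parent configurations
never observed — important downstream, because it makes zero-probability
evidence impossible for fitted networks. The pseudocount is exposed as a
parameter so sensitivity to the prior can be checked; the package default
matches add-one.

## Inference

`posterior()` computes exact conditional distributions by variable
elimination with a min-fill elimination order. Junction-tree
(Lauritzen–Spiegelhalter) propagation is the classical engine for
networks of this size, but the two are semantically interchangeable: the
contract here is *exactness*, and the engine must agree with full-joint
enumeration (`enumerate_posterior()`, the built-in oracle) to $10^{-10}$,
which the acceptance tests verify over thousands of random queries.
Zero-probability evidence raises a distinct "impossible evidence" error
rather than returning NaNs — reachable only with user-supplied CPTs,
since fitted ones are smoothed. `map_predict()` breaks posterior ties
toward the lower state index, i.e. toward *food secure*; the rule is fixed
for reproducibility.

For cross-validation the package predicts the outcome from **all** other
fourteen variables. Because that evidence covers the outcome's Markov
blanket, `posterior_given_rest()` evaluates the posterior from the
outcome's own CPT and its children's CPTs, vectorised over rows; it is
tested to agree with row-by-row `posterior()` calls exactly. (Whether one
conditions on all variables or only the Markov blanket is immaterial for
an exact engine.)

## Predictive validation

`cross_validate()` holds the structure fixed, shuffles rows with the seed,
splits them into `k` near-equal contiguous folds (remainder rows one per
leading fold), refits CPTs per fold and scores all held-out predictions:

* **Brier score** — binary single-term convention, $mean((p - y)^2)$ with
  $y = 1$ for food insecure. The single-term convention (not the two-class
  sum, which is twice it) is used because published best-model scores at a
  ~10% minority-class base rate are consistent with it in magnitude; the
  choice is documented here so it is auditable.
* **Information reward** — $mean(1 + \log_2 p^{*})$ with $p^{*}$ the
  predicted probability of the realised state; equivalently one minus the
  forecast cross-entropy in bits. Base-2 logs are used throughout (the
  base is a documented convention; switching it rescales IR and BIR
  linearly).
* **Bayesian information reward** — per case, the two-class average of
  $\log_2(p_c/q_c)$ for the class that occurred and
  $\log_2((1-p_c)/(1-q_c))$ for the other, following the Hope–Korb
  construction; the prior $q$ is the training-fold frequency of food
  insecurity. Predicting exactly the prior scores zero, so a positive
  value means the network beats the base rate.

`confusion_split()` produces the companion 90/10 train/test confusion
matrix with food insecure as the positive class; it is deliberately
seed-sensitive (a property the tests assert), which is why the
cross-validated scores, not the confusion matrix, are the primary
comparison instrument.

## Interventions and sensitivity

`do_surgery()` implements the do-operator by graph surgery: each
intervened variable loses its incoming edges and receives a point-mass
CPT on the forced state; all other CPTs are untouched (bit-identical,
which the tests check). Multi-variable interventions are one simultaneous
surgery. `interventional_query()` then answers
$P(\text{target} \mid do(\cdot))$ exactly; on parentless variables it
coincides with conditioning, and on confounded ones it equals the
backdoor-adjustment computation, both verified by enumeration.

The sensitivity analysis is belief-based and therefore uses
*observational* weights $P(x)$:

* mutual information reduction
  $I = H(FS) - \sum_x P(x) H(FS \mid x)$, in bits, also reported as
  $I/H(FS)$ (reported as 0 with a degeneracy flag if $H(FS) = 0$);
* expected change of belief
  $S^2 = \sum_x P(x) \sum_s (P(FS = s \mid x) - P(FS = s))^2$.

The $S^2$ formula is a reconstruction from the cited description of the
metric (no closed form is printed in the source literature); it is
isolated in one function so it can be swapped if a canonical definition
surfaces.

## The synthetic generator

Because real HDSS household data are access-restricted, the package ships
a first-class generator. `make_agincourt_like_network()` builds a
ground-truth network over the fifteen named variables:

* a default five-level ordering (demographics/environment, income
  channels, household resources, crop marketing, outcome) with default
  cardinalities 2–4 and a binary outcome — *plausible stand-ins*, not a
  claim about any published level table, and fully configurable;
* edges sampled independently between earlier-level/later-level pairs at
  `density` (default 0.2), every non-root-level variable guaranteed at
  least one parent (hence the outcome always has one), and parents capped
  at `max_parents = 4` so CPTs stay estimable at census-scale $n$;
* CPT rows with *monotone ordinal* structure: each edge carries a signed
  effect drawn once, a row's mean is
  $\mathrm{softmax}(a_j + \gamma \tanh(\eta) t_j)$ with $\eta$ the summed
  parent effects and $t_j$ the child's state score in $[-1,1]$, and the
  realised row is a Dirichlet draw (concentration 50) around that mean.
  The $\tanh$ saturation keeps rows informative but bounded away from
  0/1. Monotone dependencies are what ordinal household data exhibit and
  exactly what the Jonckheere–Terpstra machinery targets — a generator
  with unstructured categorical dependencies would mis-state the
  pipeline's operating conditions;
* the outcome CPT's log-odds are tilted by root-finding so the *exact*
  marginal food-insecurity probability equals `insecure_rate`
  (default 0.10, a minority class).

`sample_households()` forward-samples complete rows in topological order.
`coarsen_rare_states()` reproduces the usual state-calculation step of
merging rare ordinal states: the rarest sub-threshold state is merged
into its less-rare neighbour (ties toward the interior) until all states
meet the threshold or two remain; the recoding map is returned.

What the generator does **not** emulate: missing data (the pipeline is
complete-case by contract), longitudinal structure (one row per
household), measurement error, and real-world effect sizes. Passing tests
therefore demonstrate correctness of the machinery and recoverability
under monotone ordinal signal — not that any particular real-world
network would be recovered.

## Numerical conventions and degenerate inputs

* CPT rows must sum to 1 within $10^{-9}$ on load and $10^{-9}$ at
  construction; posteriors are normalised exactly and verified against
  enumeration to $10^{-10}$.
* Probabilities are serialised to JSON with 17 significant digits, so a
  save/load round trip reproduces doubles bit-for-bit. Parentless
  variables use the table key `"."` (JSON objects cannot reliably carry
  an empty-string key through every serialiser).
* Minimal d-separating sets break cardinality ties lexicographically on
  the sorted member list; all enumeration outputs are canonically sorted.
* Every stochastic function takes an explicit integer seed, restores the
  caller's RNG state, and is bit-reproducible given its inputs.
* Degenerate cases are contracts, not crashes: constant test columns give
  p = 1 with a flag, zero-probability evidence raises a named error,
  an entropy-free outcome reports $I/H = 0$ with a flag, and empty data
  yield uniform (prior-only) CPTs.

## Problem sizes used in the checks

The shipped tests and `scripts/acceptance.R` run the pipeline at the
scales the package targets: structure recovery and expert-prior
comparisons on 10,000-household samples (10 and 20 seeds respectively),
cross-validation and the end-to-end run on 11,739 simulated households
(matching the scale of the motivating census sample), test calibration on
1000 replicates of $n = 500$, and inference-exactness sweeps over
thousands of random networks and queries. These sizes were chosen as
representative of a census-scale analysis while keeping a full run in the
low minutes on one core.

## Known limitations

* Constraint-based learning with a trend test can miss genuinely
  non-monotone dependencies; that is a deliberate trade made for power on
  ordinal data.
* The expert-prior mechanism (`alpha_keep`) is an interpretation, not a
  published algorithm; see above.
* No missing-data handling (complete cases only), no dynamic/longitudinal
  networks, no latent-variable discovery, and no approximate inference —
  networks of this size do not need it.
* Causal conclusions inherit all the usual caveats of structure learning
  from observational data; the causal ordering restricts directions but
  cannot certify them.
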