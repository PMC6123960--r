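---
title: "Models and methods for white-stripe pattern evolution"
author: "stripemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for white-stripe pattern evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripemorph)
```

# The scientific problem

Clownfishes (Amphiprionini, ~30 species) wear zero to three vertical white
stripes on a dark body, and every species falls into one of four adult
categories: no stripe (A), a head stripe (B), head + trunk stripes (C), or
head + trunk + peduncle stripes (D).  Strikingly, no species has a trunk or
peduncle stripe without the stripes rostral to it.  This package provides
the comparative machinery to ask, on a time-calibrated phylogeny, how such
a pattern evolves: which transitions between morphs occur at all, at what
rates, whether the ancestral clownfish was fully striped, whether stripe
number tracks morphology or ecology, and whether sympatric communities are
assembled so that co-occurring species look different (the species-
recognition hypothesis).

A small number of species are polymorphic (two morphs observed in natural
populations).  Rather than forcing a single state, every analysis can be
repeated over the Cartesian product of the polymorphic species' state sets
(`enumerate_codings()`); three two-morph species give eight coding
combinations.  An ambiguity mode (tip partial likelihood 1 on each member
state) exists but is not the default, because enumeration keeps each run's
data interpretable as one concrete coding.

# Discrete-character models

## The Mk likelihood and the four transition structures

The stripe character evolves as a continuous-time Markov chain with rate
matrix $Q$, $q_{ij} \ge 0$ for $i \ne j$ and rows summing to zero (rates
per Myr).  The likelihood on the tree is computed by Felsenstein pruning:
tip partials are indicators over each tip's state set, branches propagate
by $e^{Qt}$, and the root combines partials under a prior.  Four constraint
structures are the scientific hypotheses:

* **i** — all $k(k-1)$ rates free (12 parameters for $k=4$);
* **ii** — symmetric rates, $q_{ij} = q_{ji}$ (6);
* **iii** — gaining or losing two or more stripes in one step is forbidden:
  $q_{31}=q_{41}=q_{42}=q_{13}=q_{14}=q_{24}=0$ with states ordered A–D
  (6);
* **iv** — ii and iii combined: three stepwise symmetric rates
  $A \leftrightarrow B$, $B \leftrightarrow C$, $C \leftrightarrow D$ (3).

`build_model_matrix()` encodes these as an index matrix over off-diagonal
cells (0 = forced zero, equal indices = shared parameter), and
`fit_mk()` maximizes the likelihood over the free classes on the log scale
(box constraints $[10^{-9}, 10^{3}]$ per Myr, seeded multi-start L-BFGS-B,
10 starts by default).  Equal-rates vs all-rates-different fits are
compared by a likelihood-ratio test; model sets are ranked by AICc with
Akaike weights, and a difference of 4 or more AICc units is read as
support.  Because AIC and AICc can disagree in print, both are reported in
every table.  The AICc sample size is the number of tips; that choice is a
convention, not a derivation, and is recorded in the table metadata.

**Root prior.** The default is uniform over states.  A stationary-
distribution prior and arbitrary custom priors are available.  None of the
downstream conclusions about transition structure depend on this choice in
our validation runs, but ancestral-state posteriors do, which is why the
prior is an explicit argument everywhere.

**Matrix exponential.** $e^{Qt}$ is computed by scaling-and-squaring with
a diagonal Padé [6/6] approximant (`expm_pade()`).  The test suite holds
it to a truncated-series oracle within $10^{-10}$ for $\lVert Qt \rVert
\le 10$ and checks probability conservation (row sums of 1 within
$10^{-12}$) out to $t = 100$.

## Ancestral states and stochastic mapping

`marginal_asr()` performs the standard two-pass marginal reconstruction
(subtree partials up, out-of-subtree complements down); on trees small
enough for exhaustive enumeration the posteriors agree with a brute-force
sum over all internal-node assignments to $10^{-9}$.

`sample_histories()` draws complete character histories conditional on the
tip data and a fixed $Q$ (the empirical approach: $Q$ is held at its MLE,
not integrated over).  Node states are sampled jointly — the root from its
posterior, then each child conditionally on its sampled parent — and
branch interiors from the endpoint-conditioned CTMC bridge.  The bridge
sampler uses uniformization: with $\mu^* = \max_i(-Q_{ii})$ and $R = I +
Q/\mu^*$, the number of virtual jumps is drawn from its exact conditional
distribution, jump times are uniform order statistics, and the discrete
bridge walks through powers of $R$; self-jumps are collapsed.  A naive
rejection sampler is retained internally purely as a cross-validation
oracle for the tests.  The default ensemble size is 10,000 histories.

`summarize_simmap()` returns node-state frequencies (which must match the
marginal reconstruction within Monte-Carlo error — this is an acceptance
check, not an assumption), expected transition counts, and expected dwell
times; dwell times are conserved exactly per history.

**Counting evolutionary transitions.** Statements of the form "a minimum
of five transitions to ontogenetic stripe loss" need an explicit rule.
`count_trajectory_transitions()` makes it configurable rather than
implicit: a node's majority state is the state whose posterior frequency
reaches a threshold (default 0.5), and a branch carries a transition when
parent and child majority states are defined and differ.  Raising the
threshold can only remove branches.

# State-dependent diversification (MuSSE)

`musse_loglik()` evaluates the joint likelihood of tree shape and
character under a birth–death process with state transitions, integrating
the extinction and data ODEs

$$\frac{dE_i}{dt} = \mu - (\lambda + \mu + \textstyle\sum_{j \ne i} q_{ij})E_i
  + \lambda E_i^2 + \textstyle\sum_{j \ne i} q_{ij}E_j,$$
$$\frac{dD_i}{dt} = -(\lambda + \mu + \textstyle\sum_{j \ne i} q_{ij})D_i
  + \textstyle\sum_{j \ne i} q_{ij}D_j + 2\lambda E_i D_i,$$

tip-to-root along every branch, multiplying daughter $D$ vectors and one
speciation rate at each node.  The integrator is an adaptive Cash–Karp
Runge–Kutta (4th/5th order) written in C++, with absolute and relative
tolerances of $10^{-8}$ by default; tightening to $10^{-10}$ moves the
log-likelihood by less than $10^{-5}$ on the test fixtures, and $E \in
[0,1]$, $D \ge 0$ are enforced (violations beyond rounding tolerance are
errors, not silent clips).

Speciation and extinction rates are **shared across states** throughout:
on a 30-species radiation, state-specific $\lambda$, $\mu$ would multiply
parameters without hope of identifiability, and the questions of interest
live in $Q$.  A useful side effect anchors the validation: with shared
rates the character cannot influence diversification, so the likelihood
factorizes into a tree term and the Mk term, and differences of
`musse_loglik()` across two $Q$ matrices must equal the corresponding
`mk_loglik()` differences.  The test suite holds this identity to
$10^{-4}$, and the single-state pure-birth limit to the closed-form Yule
likelihood within $10^{-6}$.  Both checks are honest because the
implementation integrates the ODEs numerically and never uses the
factorized form.

**Missing species.** Incomplete sampling is corrected by a global sampling
fraction $f \in (0,1]$: tip conditions become $D_i(0) = f \cdot
\mathbf{1}[i = \text{observed}]$, $E_i(0) = 1 - f$, treating missing
species as randomly placed.  The pipeline defaults to $f = n_\text{tips} /
30$ (capped at 1), reading the tree as a sample from the 30 described
clownfish species; the low-level functions default to $f = 1$ because a
clownfish-specific ratio is meaningless for simulated trees of arbitrary
size.  **Root handling** defaults to likelihood-weighted state combination
with survival conditioning ($D_i / [\lambda(1 - E_i)^2]$); equal weighting
and custom weights are available, and both settings are recorded in every
fit because absolute AIC values depend on them.

`musse_model_table()` fits models i–iv (parameter counts 14, 8, 8, 5
including $\lambda$ and $\mu$) and tabulates AICc, ΔAICc and weights, one
table per coding combination when the coding is polymorphic, plus the
per-coding model-iv rate estimates so their mean ± SD across combinations
can be reported.

# Phylogenetic regression and morphometric indexes

Stripe number (0–3, treated as numeric — a single-slope regression, not an
ordinal model) is regressed on one trait at a time, mirroring a simple
battery layout: host-anemone count, maximum body size, body elongation
(height / standard length), and the two dorsal-fin lobe indexes, anterior
$(l_1 - l_2)/L$ and posterior $(l_r - l_2)/L$, where $l_1$ is the third
dorsal spine, $l_2$ the most posterior spine, $l_r$ the longest soft ray
and $L$ the fin length.  Species lacking a measurement are dropped
per-regression with the count reported.

`pgls_fit()` is generalized least squares with error covariance
proportional to the Brownian-motion matrix $C$ (shared root-path lengths,
from `phylo_vcv()`): $\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$.
The slope test is $F = (\mathrm{RSS}_0 - \mathrm{RSS}_1)/(\mathrm{RSS}_1 /
(n-2))$ with both residual sums of squares in the $C^{-1}$ metric and
$\mathrm{RSS}_0$ from the intercept-only GLS fit, referred to $F(1,
n-2)$.  This construction is declared, not estimated: it reduces exactly to
OLS on a star tree, is invariant to rescaling $C$, and its type-I error at
the 5% level calibrates into $[0.03, 0.07]$ in simulation.  No multiple-
testing correction is applied across the battery (none is standard in this
layout); readers should treat the five p-values accordingly.

# The species-recognition randomization test

For a community, the statistic is the number of identically striped
unordered pairs, $\sum_s n_s(n_s - 1)/2$.  Polymorphism is handled by a
maximum-over-assignments rule: the community score is the largest pair
count attainable over all assignments of polymorphic members to their
morphs (`max_identical_pairs()`), applied identically to natural and
randomized communities so the statistic is exchangeable under the null.

The null model draws communities of the same richness uniformly without
replacement from the regional species pool (9,999 draws by default).  Two
significance summaries are reported:

* `p.value` — a one-sided binomial sign test on the direction of the
  comparison: with $g$ random communities scoring above the observed value
  and $l$ below, $p = P(\mathrm{Binom}(g + l, 1/2) \ge g)$, ties dropped.
  This is the construction that reproduces the published table style, and
  it is *intentionally bimodal*: under the null it piles up near 0 and 1,
  because it asks where the observation sits relative to the null median
  with the full precision of the randomization.  It is a direction
  summary, not a calibrated tail probability.  (A variant comparing $g$
  against half of all draws is available via `binomial_mode =
  "vs_half"`.)
* `p.mc` — the standard Monte-Carlo permutation p-value $(l + e +
  1)/(n_\text{random} + 1)$ with $e$ the tie count: the calibrated
  probability that a random community scores at most the observed value.
  Under a truly random assembly it is valid (super-uniform given the
  statistic's ties); this is the quantity used in the calibration tests.

On small pools an exhaustive enumeration over all richness-subsets
(`exact_null_proportions()`) serves as the oracle for the Monte-Carlo
proportions.

# Synthetic data: what it emulates and what it does not

Every analysis stage is exercised end-to-end on generated data, so the
package is testable with no external downloads:

* `simulate_bd_tree()` — forward birth–death simulation from a crown of
  two lineages, stopped when the extant count reaches the target (at a
  uniform time within the holding interval) and retried on extinction.
  Rejection conditioning is simple and adequate at the tree sizes used
  (≤ 500 tips); it is not a uniform sample from the fully conditioned
  birth–death distribution, which none of the validation checks require.
* `simulate_mk()` — forward CTMC along every branch, returning the full
  latent history so recovery tests have ground truth.
* `simulate_bm_traits()` — Brownian predictor and response with a known
  slope, for regression recovery and calibration.
* `simulate_pool_and_communities()` — morph-labelled pools with a set
  polymorphic fraction; communities drawn uniformly (null-true) or with a
  dissimilarity bias of adjustable strength (alternative-true).

The packaged demonstration dataset (`synthetic_clownfish_demo()`,
`inst/extdata/synthetic_*`) mimics the scale of the clownfish system: a
27-tip ultrametric tree (birth 0.25, death 0.1 per Myr), a 4-state stripe
character simulated under the stepwise symmetric model with rates 0.123,
0.103, 0.052 per Myr from a fully striped root, morph frequencies
(1, 5, 11, 10)/27, three polymorphic species (eight coding combinations),
a binary ontogenetic-trajectory character, trait measurements for 22 of 27
species in which only the anterior lobe index tracks stripe number, a
10-species pool and eight communities of richness 3–6 assembled with a
dissimilarity bias.  All of it regenerates bit-for-bit from a frozen seed
(`scripts/make_fixture.R`), and the species are labelled `syn_sp*` to make
their synthetic origin unmistakable.

Passing tests on these data show that the estimators recover known
generating processes at realistic sizes.  They do not show anything about
features the generators lack: among-lineage rate heterogeneity, state-
dependent diversification (excluded by construction here), measurement
error in morphometrics, or geographically structured community assembly.
Conclusions about the real system additionally require the real inputs —
the published time-calibrated phylogeny, the curated coding table and the
observed community lists — supplied in the same file formats.

# Validation scales and reproducibility

The acceptance checks run at these problem sizes, chosen to exercise each
method at or above the scale of its intended use: exhaustive-enumeration
likelihood checks on 50 random trees of 3–5 tips; 10,000 stochastic maps
on the 27-tip dataset compared to the marginal reconstruction at every
node; the factorization identity on ten 25-tip datasets; model-selection
recovery on ten 200-tip trees simulated under model-iv rates (0.12, 0.10,
0.05); regression coverage over 100 replicates on a 100-tip tree and
type-I error over 1,000 replicates on a 50-tip tree; randomization
proportions against exhaustive enumeration on an 8-species pool.  Every
random stage takes an explicit seed, one master seed is split
deterministically per stage in the pipeline, and `run_full_analysis()`
reruns byte-identically from the same configuration.

# Known limitations

* Hidden-state, covarion and rate-heterogeneity models are out of scope;
  so are state-specific diversification rates, GeoSSE/HiSSE variants and
  MCMC over $Q$ or histories.
* PGLS assumes plain Brownian errors; Pagel's λ and OU structures are not
  fitted.
* The AICc sample-size convention (n = tips) and the root prior are
  documented choices with no uniquely correct value; both are surfaced as
  arguments and recorded in outputs.
* The tip-count conditioning of the tree simulator is approximate (see
  above), and the community null is richness-preserving and uniform —
  abundance-weighted or spatially explicit nulls are not implemented.
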