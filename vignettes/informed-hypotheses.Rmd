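---
title: "Informed hypotheses on category proportions: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informed hypotheses on category proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordbf)
```

## The models

`ordbf` works with two conjugate families. Multinomial: counts
$x \sim \text{Multinomial}(x_+, \theta)$ with
$\theta \sim \text{Dirichlet}(\alpha)$; the concentrations $\alpha_k$ read
as a-priori category counts, and the default $\alpha_k = 1$ is uniform over
the simplex. Independent binomials: successes
$x_k \sim \text{Binomial}(\theta_k, n_k)$ with independent
$\theta_k \sim \text{Beta}(\alpha_k, \beta_k)$ priors, default
$\text{Beta}(1, 1)$. Priors live on the probability scale throughout; no
probit-scale prior is ever elicited, which keeps "one prior observation per
category" interpretable.

An informed hypothesis $\mathcal{H}_r$ constrains the proportions with
`<`/`>`, `=`, `,` (free members within a constraint) and `&` (independent
constraints). Within each independent constraint the elements — single
proportions, equality-tied groups, or free groups — must form a linearly
ordered chain. This "stick" structure is not cosmetic: both the constrained
Gibbs sampler and the stick-breaking transform below rely on every
coordinate having a well-defined interval given its chain neighbours, which
a partial order does not provide. The parser therefore cannot express
branched hypotheses, and `=` binds tighter than `,`, so `"4 , 5 = 6"` is a
free element whose members are `4` and the tied pair `{5, 6}`. Each
category may appear once; chains are stored ascending, with `>` input
reversed on parse so a single code path handles all bounds.

## Bayes factor factorization

The target quantity is
$\text{BF}_{re} = p(x \mid \mathcal{H}_r) / p(x \mid \mathcal{H}_e)$.
For pure order constraints the Klugkist identity turns this into the ratio
of posterior to prior mass of the restricted region $\mathcal{R}_r$ under
the encompassing model — the normalizing constants of the constrained
posterior and prior densities. For mixed hypotheses the factor splits as
$\text{BF}_{re} = \text{BF}_{2e\mid 1e} \times \text{BF}_{1e}$:

* **Equality part** $\text{BF}_{1e}$, analytic. For a tied group $g$ of
  $m$ categories in a multinomial model, the within-group composition is
  $\text{Dirichlet}(\alpha_g)$ by Dirichlet aggregation, and the equality
  null is its uniform point, giving the Savage–Dickey ratio
  $\log B(\alpha_g) - \log B(\alpha_g + x_g) + x_{g+} \log(1/m)$. When the
  group spans all $K$ categories this reduces exactly to the standard
  multinomial point-null test with $p_0 = 1/K$. For binomials the group's
  individual beta priors collapse onto the shared proportion with a
  $-(m-1)$ correction on both parameter sums. Multiple groups contribute
  additively on the log scale.
* **Conditional order part** $\text{BF}_{2e\mid 1e}$, estimated. Each tied
  group is merged into one category — counts summed, concentrations summed
  minus $(m-1)$, so a uniform prior stays uniform — and the merged category
  competes in the ordering at $\theta/m$, its per-original-category value.
  Tracking this multiplicity is essential: a six-category tied group with
  total posterior mass 0.57 still sits *below* a single category at 0.34
  in the intended ordering, because $0.57/6 < 0.34$. Dropping the
  multiplicity changes the fiscal-digits mixed hypothesis in the README
  from $\log \text{BF} \approx -173$ to $\approx -221$.

`&`-separated constraints are evaluated as independent bridge runs and
their log Bayes factors added. This relies on Dirichlet neutrality: the
composition within any subset of categories is itself Dirichlet with the
subset's concentrations, independent of the rest, and order constraints are
invariant to the within-subset renormalization. Each section therefore
reduces to a self-contained simplex problem. All point-null and
equality-only Bayes factors are pure log-gamma arithmetic; nothing
stochastic is involved, which matters because realistic constraint masses
reach $e^{-480}$.

## Sampling the constrained densities

Bridge sampling needs draws from the order-constrained prior and posterior.
A Dirichlet vector is a normalized vector of independent gammas, and an
ordering of the (multiplicity-scaled) proportions is equivalent to the same
ordering of the scaled gammas, because the normalizer is shared. The Gibbs
sweep therefore samples each gamma from its full conditional truncated to
the interval set by the neighbouring chain elements (free-group peers do
not bound each other); for binomials the full conditionals are truncated
betas directly. Truncated draws use the inverse-CDF method with a switch to
the survival scale when both truncation points sit in the upper tail, and a
jittered-midpoint fallback when the conditional mass underflows — events
that occur a handful of times per million updates and only for extreme
constraint violations.

The chain starts at a deterministic feasible point (element rank within
each section, scaled by multiplicity), discards `n_burn = 500` sweeps, and
keeps every draw (`thin = 1`) by default; all three are arguments. The
contract is distributional — any sampler with the constrained density as
stationary law would do — and is tested by comparing marginal moments
against naive rejection sampling, which is also exposed as
`naive_constraint_fraction()` and used throughout the test suite as the
assumption-free oracle. `effective_sample_size()` reports per-coordinate
ESS from an AR-fit spectral estimate.

## Stick-breaking probit transform

The multivariate-normal proposal lives on $\mathbb{R}^d$, so constrained
draws are mapped there coordinate by coordinate, smallest chain element
first: $\theta_k = (u_k - l_k)\Phi(\xi_k) + l_k$ on the per-category scale
$\psi_k = \theta_k / m_k$. The lower bound is the largest member of the
previous element (0 for the first). Binomial upper bounds are 1. For
multinomial coordinates the remaining stick $R$ must still accommodate the
unplaced peers of the current free element (multiplicity mass $P$, each
above the same lower bound $l$) and the members of strictly higher elements
(mass $Q$, each above every member of the current element), giving

$$u = \min\left(\frac{R - Pl}{m_k + Q},\; \frac{R - Pl - Q\max(A, l)}{m_k}\right),$$

with $A$ the largest already-placed peer. For a pure chain this is the
familiar remaining-stick-over-remaining-count bound (the smallest of three
ordered proportions has $u = 1/3$). Both inequalities hold everywhere on
the constrained region, so the inverse map is defined for every constrained
draw; the largest multinomial coordinate is the stick remainder and carries
no real coordinate. Bounds depend only on earlier coordinates, so the
Jacobian is triangular and
$\log|\det J| = \sum_k [\log m_k + \log(u_k - l_k) + \log\varphi(\xi_k)]$.

For free-group problems the forward image can exceed the region or hit an
empty interval; such points get zero target density through the region
indicator, which is harmless for bridge sampling (they are proposal points
with zero numerator weight) and costs only a little proposal efficiency.
Correctness of the whole construction is established operationally: the
round trip is the identity to $10^{-8}$ on $10^4$ draws including
free-group and merged-category problems, and quadrature of the transformed
unnormalized target over the real line reproduces known region masses
(e.g. $1/2$, $1/6$, and a multiplicity-2 case equal to a beta tail mass)
to $10^{-4}$.

## Bridge estimator and its error

With draws mapped to $\mathbb{R}^d$, the first half fits the proposal by
the method of moments; the second half and an equal number of fresh
multivariate-normal draws enter the Meng–Wong optimal-bridge iteration,
run entirely on the log scale with log-sum-exp guards, initialized at the
simple importance estimate, and stopped when the relative change falls
below $10^{-10}$ (cap 1000 iterations; hitting the cap flags the result
rather than failing silently). Defaults are 12,000 retained constrained
draws — large enough that the nine-category worked examples reproduce to
well within their Monte Carlo error in seconds, small enough that a full
analysis stays interactive; both the split and the proposal count follow
the draw count.

The reported relative mean-squared error combines an iid variance term for
the proposal side with an autocorrelation-corrected term for the MCMC side,
the correction being the spectral density at frequency zero from an
AIC-selected AR fit (window choice ours). Ten-seed replications in the test
suite confirm the seed-to-seed spread of the log estimate matches the
reported error within a factor of three. When several sections or the
posterior/prior pair combine, percentage errors add in quadrature on the
log scale — approximate, and labelled as such.

## Determinism and seeds

Every stochastic step accepts a seed. The top-level functions derive
per-section sub-seeds for the four stochastic stages (prior/posterior
sampling, prior/posterior proposal draws) from the master seed through a
small affine map modulo $2^{31}-1$, so runs are bit-reproducible end to end
and adding a section never perturbs another section's stream.

## What the generators and fixtures do and do not show

`simulate_counts()` draws exact multinomial or binomial tables from known
proportions — the idealized sampling model. Passing consistency tests on
such data (the informed Bayes factor favouring a true ordering in nearly
all replicates at $n = 500$) demonstrates the estimator works under the
model's own assumptions; it says nothing about overdispersion, dependence
between categories, or misspecified totals in real tables. The two packaged
count tables are small published datasets (fiscal first digits; gambling
stochastic-dominance violations by gender and education) and are used as
regression anchors. A CSV template for an eight-journal reporting-error
analysis ships without counts, as that dataset is not reproduced here;
`read_counts()` accepts any `label,x[,n]` table.

## Degenerate inputs, ties, and limitations

* Counts of zero are fine everywhere; a point-null proportion of zero with
  a positive count returns $\log \text{BF} = -\infty$ rather than an error.
* Collapsed concentrations must stay positive: an equality group of $m$
  categories needs $\sum \alpha > m - 1$ (and likewise for $\beta$);
  violations are errors with a remedy in the message.
* Draws exactly on a transform boundary (probability 0 in exact arithmetic,
  reachable through probit saturation beyond $|\xi| \approx 8$) are
  rejected with the offending row index.
* A hypothesis with no order constraints never invokes the sampler: the
  conditional order factor is exactly 1.
* Binomial point nulls support a single shared predicted value only;
  per-category point values and improper priors are out of scope, as are
  constraints on sums, ratios, or odds ratios of proportions, and branched
  (partial-order) hypotheses — the stick-breaking construction has no
  well-defined bounds for incomparable elements.

## Problem sizes used in the checks

The packaged acceptance script evaluates the nine-category fiscal problem
under three priors, the five-model posterior-probability set, and the three
eight-category stochastic-dominance hypotheses, all at the default 12,000
draws (about half a minute in total). The test suite runs the same worked
examples plus closed-form property checks — exchangeable-order masses
$1/m!$ up to $m = 9$, the free-group mass $1/70$, quadrature
normalizations, and rejection-oracle agreement within four combined
standard errors — at draw counts between 2,000 and 12,000 chosen so each
check's Monte Carlo error is comfortably below the tolerance it asserts.
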