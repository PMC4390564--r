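---
title: "The epigenetic animal model: methods and design notes"
author: "epivar"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by `epivar`, the
reasoning behind its numerical and design choices, what the simulator does
and does not emulate, and the package's known limitations.

## The model

The phenotype vector is modelled as

$$ y = Xb + Z_1 u \,(+\, Z_2 m) + \textstyle\sum_k Z_k c_k + Z_1 w + e $$

with flat priors on the fixed effects $b$, an additive genetic effect
$u \sim N(0, A\sigma^2_u)$, optional identity-structured random terms
$c_k$ (permanent environment, herd-year-season, ...), optionally a
maternal genetic effect $m$ correlated with $u$ through a $2\times 2$
covariance matrix $G$, a transgenerational epigenetic effect
$w \sim N(0, T(\lambda)\sigma^2_w)$, and
$e \sim N(0, I\sigma^2_e)$.

The epigenetic effect follows the autorecursive transmission model

$$ w_i = \lambda w_{f_i} + \lambda w_{m_i} + \varepsilon_i,
   \qquad \lambda = \tfrac{1}{2}(1 - v), $$

where $v \in [0,1]$ is the reset coefficient — the expected proportion of
parental epigenetic marks erased at meiosis — and $1 - v$ the transmission
coefficient, split equally between the two parents. The residual
epigenetic variance is $(1 - 2\lambda^2)\sigma^2_w$ when both parents are
known, $(1 - \lambda^2)\sigma^2_w$ with one known parent and $\sigma^2_w$
for founders, which makes the epigenetic variance stationary across
generations (unit diagonal of $T$) provided mates are epigenetically
unrelated. Writing the recursion as $w = Pw + \varepsilon$ gives
$T = (I-P)^{-1} V(\varepsilon) (I-P)^{-\mathsf T} / \sigma^2_w$, and
therefore the exact sparse inverse
$T^{-1} = (I-P)^{\mathsf T} D^{-1} (I-P)$ assembled in one pedigree pass:
with both parents known and $d = 1/(1-2\lambda^2)$, add $d$ at $(i,i)$,
$-\lambda d$ at $(i,\mathrm{sire})$ and $(i,\mathrm{dam})$, and
$\lambda^2 d$ at the three parent-pair cells; the one-parent rule uses
$d = 1/(1-\lambda^2)$; founders contribute 1. The same rule applies
whether the known parent is the sire or the dam. `build_T()` implements
the recursion exactly — on pedigrees whose mates are related its diagonal
exceeds 1 by $2\lambda^2 t_{fm}$, and the pair $T/T^{-1}$ remains mutually
inverse — while the model's stationarity assumption (unit diagonal)
corresponds to the unrelated-mates case.

At $\lambda = 0$ (total reset) $T = I$; at $\lambda = 1/2$ (no reset)
$T = A$ on non-inbred pedigrees, so the two classical extremes — a purely
environmental-looking effect and a second additive effect — are nested in
one parameter.

## Gibbs sampler

One cycle updates, in this fixed order:

1. **Location effects**, by a single-site sweep in ascending equation
   order over the mixed-model equations $Cs = r$, where $C$ carries
   $A^{-1}\sigma^2_e/\sigma^2_u$ in the $u$ block,
   $T^{-1}\sigma^2_e/\sigma^2_w$ in the $w$ block, identity blocks for the
   $c_k$, and $A^{-1} (G^{-1})_{jk}\sigma^2_e$ blocks for a maternal pair.
   Each coordinate is replaced by a draw from
   $N\big((r_i - \sum_{j\neq i} c_{ij}s_j)/c_{ii},\ \sigma^2_e/c_{ii}\big)$.
2. **$\lambda$**, from a truncated normal on $(0, 0.5)$ (its uniform-prior
   support) whose mean and precision are the parental cross-product and
   sum-of-squares sums weighted by $1/(1-2\lambda^2)$ or
   $1/(1-\lambda^2)$; see below for the two update modes.
3. **Variance components**, from scaled inverse-$\chi^2$ conditionals
   $(q + s^2_x)/\chi^2_{\nu}$ with $q$ the structure-weighted sum of
   squares ($u'A^{-1}u$, $w'T^{-1}w$, $e'e$, ...) and
   $\nu = \text{count} + n_x$; $G$ from its inverse-Wishart conditional.

$T^{-1}$ is refreshed after every $\lambda$ update. Because its sparsity
pattern depends only on the pedigree, the plan builder precomputes, for
each of the seven coefficient types of the assembly rules, the positions
it touches; the refresh is then a fixed linear combination of seven base
vectors with weights $d$, $-\lambda d$, $\lambda^2 d$ (and the one-parent
analogues), evaluated in compiled code. The whole cycle runs in C++ with
R's own RNG, so `set.seed()` makes chains bit-reproducible and resumable
(`run_gibbs(init = previous$state)` continues a chain exactly).

### The two lambda updates

The truncated-normal conditional treats the $(1-2\lambda^2)$ and
$(1-\lambda^2)$ factors — both the quadratic-form weights and the
associated normalising constants — as fixed at the current $\lambda$.
That makes it an *approximate* Gibbs step: the exact conditional is
$\prod_i N(w_i;\ \lambda(w_{f_i}+w_{m_i}),\ d_i(\lambda)\sigma^2_w)$
restricted to $(0, 0.5)$, whose $d_i(\lambda)$ dependence the TN drops.
`lambda_update = "paper_tn"` (the default) reproduces the published
algorithm. `lambda_update = "metropolis_exact"` uses the same TN as a
proposal and accepts or rejects against the exact conditional, yielding an
exact MCMC scheme at negligible extra cost; the package's
successive-conditional (Geweke-style) correctness test uses this mode,
since only an exact kernel preserves the prior in that construction. In
practice the two modes give indistinguishable posteriors on the simulated
designs here because the log-factors vary slowly over the support.

### Numerical choices

* $\lambda$'s domain is closed at $[0, 0.5]$: all rules stay finite at
  $0.5$ ($1-2\lambda^2 = 1/2$); draws are clamped to the open interval
  by $10^{-12}$.
* Truncated-normal draws use the inverse-CDF; when the interval mass
  underflows (precision extremely large, mean far outside) the draw falls
  back to the nearer boundary, and when the precision is zero (no
  informative parental effects) to a uniform prior draw. A pedigree with
  no parent-offspring links leaves $\lambda$ at its prior and a warning
  is raised.
* Variance updates refuse nonpositive posterior degrees of freedom before
  sampling starts, naming the offending term; any non-finite draw aborts
  the chain with its cycle number (divergence guard).
* Starting values: location effects 0, $\lambda = 0.25$ (prior mean), and
  the phenotypic variance split equally across the active variance
  components. Results are insensitive to these at the chain lengths used;
  the resume mechanism allows warm starts.
* Chain defaults (100,000 cycles, 20,000 burn-in, thinning 5) are
  desk-scale choices; production analyses of $10^5$-individual pedigrees
  use an order of magnitude more (e.g. 1.25M cycles), available via
  `gibbs_config()` or the CLI's `--paper-scale`.
* Fixed effects come from `model.matrix()` with treatment contrasts, so
  multi-factor models stay full rank and every equation keeps a positive
  diagonal (single-site Gibbs would random-walk on unidentifiable
  contrasts).

## The simulator

`simulate_population()` generates discrete generations: an unrelated base
(half sires, half dams), then per generation a set of full-sib families
whose sire and dam are drawn uniformly (with replacement across families)
from the previous generation's males and females; sexes alternate within
family so both sexes always exist. Founders draw
$u \sim N(0, \sigma^2_u)$, $w \sim N(0, \sigma^2_w)$; offspring draw
$u_j \sim N(\bar u_{par}, \sigma^2_u/2)$ and
$w_j \sim N(\lambda(w_f + w_m),\ (1 - 2\lambda^2)\sigma^2_w)$; each
individual gets one record $y = \mu + u + w + e$. The default
configuration is the full-scale study design (3000 founders, two
generations of 3000 families of 10, $\mu = 100$), with presets `dataset1`
($\sigma^2_u{=}210$, $\sigma^2_w{=}120$, $\sigma^2_e{=}270$,
$\lambda{=}0.30$; $h^2{=}0.35$, $\gamma^2{=}0.20$, $v{=}0.40$) and
`dataset2` ($90, 60, 450, 0.10$; $h^2{=}0.15$, $\gamma^2{=}0.10$,
$v{=}0.80$).

The offspring epigenetic variance deserves a note: the variant
$(1-\lambda)^2\sigma^2_w$ (`epi_offspring_variance = "paper_as_written"`)
appears in some descriptions of this design but contradicts the
covariance model — it shrinks the epigenetic variance every generation
(e.g. to $0.49\,\sigma^2_w$ at $\lambda = 0.3$ versus the stationary
$0.82\,\sigma^2_w$). The default `model_consistent` mode uses
$(1-2\lambda^2)\sigma^2_w$ so that the simulation and estimation models
agree, which parameter-recovery checks require; a test demonstrates the
variant's non-stationarity.

What the simulator does *not* emulate: selection, assortative or
monogamous mating, overlapping generations, unequal family sizes, missing
phenotypes, fixed-effect structure, genotypes, or mates chosen to avoid
relatedness (related matings occur by chance and are handled by the exact
recursion). Passing tests on these populations therefore says nothing
about, e.g., selected livestock data — only that the estimation machinery
recovers the parameters of the process matching its own assumptions.

## Model comparison by LogCPO

`log_cpo()` estimates the leave-one-out predictive density of each record
by the harmonic mean of its per-draw observation densities
$N(y_i;\ \hat y_i(\theta_j),\ \sigma^2_e(\theta_j))$, summed on the log
scale with log-sum-exp stabilisation. The densities condition on the
*drawn location effects* (matching the model's residual definition);
an effect-marginalised CPO is out of scope.

This conditional form has a consequence worth stating plainly: with one
record per individual, the individual-level effects track their own
record, so the harmonic-mean estimator recovers the leave-one-out penalty
for an overfitting term only slowly as the number of stored draws grows.
On data simulated *without* epigenetic variance but analysed with flat
variance priors, $\sigma^2_w$'s posterior does not concentrate at zero —
at $\lambda \to 0.5$ it trades against $\sigma^2_u$ and at
$\lambda \to 0$ against $\sigma^2_e$ — and the comparison at the
population sizes and chain lengths used in this package's test suite
favours the richer model; the margin shrinks steadily as draws
accumulate. The reverse direction is sharp: when epigenetic variance is
present, the model carrying $w$ wins the comparison in every test
replicate. Comparisons on small samples with diffuse priors should
therefore be read with care, and LogCPO differences treated as evidence
only when they are large relative to the between-seed spread.

## Diagnostics

`posterior_summary()` reports the posterior mean, standard deviation and
the shortest 95% interval (HPD95, never wider than the equal-tail
interval). Derived quantities — $v = 1 - 2\lambda$, the transmission
coefficient $1 - v$, $h^2$, $\gamma^2$ (and $m^2$ with a maternal term) —
are computed per stored cycle and summarised as chains, the ratio-of-draws
convention. The cited convergence test of the original workflow is not
described in its text; `convergence_diagnostics()` provides Geweke
z-scores (first 10% vs last 50%, spectral variance via AR fits) and
effective sample sizes as transparent substitutes, advisory only.

## Validation strategy and problem sizes

The test suite validates each conditional against an independent oracle
(2-D quadrature posterior for the intercept model, dense $\sigma^2_e
C^{-1}$ covariance, inverse-$\chi^2$ and inverse-Wishart moments, grid
integration of the exact $\lambda$ conditional), the joint sampler by
successive-conditional simulation against the priors, and end-to-end
behaviour by parameter recovery: 20 seeded replicates of a
3,000-individual population (1,000 founders plus two generations of 100
full-sib families of 10 — the full design's family size at a thirtieth of
its count) fitted with 20,000-cycle chains, requiring each true parameter
inside its HPD95 in at least 90% of replicates. The family-of-10 design
was chosen because large full-sib families give the within/between
decomposition that separates $\sigma^2_u$ from $\sigma^2_e$; with small
families the 20,000-cycle chains mix too slowly for their interval
estimates to be meaningful (effective sample sizes in the single digits).
Coverage is assessed per parameter, the statement that 95% intervals are
calibrated; joint coverage of four dependent intervals is necessarily
lower. These sizes keep the full suite in the tens of minutes on one CPU;
all of them scale up through the same configuration objects.

## Known limitations

* $A^{-1}$ uses Henderson's rules **without** inbreeding accounting, and
  the model assumes stationary epigenetic variance; both are exact for
  the simulated designs and approximations for inbred pedigrees.
* A single $\lambda$ is shared by sires and dams; sex-specific
  transmission, age-dependent epigenetic variance and
  environment-dependent reset coefficients are not modelled.
* The $\gamma^2$–$v$ confounding is intrinsic: at high reset coefficients
  $T \approx I$ and $\sigma^2_w$ trades against $\sigma^2_e$ (the
  "half-moon" joint posterior), so low-signal datasets yield wide
  $\gamma^2$ intervals and strongly negative $\sigma^2_w$–$\sigma^2_e$
  posterior correlations — reproduced qualitatively in the test suite.
* REML/likelihood estimation, multi-chain diagnostics, genomic
  relationship matrices and marker data are out of scope.
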