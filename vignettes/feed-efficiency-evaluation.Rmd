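---
title: "Bayesian multi-trait evaluation of feed efficiency: model, derivations, and design choices"
author: "BayesFeedEff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multi-trait evaluation of feed efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BayesFeedEff)
```

## The problem

Feed is the dominant cost in pig production, so breeding programs want to
select animals that eat less *for the production they deliver*.  Two
families of efficiency traits are in use:

* **FCR** (feed conversion ratio) = ADFI / ADG, a *ratio* of two correlated,
  roughly Gaussian traits.  Its distribution is not Gaussian, depends on the
  population means of both components, and truncation selection on it puts
  unexpected pressure on the components.
* **RFI** (residual feed intake): feed intake conditional on production.
  The *phenotypic* definition (RFI_P) removes the phenotypic regression of
  intake on production, making RFI_P phenotypically independent of ADG and
  LMP; the *genetic* definition (RFI_G) uses genetic partial regression
  coefficients, making the breeding values of RFI_G genetically independent
  of production.

This package implements a fully Bayesian treatment of both, built on a
single trivariate animal model for the recorded traits, so that every
derived quantity — RFI and FCR breeding values, their (co)variances,
genetic trends, and direct/correlated responses to truncation selection —
is obtained as a *function of each posterior sample* and only then
summarized (the ergodic-averaging rule: functions first, averaging last).
This propagates the uncertainty in the "fixed" effects and covariance
matrices into everything downstream, and it never requires a distributional
assumption for the ratio trait.

## The model

For the three recorded traits, average daily feed intake (ADFI, kg/d),
average daily gain (ADG, kg/d) and lean meat percentage (LMP, %):

$$
\mathbf{y}_t \;=\; \mathbf{X}\mathbf{b}_t + b_t\,\mathbf{x}_{(t)} +
\mathbf{Z}\mathbf{a}_t + \mathbf{S}\mathbf{p}_t + \mathbf{e}_t,
\qquad t \in \{\text{ADFI}, \text{ADG}, \text{LMP}\},
$$

with year-quarter, gender and sow-parity as cross-classified "fixed"
factors, a trait-specific body-weight covariate (start BW for ADFI and ADG,
end BW for LMP — animals are tested over a fixed weight interval, so
average BW is not informative), a pen effect (pigs are housed in mixed-sex
pens of 12) and an additive genetic animal effect.  The random-effect
covariance structure is

$$
\operatorname{Var}(\mathbf{a}) = \mathbf{A} \otimes \mathbf{G}_0,\quad
\operatorname{Var}(\mathbf{p}) = \mathbf{I} \otimes \mathbf{K}_0,\quad
\operatorname{Var}(\mathbf{e}) = \mathbf{I} \otimes \mathbf{R}_0,
$$

where **A** is the pedigree-based numerator relationship matrix and G0, K0,
R0 are 3×3 covariance matrices.  Priors are flat for all location
parameters and inverse Wishart for the covariance matrices; the default
prior degrees of freedom $\nu_0 = -(\dim + 1) = -4$ with a zero scale
matrix is the improper flat limit.  A guard requires more than
$\dim - 1 + |\nu_0|$ levels per random term so the full conditionals stay
proper; a proper prior is available through `priorNu`/`priorScale`.

`runGibbs()` samples this posterior.  Location effects whose incidence is
shared across the three traits (factor levels, pens, animals) are drawn as
3-trait blocks from their multivariate-normal full conditionals — with a
genetic correlation of 0.82 between ADFI and ADG, scalar single-site
updates would mix poorly.  The covariate regressions (trait-specific
incidence) are scalar updates.  Covariance matrices are drawn from their
inverse-Wishart full conditionals, with the genetic scale matrix
$\mathbf{M}'\mathbf{A}^{-1}\mathbf{M}$ accumulated through the sparse
A-inverse.  The sampler itself is C++ for speed; all randomness comes from
R's RNG stream, so a single `seed` makes chains bit-identical (the sampler
is single-threaded, which keeps this reproducibility independent of the
machine's core count).

### Pedigree algebra

* `relationshipMatrix()` builds dense **A** by the tabular method (guarded
  above 10,000 animals — the sampler never needs dense A).
* `inbreedingCoefficients()` uses the Meuwissen–Luo ancestor-tracing
  recursion on the $LDL'$ factorization of **A**, so F is available without
  forming **A**.
* `aInverse()` assembles sparse $\mathbf{A}^{-1}$ from Henderson's
  per-animal contributions *with* inbreeding (Mendelian sampling variance
  $\tfrac12 - \tfrac14(F_s + F_d)$).  Multi-generation selection in the
  simulator does produce inbreeding, so the simplified F = 0 rules would be
  wrong here.

Unknown parents (coded `0` or empty) are treated as unrelated founders;
files are re-sorted topologically on load rather than rejected, and
parents referenced but never listed become implicit founders.

### Identifiability

A model with flat priors on all cross-classified factors is
not identified up to level shifts, which would make the population means
needed by the FCR construction ill-defined.  We therefore impose corner
constraints: the first factor (year-quarter) keeps all its levels and
carries the intercept; every later factor drops its first level.  The
body-weight covariates are centered at their sample means, which
decorrelates the regression from the intercept-carrying factor levels and
visibly improves mixing; population means are computed on the original
scale, so this is purely a reparameterization.

## Derived traits, per posterior sample

With $\mathbf{P}_0 = \mathbf{G}_0 + \mathbf{K}_0 + \mathbf{R}_0$ the
phenotypic covariance matrix (the pen variance counts as phenotypic), each
saved sample yields

* partial regression coefficients
  $\mathbf{b}_P = \mathbf{P}_p^{-1}\mathbf{P}_{p,\text{ADFI}}$ and
  $\mathbf{b}_G = \mathbf{G}_p^{-1}\mathbf{G}_{p,\text{ADFI}}$, where the
  $p$ subscript selects the (ADG, LMP) sub-block;
* RFI breeding values
  $\mathbf{a}_{\text{RFI}} = \mathbf{a}_{\text{ADFI}} -
  [\mathbf{a}_{\text{ADG}}\;\mathbf{a}_{\text{LMP}}]\,\mathbf{b}$ on either
  basis;
* the 5×3 transform **B** with rows (ADFI, RFI_P, RFI_G, ADG, LMP) and the
  derived covariances $\mathbf{B}\mathbf{G}_0\mathbf{B}'$ and
  $\mathbf{B}\mathbf{P}_0\mathbf{B}'$ — by construction the (RFI_G, ADG)
  and (RFI_G, LMP) genetic covariances and the (RFI_P, ADG) and
  (RFI_P, LMP) phenotypic covariances are exactly zero, which the test
  suite asserts to 1e-10 on every sample;
* population means $\mu_{\text{ADFI}}, \mu_{\text{ADG}}$ as the
  observation-weighted average of each factor's level effects plus the
  regression at the population-average covariate (weighted, not unweighted,
  averaging: the mean should describe the recorded population);
* FCR breeding values
  $\mathbf{a}_{\text{FCR}} =
  (\mu_{\text{ADFI}} + \mathbf{a}_{\text{ADFI}})/(\mu_{\text{ADG}} +
  \mathbf{a}_{\text{ADG}}) - \mu_{\text{ADFI}}/\mu_{\text{ADG}}$, computed
  with the *same sample's* means so their uncertainty propagates.  No
  Taylor approximation is involved; the genetic variance of FCR is obtained
  empirically from the per-sample breeding values (below).  If a sample
  puts $\mu_{\text{ADG}} + a_{\text{ADG}} \le 0$ the derivation fails
  loudly with the animal ids and sample index — silently clipping such
  samples would bias the posterior summaries.  The phenotypic FCR deviation
  (residuals added to numerator and denominator) is available for
  between-animal spread comparisons but is never used as a variance
  component; pen effects are deliberately left out of this expression.

`deriveTraits()` runs this over the whole chain and returns the six-trait
per-sample breeding-value array (RFI_G, RFI_P, FCR, ADFI, ADG, LMP) for
the candidates.

## Selection analysis

Genetic trends are yearly means of breeding values,
$\mathbf{r} = (\mathbf{T}'\mathbf{T})^{-1}\mathbf{T}'\mathbf{a}$ with
**T** the animal-by-birth-year incidence ("yearly batches" are birth years
here; a test-year basis can be supplied instead).  Because selection acts
within an age group, the genetic (co)variance *available* to selection is
the covariance across candidates of the trend-corrected values
$\mathbf{a}^* = \mathbf{a} - \mathbf{T}\mathbf{r}$, computed per sample —
this is the quantity that is defined even for FCR.  The superiority of a
truncation-selected group for response trait $j$ under criterion $j'$ is

$$
\bar a^s_{jj'} = \frac{1}{n_s}\sum_i a^*_{ij}\,
\mathbb{1}\!\left(a^*_{ij'} \text{ ranks in the top } n_s\right)
\;-\; \overline{a^*_j},
$$

with $n_s = \lceil \text{fraction} \times n\rceil$, the candidate set all
phenotyped animals, the ranking redone in every posterior sample, and
boundary ties broken by ascending animal id for reproducibility.  Favorable
directions default to minimizing ADFI, FCR, RFI_P and RFI_G and maximizing
ADG and LMP.  `responseMatrix()` assembles the 6×6 posterior mean/SD table
with direct responses on the diagonal; the subtraction of the
population-mean makes the baseline explicit rather than leaving it to the
trend correction alone.

## The synthetic population

Real test-station data of this kind are proprietary, so the simulator is a
first-class module: every downstream claim is exercised against data whose
truth is known.  `defaultTruth()` fixes the generating parameters to
reference estimates for such a population: genetic variances (0.035, 0.004,
2.024), genetic correlations (0.82, −0.39, −0.17), heritabilities (0.32,
0.26, 0.56) and phenotypic correlations (0.68, −0.30, −0.17) for (ADFI,
ADG, LMP); trait means 2.61 kg/d, 1.12 kg/d and 62.7%; start BW 54.9 kg
(SD 11.3).  The reference estimates do not identify how the non-genetic
(co)variance splits between pen and residual; we assign pens 10% of it with
the same correlation structure as the remainder (pens are a modest grouping
effect), so K0 + R0 reproduces P0 − G0 exactly; the share is configurable.

`simulatePopulation()` draws founder breeding values from G0 and builds
offspring as parent average plus an inbreeding-adjusted Mendelian sampling
deviation, so the stacked values realize $\mathbf{A} \otimes \mathbf{G}_0$
exactly.  Defaults emulate the commercial scale: ~3,000 phenotyped pigs
(87% boars, matching the recorded sex ratio) in pens of 12 across four
generations on 600 founders.  Between generations, parents are chosen by
truncation on recorded phenotypic FCR (top 25% eligible; sires serve four
litters) — data-based selection keeps Bayesian inference from the recorded
phenotypes valid, and it induces the realistic genetic trends the
trend-correction machinery needs.  Selection on true breeding values is
available (`basis = "true_bv"`) for stress tests, at the cost of
ignorability.  Unreported nuisance structure is fixed once: 4 quarters per
birth year with level effects drawn once from a ±5% spread around the
trait means (internal fixed seed, independent of the simulation seed), six
sow parities uniform with a ±2% spread, gilts eating 0.08 kg/d less,
gaining 0.04 kg/d less and measuring 0.8% leaner than boars, 50–60 days on
test, and end BW = start BW + days × ADG, which makes the LMP covariate
realistically endogenous (as it is in real data, where end weight reflects
realized gain).

What the generator does *not* emulate: feeder-visit-level intake records
and their error-cleaning, growth-curve shapes within the test period,
litter environmental effects (excluded from the model on the same grounds
as in the source analysis), maternal effects, and genotype data.  Passing
tests therefore validate the estimation and selection machinery under the
stated covariance structure, not robustness to those data pathologies.

## Numerical choices

* Chain defaults are desk-scale: 60,000 iterations, 10,000 burn-in,
  thinning 25 (2,000 saved samples).  The commercial-scale prescription
  (1.1M/100k/250, 4,000 samples) is a configuration choice away and changes
  nothing structurally.
* Start values carve the phenotypic sample covariance into 40% genetic,
  10% pen, 50% residual; with the block updates the chain forgets them
  within a few hundred iterations.
* Every 3×3 full-conditional solve is a hand-rolled Cholesky; a
  non-positive-definite conditional stops the sampler with the iteration
  index rather than limping on.
* Effective sample sizes use Geyer's initial positive monotone sequence on
  the autocorrelations; the Geweke z compares the first 10% with the last
  50% with ESS-corrected standard errors.  Constant chains report `NA`
  rather than crashing.
* Chains persist as full-precision (`%.17g`) delimited text plus a JSON
  metadata file, so a write/read round trip is bit-identical.

## Scale of the validation runs

The bundled tests and the acceptance script run the full machinery at a
deliberately reduced scale chosen to keep a complete validation cycle in
the minutes range on a single core: ~2,000 phenotyped pigs over three
generations on 400 founders for parameter-recovery checks (posterior means
of h² and genetic correlations cover the generating values within two
posterior SD), ~200 animals for the sampler-versus-BLUP equivalence check
(with covariances fixed at truth, posterior-mean breeding values correlate
> 0.999 with the direct sparse solution of the mixed-model equations), and
~150 animals for fast structural tests.

## Known limitations

* Records must be complete across the three traits (the data this emulates
  are); missing-trait records would need a different residual update.
* One record per animal; repeated measures are out of scope.
* The h² denominator includes the pen variance by default, consistent with
  defining P0 = G0 + K0 + R0; `includePen = FALSE` exposes the
  alternative, since analyses in this literature are not always explicit about this
  choice.
* No genomic relationships, maternal or dominance effects, and no
  economic-index weighting of the selection criteria.
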