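---
title: "Liability-threshold models for binary traits in twin families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold models for binary traits in twin families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinliab)
```

kinliab estimates how much of the variation in a binary trait — its
motivating application is self-reported hair colour in a large Dutch
twin-family cohort — is genetic, from two complementary sources: the
resemblance of relatives in extended twin families, and genome-wide SNP
data on unrelated individuals. This vignette explains the models, the
numerical machinery, and the design decisions behind both, and says what
the package's simulation-based checks do and do not establish about real
data.

## The liability-threshold model

A binary trait is modelled as the dichotomisation of an unobserved
standard-normal *liability*. A trait with prevalence $K$ corresponds to a
threshold $t$ with $\Phi(t) = K$: an individual is a case when their
liability falls **below** $t$. Under this orientation a larger threshold
means a more common trait — threshold 0 gives prevalence 0.50, threshold 1
gives about 84%, threshold $-1$ about 16%. This is the convention used by
prevalence-threshold tables in the twin literature this package follows;
it is the mirror image of the "affected above threshold" convention common
in psychiatric genetics, and it is applied consistently everywhere,
including the simulator. `prevalence_to_threshold()` and
`threshold_to_prevalence()` are exact inverses (`qnorm`/`pnorm`).

Association between two binary measurements of relatives is expressed on
the liability scale as a *tetrachoric correlation*: the correlation of the
two latent normals that, together with the two thresholds, reproduces the
observed 2×2 table. `estimate_tetrachoric()` uses the standard two-step
maximum-likelihood estimator: thresholds are fixed at the empirical
marginal quantiles, then the multinomial likelihood is maximised over the
correlation by 1-D optimisation. Standard errors come from the observed
information (numerical second derivative of the profile log-likelihood).
Degenerate tables are never silently estimated: an empty margin gives a
missing estimate with a diagnostic, and boundary solutions are pinched at
$|r| = 1 - 10^{-6}$ and flagged with a missing SE — relevant for rare
classes such as red (4.5%) and black (3.4%) hair, where concordant-control
tables dominate.

### Bivariate and family orthant probabilities

All 2×2 cell probabilities derive from the bivariate standard-normal CDF,
computed by deterministic quadrature of the angular (Sheppard/Owen)
representation

$$\Phi_2(h, k; r) = \Phi(h)\Phi(k) + \frac{1}{2\pi}\int_0^{\arcsin r}
\exp\!\Big(-\frac{h^2 - 2hk\sin\theta + k^2}{2\cos^2\theta}\Big)\,
d\theta,$$

whose integrand stays smooth as $|r| \to 1$. With 64 Gauss–Legendre nodes
the absolute error is at machine level (checked against an independent
multivariate-normal implementation in the test suite), and results are
bit-reproducible across runs — there is no Monte Carlo anywhere in the
likelihoods.

## The twin-family variance-components model

Liability variance is decomposed per sex into additive genetic ($A$),
dominance ($D$) *or* shared-environment ($C$), and unique-environment
($E$) proportions, with $A_s + D_s (\text{or } C_s) + E_s = 1$ for each
sex $s$. The five relevant pair classes of the extended design (spouses,
four parent–offspring sex combinations, five twin classes, three sibling
classes) have expected liability correlations, writing $a_s = \sqrt{A_s}$
and the parental additive correlation $\rho_A = \mu\, a_m a_f$:

* spouses: $\mu$ (the phenotypic assortative-mating coefficient);
* MZ twins of sex $s$: $A_s + D_s$ (or $+ C_s$);
* same-sex DZ twins and siblings: $\tfrac12 A_s (1 + \rho_A) +
  \tfrac14 D_s$ (or $+ C_s$);
* opposite-sex DZ twins and siblings: $\tfrac12 a_m a_f (1 + \rho_A) +
  \tfrac14 d_m d_f$ (or $+ c_m c_f$);
* parent of sex $x$ with offspring of sex $y$:
  $\tfrac12 a_y (a_x + \mu\, a_{\bar x})$, where $\bar x$ is the other
  parent's sex. Neither $D$ nor $C$ is shared across generations.

Three structural decisions deserve comment, because the design space was
genuinely open:

* **Assortment algebra.** Spouses are assumed to match on the *phenotypic*
  liability, in a single generation: the spousal correlation is the free
  parameter $\mu$ itself, it induces a parental additive correlation
  $\mu\, a_m a_f$, and there is no iterated-equilibrium inflation of the
  additive variance. This is the simplest internally consistent path
  model. It is also the reading most consistent with the published
  hair-colour analyses this package re-implements: for three of the five
  published colour classes the fitted assortment coefficient essentially
  equals the observed spousal tetrachoric correlation. The one exception
  (red hair, where the published coefficient far exceeds the published
  spousal correlation) is discussed under *Known limitations*.
* **Shared environment** is shared within the offspring generation only
  (all twins and siblings equally, correlation 1); there is no cultural
  transmission from parents, and spouses do not share $C$.
* **Sex limitation is quantitative only**: the same genetic factors act in
  both sexes (cross-sex genetic correlation fixed at 1) but with
  sex-specific variance proportions. A qualitative sex limitation
  (sex-specific genes) is out of scope.

Heritability is reported as broad-sense $A + D$ under ADE and narrow-sense
$A$ under ACE/AE, per sex.

## Fitting

### Weighted least squares on correlation tables

`fit_wls()` minimises $\sum_k w_k (r^{obs}_k - r^{model}_k)^2$ over the
components (log-ratio-reparameterised onto the per-sex simplex) and
$\operatorname{artanh}\mu$. Weights are pair counts when available, else
inverse squared SEs, else equal. Optimisation runs BFGS from a fixed
5-point grid of starting values, so fits are exactly reproducible. When
refitting *published* correlation tables, which print neither pair counts
nor SEs, `default_pair_counts()` reconstructs approximate per-class pair
counts from the published cohort composition (twin pair counts, ~1387
parental couples, 2008 extra siblings in 7497 families); these are the
default weights used by the command-line `fit-family` tool and the
acceptance script. WLS parameter SEs are reported as missing — the inputs
carry no sampling metadata that would make them honest.

### Full maximum likelihood on family data

`fit_ml()` maximises the exact likelihood of the binary observations: each
family contributes the multivariate-normal rectangle probability over its
members' case/control orthants, with member thresholds $t_i = t_{sex(i)} +
\sum_j \beta_j x_{ij}$ and the correlation matrix implied by the model.
Rather than generic numerical integration, the family correlation matrix
is decomposed exactly into at most three shared factors plus an MZ-pair
term:

* a transmitted factor (loading $a_s\sqrt{(1+\rho_A)/2}$ on offspring and
  the matching projections on the parents),
* a family dominance factor (loading $d_s/2$) or shared-environment factor
  (loading $c_s$),
* a residual spousal factor carrying the part of $\mu$ not routed through
  the transmitted factor,
* and, for an MZ pair, one extra shared term with loading
  $\sqrt{\tfrac12 A_s (1-\rho_A) + \tfrac34 D_s}$.

Conditional on the shared factors, members are independent — except the MZ
pair, which is integrated analytically as a conditional bivariate normal
(its co-twins have identical loadings, so only a 2-D CDF with a constant
conditional correlation is needed). The remaining integral has dimension
at most 3 and is evaluated by product Gauss–Hermite quadrature (40/24/16
nodes per dimension for 1/2/3 dimensions); two-member families use the
exact bivariate CDF directly. The test suite verifies both that the
factorisation reproduces the pair-class correlation matrix to $10^{-10}$
over random parameter draws and that pattern probabilities agree with an
independent multivariate-normal quadrature to $10^{-5}$ or better.
Parameter points whose implied structure is not a valid correlation matrix
(negative idiosyncratic variance) are rejected before any likelihood
evaluation.

Without covariates, families with the same role/sex structure are
aggregated by phenotype pattern, so the likelihood cost is independent of
the number of families — a fit to 8,000 families costs the same as one to
800. With covariates (z-scored age, genotype principal components supplied
as columns) each family is evaluated individually. Optimisation is BFGS on
the unconstrained scale, initialised from the per-sex sample prevalences
and, ideally, a WLS fit (`init =`). Observed-information SEs are computed
on request and reported as missing, with a flag, when the optimum sits on
a simplex boundary.

`likelihood_ratio_test()` compares nested ML fits; the default
significance level is a stringent 0.0001, appropriate for the very large
samples this design targets.

## The pedigree simulator

`simulate_families()` generates data with *exactly* the covariance
structure the model assumes — it is the package's ground truth for
recovery and calibration tests.

* The father's liability is built from independent standard-normal
  components with sex-specific loadings.
* The mother's component vector is regressed on the father's realised
  liability with coefficients $\mu \times$ (her loadings); the residual
  covariance is $I - mm'$ (with $m$ the coefficient vector), which keeps
  every component at unit variance and mutually uncorrelated, yields a
  spousal liability correlation of exactly $\mu$, and induces the parental
  additive correlation $\mu\, a_m a_f$ the model expects. (Independent
  unit-variance residuals would inflate the maternal liability variance
  above 1 — the components would correlate through the shared paternal
  phenotype — so the residuals are chosen jointly.)
* Offspring additive values are the parental mean plus segregation noise
  of variance $(1 - \rho_A)/2$; MZ co-twins duplicate their additive and
  dominance values exactly; DZ twins and siblings share dominance with
  correlation $\tfrac14$ (a $\sqrt{1/4}$ family-level plus $\sqrt{3/4}$
  individual-level part) and shared environment fully.
* Phenotype: case when liability < sex-specific threshold (optionally
  shifted by a linear age effect).

The default family-composition mix mirrors the motivating cohort: twin
types in proportion MZM 2345 : MZF 4651 : DZM 1678 : DZF 2710 : DOS 3975,
both parents present, and 0/1/2 extra siblings with probabilities
0.765/0.20/0.035 — about 0.27 extra siblings per family, matching 2,008
siblings over 7,497 families. Ages are uniform on 14–80 (the cohort's
range) with a default age effect of zero on the threshold: the cohort
analyses found age effects significant but published no effect size, so
the default is a configurable stand-in, not an estimate. All randomness
flows from the single mandatory `seed`; identical seeds give identical
output.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs, geographic/ancestry stratification (principal
components are accepted as generic covariates, never computed), secular or
age-dependent changes in the variance decomposition, misclassification of
self-reports beyond what $E$ absorbs, and twin-specific environment.
Passing recovery tests therefore establishes internal consistency of
estimator and model, not robustness to these real-data features.

## SNP heritability (GREML)

`compute_grm()` builds the genetic relationship matrix
$A_{jk} = \frac1m \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
{2 p_i (1 - p_i)}$ from a dosage matrix, with in-sample allele-frequency
estimates by default (reference-panel frequencies may be supplied),
excluding monomorphic and low-MAF SNPs with a message. Per-chromosome
GRMs merge by SNP-count-weighted averaging (`merge_grms()`), which
reproduces the pooled-SNP GRM exactly when the same frequencies are used.
`select_unrelated()` applies the standard relatedness cut-off (default
0.025) by deterministic greedy removal of the individual with the most
violations. GRMs read and write the GCTA binary triplet format
bit-compatibly, plus a plain-text dialect for debugging.

`greml_reml()` fits $y = X\beta + g + e$, $\mathrm{var}(g) = V_g\,A$,
$\mathrm{var}(e) = V_e I$, by average-information REML in the eigenbasis
of the GRM: the first step is EM, later steps are AI updates with
components clamped at a small positive floor ($10^{-6} V_p$), step-halving
when an update would decrease the restricted likelihood, and a guaranteed-
ascent EM fallback. Convergence is declared when the restricted
log-likelihood changes by less than $10^{-8}$ (at most 100 iterations);
non-convergence is flagged, never silent. Fixed covariates are projected
out inside the restricted likelihood (no pre-residualisation). The
reported quantity is $V_g / (V_g + V_e)$ on the *observed* scale — for a
0/1 case-control phenotype no prevalence-based liability transformation is
applied, matching how the motivating analyses tabulate it; a liability
transformation is intentionally not part of the default output. A GRM that
is numerically a multiple of the identity makes $V_g$ and $V_e$
unidentifiable and is refused with an error. The test suite cross-checks
the REML optimum against a profiled grid search of an independently coded
restricted likelihood.

The platform-effect SNP filter used in multi-platform cohorts is
represented only as the ability to pre-filter the dosage matrix by an
exclusion list; re-implementing the case-control platform test itself
would require multi-platform raw data.

## Problem sizes used by the checks

The automated checks run at sizes chosen to make sampling noise small
relative to the tolerances while staying desk-scale: generator↔model
consistency at 20,000 families (all 13 pair-class tetrachorics within 3
Monte-Carlo SEs of the model values); ML parameter recovery at 8,000
families (every component and $\mu$ within 0.05 of truth); WLS
heritability bias over 100 replicates of 1,500 families (within 0.02);
likelihood-ratio calibration over 200 replicates of 500 spouse pairs
simulated under random mating (rejection rate 0.05 ± 0.03 at
$\alpha = 0.05$); GREML recovery at $n = 2000$ individuals × $m = 5000$
SNPs (estimate within 2 reported SEs of the simulated 0.5 and 0).

## Known limitations

* **Red hair and the printed assortment coefficient.** For the rare red
  class, the published variance-components table reports an assortment
  coefficient (0.704) far above the published spousal tetrachoric
  correlation (0.528), while for blond, brown and light-vs-dark the two
  essentially coincide. Under this package's algebra — where the expected
  spousal correlation *is* the assortment parameter — the published red
  correlations imply an additive proportion near 0.84 rather than the
  published 0.73: the parent–offspring correlations (mean ≈ 0.60) force
  $A \ge 2\,\bar r_{PO}/(1+\mu) \approx 0.78$ for any $\mu$ at or below
  the printed spousal value. The two published red numbers cannot both be
  reproduced from the published correlations by any internally consistent
  single-generation phenotypic-assortment model; the package reports the
  refit honestly rather than special-casing the red class.
* WLS on a printed table cannot use information the table does not carry
  (pair counts, SEs, covariances between the 13 estimates); the
  reconstructed pair-count weights are approximations.
* Estimates at simplex boundaries (e.g. $E \to 0$ for nearly perfectly
  concordant MZ classes) are reported with missing SEs and a flag; they
  are valid WLS/ML solutions but their sampling theory is non-standard.
* Case-control GREML on the observed scale is prevalence-dependent;
  comparisons across traits with very different prevalences (blond at 39%
  versus black at 3.4%) should be made with that in mind.

## A worked refit

```{r worked, eval = FALSE}
tab <- read_correlation_table(
  system.file("extdata", "hair_color_family_correlations.tsv",
              package = "kinliab"))
blond <- correlation_table_row(tab, "blond", n_pairs = default_pair_counts())
fit <- fit_wls(blond, model_spec("ADE", sex_limitation = TRUE,
                                 assortment = TRUE))
tidy(fit)
autoplot(fit)
plot_fit_correlations(fit)
```
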