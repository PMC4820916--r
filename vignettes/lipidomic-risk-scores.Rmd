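---
title: "Lipidomic risk scores for incident type 2 diabetes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipidomic risk scores for incident type 2 diabetes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidrisk)
```

# The problem

Type 2 diabetes (T2D) is usually detected through dysglycemia, but the
lipid metabolism disturbances that accompany insulin resistance are
measurable in plasma years earlier. A *lipidomic risk score* (LRS) is a
weighted sum of inverse-normalized plasma concentrations of a handful of
lipid species, chosen by a lipidome-wide survival screen and a backward
elimination step, intended to predict progression to T2D in initially
diabetes-free individuals.

Two features make this a non-standard modeling exercise:

1. **Family structure.** Development cohorts drawn from extended pedigrees
   violate the independence assumptions behind Cox regression and ROC
   analysis. The package therefore fits *kinship-frailty* Cox models and a
   *liability-threshold* ROC in which relatedness enters as a polygenic
   random effect.
2. **Interval follow-up.** Validation cohorts often record only "developed
   T2D by some follow-up visit" with person-time exposure rather than an
   event date, which calls for Poisson person-time models instead of Cox
   regression.

This vignette documents the models, the estimation choices, the synthetic
cohort generator used for testing, and the package's known limitations.

# Relationship matrices

`build_relationship_matrix()` implements the classical founder-down
kinship recursion: founders are unrelated and non-inbred; for an
individual $i$ with parents $f, m$,
$\varphi(i,j) = \tfrac12\{\varphi(f,j) + \varphi(m,j)\}$ for previously
placed $j$, and $\varphi(i,i) = \tfrac12\{1 + \varphi(f,m)\}$. The package
reports coefficients on the $2\varphi$ scale, on which self and identical
twins score 1, parent-offspring and full siblings 0.5, and
grandparent-grandchild, avuncular, half-siblings and double first cousins
0.25. Some published tabulations list far smaller values for 3rd-6th
degree relatives (0.0078 down to 0.0001); those are inconsistent with the
recursion (first cousins are 0.125 on this scale) and are deliberately not
reproduced. The recursion is validated in the test suite against a
gene-dropping Monte Carlo estimate of expected allele sharing.

# Kinship-frailty Cox models

`fit_frailty_cox()` fits

$$\lambda_i(t) = \lambda_0(t)\, \exp(x_i^\top \beta + b_i), \qquad
b \sim N(0, \sigma^2 K),$$

with $K$ the relationship matrix. Estimation is penalized partial
likelihood: a joint Newton iteration over $(\beta, b)$ maximizes the Efron
partial likelihood penalized by $b^\top K^{-1} b / (2\sigma^2)$, and the
frailty variance maximizes a Laplace approximation to the marginal
likelihood,

$$\ell_m(\sigma^2) = \ell_{\text{pen}}(\hat\beta, \hat b)
 - \tfrac12\left\{ n\log\sigma^2 + \log|K| + \log|H_{bb}| \right\},$$

searched on a log-spaced grid and refined by golden-section search.
As $\sigma^2 \to 0$ the criterion converges to the ordinary partial
likelihood, so the profile search always also considers the boundary and
the fit reduces *exactly* to plain Cox regression when the data carry no
familial clustering — a property the test suite verifies coefficient by
coefficient against an independent partial-likelihood implementation.

Numerical choices: Efron handling of tied event times (ties are common
under interval-recorded follow-up); step halving if a Newton step fails to
improve the penalized likelihood; convergence when the penalized
log-likelihood changes by less than $10^{-8}$; the linear predictor is
centered before exponentiation for numerical stability. Standard errors
come from the inverse of the full penalized information, which reduces to
the usual Cox information when $\sigma^2 = 0$.

## Lipidome screening and score construction

`screen_lipidome()` fits one adjusted frailty-Cox model per species with
the species concentration inverse-normalized,
$z_i = \Phi^{-1}\{(r_i - 0.5)/n\}$ with average ranks for ties
(`inverse_normalize()`; the Blom offset $3/8$ is available). Wald
p-values are corrected by the Benjamini-Hochberg step-up rule
(`bh_fdr()`), and species pass at FDR < 0.2 by default. With a kinship
matrix supplied, the frailty variance is by default profiled **once** on
the covariates-only null model and held fixed across the per-species fits
(a two-step scheme analogous to GRAMMAR screening in genetic association);
`sigma2 = "per_species"` re-profiles inside every fit at roughly 20x the
cost. The adjustment set (`default_adjustment()`) contains age, age
squared, sex, their interactions, blood pressures, waist, BMI, total and
HDL cholesterol, triglycerides and drug-use flags.

`backward_eliminate()` starts from the joint adjusted model on all
candidates and repeatedly removes the candidate with the largest Wald
p-value above `alpha_stay` (default 0.05; the elimination rule is
deterministic, so the retained set does not depend on candidate order).
The final coefficients become the score weights:
$\mathrm{LRS} = \sum_s w_s\, i(\text{conc}_s)$, evaluated by
`score_lrs()` with inverse normalization computed within the cohort being
scored. Whether the elimination refits use the mixed or the plain model is
controlled by `sigma2`; the default re-profiles the mixed model, the
paper-agnostic cheap alternative (`sigma2 = 0`) is available.

`tertile_hazards()` quantifies the score on the tertile scale under three
designs — prediabetes-stratified, restricted to normoglycemic subjects,
and tertile-by-prediabetes interaction — because baseline dysglycemia is
both a strong risk factor and a potential confounder of any lipid signal.

# The family-data ROC

Classical empirical ROC points are biased when subjects are related. The
package's `family_roc()` instead estimates, for every cutoff $c$ of the
predictor:

* $p$ — the proportion of subjects above $c$;
* $p_1, p_0$ — the outcome prevalence among subjects above and below $c$;

each through a liability-threshold probit model
(`estimate_prevalence()`) with a polygenic random effect
$g \sim N(0, h^2 K)$ and residual variance $1 - h^2$ (total latent
variance 1, so the marginal prevalence at covariates $x$ is
$\Phi(\mu + x^\top\beta)$). The three prevalences are combined by Bayes'
rule into

$$\text{sens} = \frac{p\,p_1}{p\,p_1 + (1-p)\,p_0}, \qquad
\text{spec} = \frac{(1-p)(1-p_0)}{(1-p)(1-p_0) + p\,(1-p_1)},$$

and the points assembled into a curve with trapezoidal AUC and the
Hanley-McNeil standard error ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$).
`compare_aucs()` contrasts two areas by the 1-df chi-square on
$z = (A_1 - A_2)/\sqrt{\mathrm{se}_1^2 + \mathrm{se}_2^2 -
2 r\,\mathrm{se}_1 \mathrm{se}_2}$; the correlation $r$ defaults to 0 and
should be estimated by bootstrapping paired curves when both areas come
from the same subjects.

Estimation of the liability model uses a Laplace approximation (Newton on
the $n$-dimensional random effect inside, golden-section profile of $h^2$
outside). Design choices worth knowing:

* With no kinship matrix the model is an ordinary probit fitted by the
  package's own Newton iteration; with no covariates its prevalence is the
  sample case fraction exactly. The whole ROC then collapses onto the
  classical empirical ROC — this equivalence (max sensitivity deviation
  below 0.02 at $n = 2000$) is the key validation of the method and part
  of the test suite.
* Degenerate all-case/all-control cutoff subsets clamp the prevalence to
  half a count, with a warning.
* The cutoff grid uses all distinct observed values up to 200, else 200
  quantile-spaced cutoffs: an unbounded "entire spectrum" grid is
  impractical and adds nothing beyond the resolution of the curve.
* With a kinship matrix, $h^2$ is estimated once on the full-sample
  outcome model and held fixed across cutoffs; per-cutoff re-estimation is
  noisy in the extreme subsets and two orders of magnitude slower. Whether
  $p$ itself should be covariate-adjusted is unsettled; the package uses
  the same polygenic intercept-only model for $p$ by default.

# Incremental value metrics

`incremental_report()` contrasts a base and an augmented Cox model by five
metrics: likelihood-ratio $\chi^2$, $\Delta$AIC (identically
$-\mathrm{LR}\chi^2 + 2\,\Delta\mathrm{df}$ for nested fits), the change
in Uno's inverse-probability-of-censoring-weighted (IPCW) concordance
truncated at a horizon, the integrated discrimination improvement (IDI),
and the continuous net reclassification index (NRI), the latter three on
predicted risks $1 - \exp\{-\hat H_0(\tau) e^{x^\top\hat\beta}\}$ with a
Breslow baseline. Event status at the horizon is estimated by IPCW: events
before $\tau$ weighted by $1/\hat G(T^-)$, survivors past $\tau$ by
$1/\hat G(\tau)$, with $\hat G$ the censoring Kaplan-Meier. Under no
censoring every metric reduces exactly to its definitional form, which the
tests verify against brute-force oracles.

The evaluation horizon defaults to 10 years for exact-time cohorts (about
the median follow-up of a long family study) and should be set to 5 for
interval cohorts. Confidence intervals come from a bootstrap that
resamples *families* as units when a cluster column is given — resampling
subjects from a pedigree would destroy the dependence the frailty model
exists to capture.

# Person-time validation

When only "T2D by end of follow-up" is known, `fit_poisson_offset()` fits
a log-link Poisson model with $\log(\text{person-years})$ as offset, so
coefficients are log incidence-rate ratios; score IRRs are reported per
standard deviation of the score in the validation cohort itself (matching
the "per SD change" convention). Three designs are standard: unadjusted,
clinical-covariate adjusted, and prediabetes-adjusted
(`poisson_designs()`). `recalibrate_lrs()` refits the score's species
jointly in this Poisson design and re-labels the coefficients as
recalibrated weights; `bootstrap_validate()` provides percentile bootstrap
CIs (1000 replicates recommended); `cuzick_trend()` implements the
Wilcoxon-type trend test across ordered groups with midrank ties,
validated against a permutation oracle.

# Insulin resistance panel

`compute_ir_panel()` evaluates the printed surrogate formulas exactly:
HOMA-IR $= \mathrm{FPG}\,(\text{mg/dl}) \times \mathrm{FPI}\,(\text{IU/L}) / 405$;
QUICKI $= 1/\{\log_{10}\mathrm{FPI} + \log_{10}\mathrm{FPG}\}$ (base-10,
as in the index's original definition — the source formula writes "log"
bare, so the base is exposed as an argument); McAuley
$= \exp\{2.63 - 0.28\ln \mathrm{FPI} - 0.31 \ln \mathrm{TG}\,
(\text{mmol/l})\}$; and the leptin/adiponectin ratio. FPI units are taken
as printed (IU/L); a laboratory reporting uIU/ml must convert before
calling, since McAuley's scale depends on it. `tertile_ir_association()`
summarizes each measure by tertile medians/IQRs, a Kruskal-Wallis test,
and the Koenker-Machado pseudo-$R^1$ of a median regression on tertile
indicators. Because the design is a factor, that median regression has a
closed form — fitted values are per-tertile medians, the null fit the
overall median — so
$R^1 = 1 - \sum|y - \mathrm{med}_g| / \sum|y - \mathrm{med}|$ is computed
exactly rather than through a linear-programming solver.

# Cost-effectiveness analysis

`build_default_strategies()` instantiates seven screening-and-intervention
strategies over a 5-year horizon: no screening; fasting plasma glucose
(FPG) followed by lifestyle intervention or metformin for the
impaired-fasting-glucose group; LRS followed by metformin or lifestyle for
the high-score group; FPG and LRS combined; and risk-factor assessment
combined with LRS. Screening cost per person sums the per-test assay costs
(LRS: three lipid species at about \$1 each plus \$4 mass spectrometry and
\$4 manpower, i.e. \$11/assay) plus — charged once per strategy, never per
assay — \$29 sample preparation for blood-based strategies and a \$50
primary-care visit. Intervention efficacies are 0.58 (lifestyle) and 0.31
(metformin); treated 5-year T2D probability is
$p_{\text{group}} (1 - \text{efficacy})$.

Decision trees are generated mechanically from the strategy specification
(screen $\to$ risk groups $\to$ intervention $\to$ 5-year T2D chance node
$\to$ cost/QALY leaf) and `rollback()` computes expectations by backward
induction, tested against full path enumeration. `icer_nmb()` reports
incremental cost-effectiveness ratios against a reference strategy
(undefined and flagged when incremental QALYs are non-positive) and net
monetary benefit at a willingness to pay of \$4450.12 per 5-year program.
All costs and QALYs are *undiscounted* 2015 US\$, a deliberate
proof-of-principle choice. Sensitivity analysis: `tornado()` sweeps each
parameter across its range one at a time (cohort-derived probabilities get
wide $\pm 50\%$ ranges, trial-reported costs and efficacies tighter
$\pm 10\text{-}20\%$ brackets — with these defaults the decision is most
sensitive to the 5-year T2D probability of the high-risk group), and
`one_way_microsim()` samples the chosen parameter uniformly, rolls the
trees back per run, and smooths each strategy's expected value with a
fourth-order polynomial least-squares fit.

**Reconstructed defaults.** The intervention costs, medical costs, QALY
values and risk-group frequencies shipped by `cea_costs()`,
`cea_utilities()` and `build_default_strategies()` are *synthetic*,
Diabetes-Prevention-Program-flavoured reconstructions: the authoritative
supplementary tables are not publicly deposited. They are chosen to be
realistic in magnitude (generic metformin far cheaper than lifestyle
coaching over five years; a large 5-year medical cost excess for
diabetes), they are clearly labelled, and every analysis function accepts
overrides. Conclusions about *which* strategy wins should only be drawn
from user-supplied, cohort-derived inputs; the high-score group for an
LRS-based strategy is naturally defined by the Youden-optimal ROC cutoff
(`youden_cutoff()`).

# The synthetic cohort generator

`simulate_pedigree_cohort()` and `simulate_unrelated_cohort()` exist so
that every downstream stage is testable against *known* truth without the
restricted cohort data. The generator emulates:

* **Pedigree structure:** three-generation families (founder couple,
  married-in spouses, grandchildren) — about 40 families and 750+ subjects
  at the defaults, reproducing the kinship coefficient classes above;
* **Lipidome:** 319 species, log-normal marginals (concentrations show
  wide inter-individual variability), a polygenic covariance
  $h^2 K + (1 - h^2) I$ per species across family members
  (default $h^2 = 0.3$), and block correlation across species (blocks of
  10, $\rho = 0.3$) mimicking lipid-class co-regulation;
* **Outcome:** proportional-hazards event times with an exponential
  baseline (about 0.013 events/person-year, matching a familial cohort's
  crude incidence; Weibull shape configurable) and a linear predictor
  carrying planted per-SD log hazard ratios (+0.42, -0.34, +0.54 on three
  of ten candidate species — the same magnitudes and sign pattern as a
  ceramide/lyso-phosphatidylcholine/triacylglycerol score) plus modest
  covariate effects; censoring by 23-year administrative follow-up and
  exponential dropout;
* **Recording conventions:** the pedigree cohort records exact event times
  by default (interval-midpoint and visit-date conventions are available,
  since source data could have used either); the unrelated cohort records
  only end-of-follow-up status with person-years exposure, the at-risk
  exposure being the default so that crude rates match the planted hazard;
* **Glycemic state and insulin resistance:** baseline prediabetes from a
  logistic model on age and BMI, fasting glucose kept consistent with the
  class thresholds, and `simulate_ir_measures()` couples the
  insulin-resistance panel to the planted lipid signal with a tunable
  monotone strength.

Every function is deterministic given the config seed, and the generator
restores the caller's RNG state.

**What passing tests do and do not show.** The generator plants clean
multiplicative hazards on inverse-normal scales, Gaussian covariate
structure and exchangeable block correlations. Real lipidomes have
heavier tails, batch effects, assay floors and far richer cross-species
correlation; real cohorts have informative dropout and measurement error
in outcomes. Green tests therefore certify the *statistical machinery*
(estimators recover what was planted, error rates calibrate, metrics equal
their definitional oracles), not that any particular published effect
would replicate in new data.

# Simulation sizes used by the test and acceptance suites

The package's property checks run at sizes chosen to make each check
statistically meaningful: ROC-equivalence at $n = 2000$; Cox CI coverage
over 200 simulations of $n = 600$; the all-null screen over the full 319
species at $n = 500$; Poisson bootstrap coverage over 100 outer
simulations with 200-replicate bootstraps; gene-dropping at 40,000 drops.
Where the generator's species count does not enter a property (e.g. CI
coverage of a single planted species), simulations use a reduced lipidome
so the suites complete in minutes.

# Known limitations

* No left truncation, time-varying covariates or competing risks in the
  survival models.
* Risk prediction (`predict_risk()`) supports unstratified fits only.
* The liability ROC treats the estimated $h^2$ as fixed across cutoffs;
  uncertainty in $h^2$ is not propagated into the AUC standard error.
* The CEA is a one-shot 5-year tree, not a multi-year state-transition
  model, and performs no probabilistic sensitivity analysis beyond the
  one-way microsimulation.
* Categorical NRI is deliberately not implemented (only the continuous
  version is reported).
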