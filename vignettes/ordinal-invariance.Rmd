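---
title: "Measurement invariance and latent trends for ordinal symptom scales"
author: "ordinvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement invariance and latent trends for ordinal symptom scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordinvar)
```

## The problem

Repeated cross-sectional surveys ask new respondents the same ordinal symptom
items year after year, and rising mean scores are routinely read as rising
symptom burden. That reading assumes *measurement invariance*: that an item
maps the underlying trait onto response categories the same way in every
cohort. If instead respondents' reporting behavior changes — the same latent
level produces higher observed answers — the trend is measurement artifact,
not latent change. `ordinvar` implements the full decision pipeline for
separating the two on ordinal data: dimensionality screening, ordinal
multigroup confirmatory factor analysis, a sequential invariance ladder with
delta-fit decision rules, effect sizes of noninvariance, and latent-mean
trends with freed-versus-fixed counterfactuals. A synthetic survey generator
with controllable noninvariance makes every stage testable without access to
any particular survey's microdata.

## The model

Each of $K$ ordinal items $Y_j \in \{1, \dots, C\}$ is a thresholded latent
response:

$$y_j^* = \nu_j + \lambda_j \eta + \varepsilon_j, \qquad
Y_j = c \iff \tau_{j,c-1} < y_j^* \le \tau_{j,c},$$

with $\eta \sim N(\kappa_g, \phi_g)$ in group $g$, normal residuals with
variance $\theta_j$ (optionally correlated for designated item pairs), and
strictly increasing thresholds $\tau_{j,1} < \dots < \tau_{j,C-1}$. Under the
**delta parameterization** the total latent-response variance
$\psi_j = \lambda_j^2\phi + \theta_j$ is standardized in the reference
condition, and the data inform two kinds of moments per group: standardized
thresholds and the polychoric correlation matrix.

Estimation is the standard two-stage ordinal pipeline, written here from the
ground up:

1. **Thresholds**: $\hat\tau_{jc} = \Phi^{-1}$(cumulative proportion), per
   item, with pairwise deletion of missing cells.
2. **Polychoric correlations**: per pair, the bivariate-normal multinomial
   likelihood is maximized over $\rho$ with thresholds fixed (two-step), by a
   bracketed search on $(-0.999, 0.999)$ refined by Newton steps to score
   tolerance $10^{-8}$. The bivariate normal CDF uses a single-integral
   representation evaluated with 24 Gauss–Legendre nodes (absolute error
   about $3\times 10^{-12}$ for $|\rho| \le 0.99$).
3. **Asymptotic covariance**: the full covariance of the moment vector is
   assembled from per-observation influence functions — closed-form for
   thresholds, pairwise-likelihood scores with a numerically differentiated
   threshold-correction term for the correlations, rescaled for pairwise
   deletion. Its diagonal supplies the DWLS weights; the full matrix feeds
   the robust test statistic and sandwich standard errors.
4. **DWLS fit**: $F = \sum_g n_g\, (s_g - \sigma_g(\theta))' W_g^{-1}
   (s_g - \sigma_g(\theta))$ with diagonal $W_g$, minimized by damped
   Gauss–Newton with analytic Jacobians (convergence: relative $F$ change
   $< 10^{-10}$ and gradient norm $< 10^{-6}$). The reported chi-square is
   the mean-and-variance adjusted (scaled-and-shifted) statistic computed
   from trace terms of the full covariance; a mean-adjusted-only statistic
   is kept alongside and flagged in the diagnostics.

Fit indices: CFI and TLI from the scaled statistics of the target and the
null model (free thresholds, zero correlations); RMSEA multiplies the
per-group noncentrality form by $\sqrt{G}$, i.e.
$\sqrt{G}\sqrt{\max(\chi^2 - df, 0)/(df\,(N - G))}$, with a 90% CI from
inverting the noncentral chi-square (the same convention is used on both
sides of every delta comparison, which is all the decision rules require);
SRMR is computed over residual polychoric correlations only, thresholds
excluded.

## Identification across invariance levels

Ordinal invariance testing cannot free location and scale parameters at
will: $\nu_j$, $\psi_j$ and the thresholds trade off. The package pins one
concrete schedule (reference group = first group):

| level       | thresholds | loadings | $\nu_j$ (non-ref) | $\psi_j$ (non-ref) | $\phi_g$ (non-ref) | $\kappa_g$ (non-ref) |
|-------------|-----------|----------|-------------------|--------------------|--------------------|----------------------|
| configural  | free/group | free/group | 0 | 1 | 1 | 0 |
| thresholds  | equal      | free/group | free | free | 1 | 0 |
| loadings    | equal      | equal      | free | free | free | 0 |
| intercepts  | equal      | equal      | 0 (all groups) | free | free | free |

With $C = 4$ (three thresholds per item) each non-reference group gains one
net constraint per item at the threshold step, $(G-1)(K-1)$ at each of the
loading and intercept steps. Items released by the partial-invariance search
revert the step's own parameter (only) to its configural treatment; an item
with group-specific thresholds keeps $\nu_j = 0$, $\psi_j = 1$ for
identification. Latent means are only reported once at least partial scalar
invariance holds.

## Decision rules and partial search

Transitions are judged by delta fit indices, never by the chi-square
difference: the threshold and loading steps pass when
$\Delta RMSEA \le 0.01$ *and* $\Delta CFI \ge -0.004$; the intercept step
uses the stricter $\Delta CFI \ge -0.002$ alone. On failure, a greedy search
frees one item at a time — each candidate is refit, not approximated — and
keeps the item that most improves the step's decision margin (the minimum
slack across the rule's components), ties broken by item index. Partial
invariance is accepted only if at most half the items (3 of 6 by default)
must be released; otherwise the step is declared noninvariant and the ladder
stops.

Two practical notes. First, the refit guarantee applies to the fit function:
releasing a parameter can never worsen $F$. CFI itself can tick down by a
fraction of a point when an *irrelevant* parameter is freed, because the
model loses degrees of freedom faster than misfit; this is why candidates
are ranked by decision margin rather than by raw CFI. Second, a score-based
preselection would be cheaper, but refits are what the decisions are made
from, so the search is refit-based throughout.

## Effect size of noninvariance

For an item with different parameters in a focal and a reference group, the
observed-score impact is

$$d_{MACS} = \frac{1}{SD_{pooled}}\sqrt{\int \big(E_F[Y|\eta] -
E_R[Y|\eta]\big)^2\, N(\eta; \kappa_R, \phi_R)\, d\eta},$$

with $E[Y|\eta] = \sum_c c\,[\Phi((\tau_c - \nu - \lambda\eta)/\sqrt\theta) -
\Phi((\tau_{c-1} - \nu - \lambda\eta)/\sqrt\theta)]$. The integral is
evaluated by Gauss–Hermite quadrature (50 nodes, with a node-doubling
convergence check at relative tolerance $10^{-4}$). The pooled SD is the
square root of the average of the two groups' model-implied observed item
variances, each computed under its own latent distribution — the cited
definition leaves the denominator open, so this choice is pinned here.
Bands: below 0.20 negligible, 0.20–0.40 small, 0.40–0.70 medium, 0.70+
large. The measure is deliberately asymmetric in reference and focal group
(the reference latent distribution weights the integrand); swapping roles
can change $d$ and the package does not hide that.

## Dimensionality screening

Parallel analysis compares observed eigenvalues of the polychoric (default)
or Pearson correlation matrix against the 95th percentile of eigenvalues
from 200 reference datasets. The reference scheme is column-wise permutation
of the observed responses — it preserves the marginal category
distributions exactly, so the univariate thresholds can be reused across
reference sets; an independent-multinomial scheme is switchable. Retention
counts components sequentially from the first; a first-to-second eigenvalue
ratio above 4 flags essential unidimensionality. Reference-set polychoric
estimation uses a relaxed inner tolerance ($10^{-4}$, no Newton polish):
eigenvalue percentiles are insensitive at that scale.

## Dynamic fit-index cutoffs

Fixed universal cutoffs calibrate badly for ordinal one-factor models, so
cutoffs are simulated from the fitted model itself: Level 0 simulates from
the estimates as-is; Level $k$ adds $k$ omitted residual correlations of
magnitude 0.3 between the lowest-index unmodeled pairs while the unmodified
model is fit to each replication. Cutoffs are the 5th percentile of CFI and
95th percentiles of RMSEA and SRMR per level; the downstream rule is
"observed index within the Level-1 cutoff". Because finite-replication
percentiles of adjacent levels can cross even though the misspecification
ladder is monotone in expectation, the cutoff definition applies an isotone
adjustment (running min for CFI, running max for RMSEA/SRMR) across levels.
The misspecification magnitudes are configurable; nothing in the package
promises to reproduce any published cutoff table — cutoffs are conditional
on the data and model by design.

## Trends and counterfactuals

Given (partial) scalar invariance, trends are standardized latent-mean
deviations $(\hat\kappa_g - \hat\kappa_{ref})/\sqrt{\hat\phi_{ref}}$ with
delta-method 95% CIs from the sandwich parameter covariance. Centering on a
different reference group is an exact transformation of the same fit — no
refit — and preserves latent-mean *differences* exactly; the standardized
deviations shift by a constant only when the two reference groups'
estimated latent SDs coincide, since the denominator is deliberately the
reference group's SD (not a pooled one). The freed-versus-fixed
counterfactual fits two otherwise-identical scalar models — noninvariant
parameters freed versus fixed — and reports the per-group trend differences
and their maximum: the practical cost of ignoring the detected
noninvariance. A one-way ANOVA intraclass correlation (truncated at zero,
unbalanced-design average cluster size) quantifies how much clustering the
single-level models ignore.

## The synthetic generator

`popSpec()` / `simulateOrdinal()` generate from exactly the model the CFA
assumes: per group, $\eta \sim N(\kappa_g, \phi_g)$, multivariate normal
residuals with designated correlated pairs, thresholded latent responses,
then MCAR missingness (default 5%, matching the 5–6% item-level missingness
typical of large school surveys; a MAR mode with missingness increasing in
$\eta$ is available but off by default). Defaults emulate a six-item,
four-category depressive-symptom inventory: loadings spread over 0.65–0.86,
right-skewed category distribution (0.55, 0.25, 0.12, 0.08 in the reference
group), one correlated residual pair (items 3–4), groups of 600–6000 formed
by survey-year × gender × age-band grids, reference-group scaling
$\kappa = 0$, $\phi = 1$, $Var(y^*) = 1$. Noninvariance is injected as
location shifts on thresholds, loadings, or latent-response intercepts (an
intercept shift equals an opposite uniform threshold shift; both entry
points exist and the equivalence is tested). One root seed spawns per-group
child streams, so adding a group never perturbs the others.

What the generator does *not* emulate: real sampling frames and privacy
suppression, non-normal latent distributions, category-specific (non-uniform)
threshold DIF, and selection-driven missingness. Passing tests therefore
demonstrate that the pipeline recovers truth *when the model holds* and
detects the injected violations; they do not certify behavior under
misspecifications the generator cannot produce.

## Numerical choices and degenerate inputs

- Empty categories (interior or marginal) are collapsed with the adjacent
  category with a warning by default; a strict mode errors instead. An item
  with all mass in one category is an error naming the item.
- Perfectly associated pairs clip the polychoric estimate at $\pm 0.999$
  with a boundary warning; zero table margins are errors.
- $\phi$ and $\psi$ are optimized on the log scale, so inadmissible
  non-positive variances cannot occur mid-iteration; negative *implied*
  residual variances (Heywood solutions) are flagged with a warning, never
  silently accepted.
- Start values come from sample thresholds and a principal-factor
  decomposition of the average polychoric matrix; ladder steps warm-start
  from the previous accepted step.
- Identification is verified by the column rank of the weighted Jacobian at
  the start values.
- Test and example problem sizes are desk-scale by choice: groups of
  600–2000, 100–200 replications for stochastic checks — large enough for
  the asymptotics the methods rely on, small enough to run routinely.

## Limitations

One factor only, delta parameterization only, no full-information maximum
likelihood, no alignment or Bayesian approximate invariance, no
age–period–cohort decomposition, and no correction of the fitted models for
cluster sampling (the ICC check quantifies, but does not remove, that
omission).
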