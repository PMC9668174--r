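---
title: "Robust aggregated gene-environment interaction testing with sample splitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust aggregated gene-environment interaction testing with sample splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritss)
```

## The problem

Single-variant gene-environment (G×E) interaction tests are chronically
underpowered: realistic interaction effects are small, and genome-wide
multiplicity eats what little signal there is. Aggregating many weak
variant-by-exposure products into one *interaction score*
$U_i = \sum_j \sum_l \pi_{jl} X_{ij} E_{il}$ recovers power, but creates two
new problems. First, the score has to be *learned* from data, and learning
and testing on the same samples invalidates inference. Second, interaction
tests are notoriously sensitive to misspecified main effects: if the model
for the exposure main effect is too rigid (say, linear in pack-years of
smoking when the truth is not), residual main-effect structure leaks into
the interaction statistic and produces false positives, especially when
genotypes and exposures are correlated.

This package implements a testing framework that addresses both problems at
once, for a quantitative trait $Y_i$ observed with a dosage matrix
$X_i \in [0,2]^m$, exposures $E_i \in \mathbb{R}^d$ and covariates
$Z_i \in \mathbb{R}^p$, under the working model

$$Y_i = \mu(E_i, Z_i) + \sum_{j=1}^m \pi_j(E_i, Z_i)\, X_{ij} + \varepsilon_i,
\qquad E[\varepsilon_i \mid X_i, E_i, Z_i] = 0,$$

with the null hypothesis that each $\pi_j$ depends on $Z_i$ only (no
variant-by-exposure interaction). The implementation assumes additive,
$Z$-free genetic main effects under the null, $\pi_{0j}(Z_i)=\pi_{0j}$,
which is also how the simulation studies are generated.

## The cross-fitting layout

The samples are split into $K$ test folds $I_1,\dots,I_K$ of near-equal
size (`split_config()`, default $K=4$). Each fold's complement is further
partitioned into three disjoint parts according to fractions
$c=(c_1,c_2,c_3)$, default $(1/3,1/3,1/3)$:

* **C1 — screening.** A screening strategy proposes up to two candidate
  interaction scores for a chosen exposure $E_{\cdot t}$.
* **C2 — combination.** The candidates enter a flexible main-effect model
  as linear predictors; the second score is retained only if its
  coefficient p-value is below 0.05 (the $c_2$ gate), and the combined
  score is $U = U_1 + c_2 U_2$. The main-effect model fitted here is kept
  and later residualizes the fold's test samples.
* **C3 — orthogonalization.** The combined score is transformed to
  $U' = U - \hat f(E,Z) - X'\hat\gamma$, estimated by alternating
  conditional fits so that $U'$ has (numerically) zero sample covariance
  with every main-effect basis column and every genotype column.

On the held-out fold, $T_k = \sum_{i \in I_k} \hat U'_i \hat Y^{resid}_i$
and $\hat\sigma^2_k = \sum_{i \in I_k} (\hat U'_i \hat Y^{resid}_i)^2$ are
accumulated, and the overall statistic is
$z = \sum_k T_k / \sqrt{\sum_k \hat\sigma^2_k}$, asymptotically standard
normal under the null; we report the two-sided p-value
$2(1-\Phi(|z|))$ (the reference distribution is symmetric and the
alternative is magnitude-agnostic, so two-sided is the natural choice).
Every sample sits in exactly one test fold, so each contributes exactly
once to the statistic. Because screening, model fitting, and evaluation
never share samples, *any* screening procedure yields a valid test; the
orthogonalization makes the statistic additionally insensitive to
first-order main-effect estimation error, which is what rescues validity
when $\mu$ is hard to estimate and $X$ and $E$ are correlated.

The splitting fractions trade screening power ($c_1$) against the accuracy
of the nuisance fits ($c_2$, $c_3$); the equal split is the default
because it gave the most stable small-sample calibration in our studies,
and $K=4$ slightly outperforms $K=3$ in power since more of the sample is
screened. Complement parts are sized by largest-remainder apportionment
with remainder ties resolved toward the lower part index — the
deterministic rule matters only for exact reproducibility of seeded runs.

## Screening strategies

**Strategy 1 (risk-score subcomponents).** An all-linear working model
$Y = \mu_0 + E'\mu_1 + Z'\mu_2 + X'\pi_0$ fitted on C1 provides risk-score
weights $\hat\pi_0$. C1 is then split in half; each half ranks variants by
the absolute single-variant statistic of the weighted product
$\hat\pi_{0j} X_{ij} E_{it}$ and, over subset sizes
$\{10, 15, 20, \dots, m\}$, the top-$s$ weighted score is evaluated in the
*other* half, keeping the size with the largest squared interaction
z-statistic. $U_1$ aggregates the variants selected by both halves,
$U_2$ those selected by exactly one, both with weights $\hat\pi_{0j}$.
Cross-evaluated ranking is our approximation to best-subset selection; the
exact subset search is combinatorial and unnecessary here, since the gate
and the robust statistic tolerate imperfect screens.

**Strategy 2 (aggregated single-variant scan).** Per variant, the model
$Y = \mu_0 + E'\mu_1 + Z'\mu_2 + X_j\pi_{0j} + E_t X_j \pi_{jt}$ yields an
interaction p-value; Benjamini-Hochberg q-values group variants into
$U_1$ ($q \le 0.05$) and $U_2$ ($0.05 < q \le 0.2$), weighted by
$\hat\pi_{jt}$.

$U_1$ always additionally retains at least the single best-ranked variant
(`min_keep = 1`). This is a deliberate design choice: with hard
thresholds, a complete null frequently leaves *every* fold with an empty
score, the overall statistic degenerates to $0/0$, and the reported
p-value collapses to a point mass at 1 — the null p-value distribution is
then visibly non-uniform even though the test is conservative. Retaining
the top candidate costs nothing in validity (the statistic is valid for
any screen output) and restores the continuous, uniform null distribution
that the asymptotic theory promises. Setting `min_keep = 0` recovers hard
thresholding.

The single-variant statistics in both strategies are computed by exact
Frisch-Waugh updates against the QR factorization of the shared base
design, which is algebraically identical to refitting the full model per
variant and roughly two orders of magnitude faster.

## Main effects and the ACE orthogonalization

All "flexible" fits use the same additive basis: an unpenalized cubic
regression spline with 5 basis functions (`spline_df`) per continuous
exposure/covariate column, a linear term per binary column (detected as
$\le 2$ distinct values), and a linear additive term per genotype column.
Unpenalized bases keep every fit an ordinary least-squares problem —
deterministic, fast, and exactly reproducible — at the price of a fixed
basis dimension; `spline_df = 1` degrades every term to linear. Tensor
interactions between exposures and covariates are deliberately out of
scope; the basis dimension must stay small relative to the part sizes
(the fitter enforces a 5:1 observation:column margin). Rank-deficient
designs drop aliased columns with a warning; collinear candidate scores
are an error because the $c_2$ gate would be meaningless.

The orthogonalization alternates two conditional least-squares fits — the
smooth $(E, Z)$ block and the (column-centered) genotype block — until the
maximum coefficient change falls below `tol = 1e-10` *and* the residual's
covariance with every design column is below $10^{-8}$ times the column
scale, or `max_iter = 100`. Both blocks are linear in their coefficients,
so the fixed point coincides with the joint least-squares projection of
$U$ on the stacked design; the alternating form is kept because it
mirrors the conditional-expectation formulation and the per-block
structure (smooth vs genetic) of the problem. Centering the genotype
block removes its overlap with the intercept, which otherwise slows the
alternation badly. A score with zero variance on C3 short-circuits to the
identity-zero model: the fold then contributes exactly $(0, 0)$ and the
sample accounting stays intact. If every fold is degenerate, the result
carries $z = 0$, $p = 1$ and a degeneracy flag rather than an error.

The residualization model for the test fold is the main-effect part of
the C2 fit. The alternative — a dedicated refit on C2 ∪ C3 — would leak
the orthogonalization samples into the residualizer; C2 is the only part
where $\hat\mu$ and $\hat\pi_0$ are estimated flexibly, so it is the
natural (and our fixed) choice.

## Comparators

`gamsv_test()` is the single-variant scan with spline exposure main
effects (same basis family), summarized by the Bonferroni-corrected
minimum p-value. `nonrobust_test()` (D1/D2) runs the identical pipeline
but tests with the raw score $U$ instead of $U'$ — it exists to
demonstrate what the orthogonalization buys. GESAT, a published
variance-component test, is not reimplemented; externally computed GESAT
p-values can be compared side by side in study tables.

## The synthetic-data generator

`simulate_null()` generates the five null scenarios: per-variant allele
frequencies uniform on `maf_range` (default 0.05–0.5) with Hardy-Weinberg
dosages; exposures jointly Gaussian with exchangeable correlation 0.3;
two standard-normal covariates; genetic effects $\pi_{0j} \sim N(0,
0.15^2)$; linear exposure/covariate main effects 0.3/0.2. The scenario
modifiers are explicit parameters: the nonlinear exposure effect
($0.5 E_1^2 + 0.5\sin 2E_1$, scenarios 2–5), heteroscedastic non-normal
errors ($(1+|E_1|/2)$ times a centered, scaled $\chi^2_4$, scenarios 3
and 5), and gene-environment correlation ($E_1$ gains 0.3 times the
standardized dosage sum of the designated leading 10% of variants,
scenarios 4 and 5). With `select = TRUE` a pool of `m_pool` variants is
simulated and the `m` with the smallest marginal association p-values in
the *same* data are kept, emulating GWAS-based variant selection.
`simulate_power()` plants interactions on scenario 1: each variant
interacts with $E_1$ independently with probability `p_XE`, with effect
$\delta_j = \pi_{0j}\beta_j$, $\beta_j \sim N(\mu_{XE}, \sigma_{XE}^2)$,
so the planted architecture is a risk-score subcomponent — exactly what
strategy 1 is built to find; `weighted = FALSE` unties the effects from
the risk-score weights.

The generator emulates independent samples with clean dosages and
error-free exposures. It does not emulate linkage disequilibrium,
population stratification, relatedness, exposure measurement error, or
ascertainment — so calibrated tests here say nothing about confounding
through those channels in real data; they validate the statistic's
behavior under the stated sampling model only.

## Problem sizes and study defaults

The packaged studies run at a desk scale chosen so the full suite
completes on a single CPU in minutes: $n = 3000$, $m = 50$, $d = 5$,
$p = 2$, $K = 4$, $c = (1/3, 1/3, 1/3)$, 200 replicates, with calibration
asserted through exact binomial confidence bounds and
Kolmogorov-Smirnov uniformity rather than exact rates. The default
$\mu_{XE} = 0.25$, $\sigma_{XE} = 0.1$ in `power_config()` was fixed once
by a coarse calibration so the strategy-1 test has intermediate
(roughly 50%) power at density $p_{XE} = 0.4$ at this $n$ — intermediate
power is where the strategy-1 vs strategy-2 ordering is informative.
Reference-scale analyses ($n$ in the tens of thousands, $m$ of order
$10^2$–$10^3$, thousands of replicates) are supported by the same
configuration objects; the method genuinely targets biobank-scale data,
and at small $n$ the nuisance fits are noisy enough that mild
finite-sample inflation of the z-score variance is expected.

## Worked example

```{r example, eval = FALSE}
coh <- simulate_null(scenario_config(n = 3000, m = 50, seed = 42))
fit <- ritss(coh, env_index = 1, strategy = 1,
             config = split_config(K = 4, seed = 7))
summary(fit)

# a small null study with QQ coordinates and rejection rates
study <- run_study(
  list(ritss1 = function(c) ritss(c, 1, 1, split_config(K = 4, seed = 1))$p_value),
  null_generator(scenario_config(n = 3000, m = 50)),
  n_reps = 50, seed = 2024)
study$rejection
```

## Limitations

* The variant set must be pre-selected and of moderate size
  ($m \ll n$); the 5:1 fit-size margin is a hard floor.
* Binary exposures are detected, but dedicated dichotomous-trait
  extensions (binary $Y$) are out of scope.
* A significant aggregated score does not localize which of its terms
  truly interact; the $m_4$/$m_3$ overlap sets are a fine-mapping
  heuristic, not an inference.
* Missing data are handled by complete-case deletion at load time; no
  imputation is attempted.
* The exact subset-search and q-band constants are package choices among
  reasonable instantiations of the screening ideas; both are parameters,
  and conclusions that depend on them should be checked across settings.
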