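---
title: "Fast score tests for case-control GWAS with missing genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast score tests for case-control GWAS with missing genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globalscore)
```

## The problem

A genome-wide association scan for a binary trait fits, at every SNP, the
logistic regression

$$\operatorname{logit} \Pr(Y_i = 1) = \beta_0 + \beta_e E_i + \beta_g G_i,$$

with $Y_i$ case/control status, $E_i$ adjustment covariates and $G_i$ the
additively coded genotype (0/1/2 copies of the effect allele), and tests
$H_0\!: \beta_g = 0$. Wald and likelihood-ratio tests need an iterative
full-model fit per SNP. The Rao score test needs only the *null* fit —
and because the null model contains no genotype, that fit is the *same*
for every SNP. With complete data one global Newton–Raphson fit services
a million markers.

Missing genotype calls break this: the conventional score test (CST)
performs a complete-case analysis, excluding individuals missing at the
tested SNP, and since the missingness pattern differs across loci the
null model must be refit per SNP — the computational advantage of the
score test evaporates. This package implements two score tests that keep
a *single global null fit* regardless of missingness, together with the
conventional comparators, a PLINK-format scanner, and a Monte-Carlo
laboratory for validating their operating characteristics.

## The statistics

Write $X_1 = (1, E)$, $X_2$ for the tested genotype columns ($G$, or
$(G, G\!\cdot\!E)$ for the joint 2-df gene–environment test),
$\theta_1 = (\beta_0, \beta_e)$, and let $I_i \in \{0,1\}$ indicate an
observed genotype. Per-individual scores at a null value $\theta_1$ are
$u_{1i} = X_{1i}(y_i - \pi_i)$ and $u_{2i} = X_{2i}(y_i - \pi_i)$ with
$\pi_i = \operatorname{expit}(X_{1i}\theta_1)$; weighted cross products
$S_{jk} = \sum_i I_i\, w_i X_{ji} X_{ki}^{\!\top}$, $w_i = \pi_i(1-\pi_i)$,
are the "missing-weighted" information blocks (superscript-$m$ algebra).
$S^f_{11}$ denotes the full-sample nuisance block (no $I_i$).

* **CST** — refit $\check\theta_1^m$ on the complete cases of the SNP;
  $$S_\mathrm{CST} = U^{\top} C^{-1} U,\qquad
    U = \sum_i I_i u_{2i}(\check\theta_1^m),\quad
    C = S_{22} - S_{21} S_{11}^{-1} S_{12}.$$
* **PM1** — keep the global fit $\check\theta_1^f$ (all $n$ individuals,
  genotype-free) and use
  $C_f = S_{22} - S_{21} (S^f_{11})^{-1} S_{12}$, all score terms at
  $\check\theta_1^f$. The *full-sample* middle block is what makes PM1
  cheap, but it inflates the variance under missingness: PM1 is
  asymptotically less powerful than CST.
* **PM2** — efficient-score correction. Each individual's genotype score
  is orthogonalized against the nuisance score,
  $$u^*_{2i} = I_i u_{2i} - S_{21} S_{11}^{-1} I_i u_{1i}
    \quad\text{at } \check\theta_1^f,$$
  and $S_\mathrm{PM2} = (\sum_i u^*_{2i})^{\top} C^{-1} (\sum_i u^*_{2i})$
  with the same complete-case-form $C$ as CST (all blocks at
  $\check\theta_1^f$). The projection removes exactly the term that the
  global fit fails to zero out ($\sum_i I_i u_{1i}(\check\theta_1^f) \ne 0$
  when genotypes are missing), making PM2 asymptotically equivalent to
  CST while still requiring only the one global fit.

All statistics are referred to a $\chi^2$ distribution with
$\mathrm{df} = \mathrm{ncol}(X_2)$. Wald, likelihood-ratio and a
median-imputation score test (missing codes replaced by the observed
median, rounded onto the 0/1/2 lattice) are provided as comparators.

Two formulation details are worth recording:

* The literature's scaled form carries $1/n$ factors in the blocks and
  $1/\sqrt{n}$ in the summed scores; these cancel inside every quadratic
  form, so the implementation works with unnormalized sums throughout.
  A unit test assembles the scaled formula independently and confirms the
  cancellation.
* The variance of PM2 is stated against the complete-case-form $V_m$,
  which is elsewhere defined at the complete-case refit
  $\check\theta_1^m$. Recomputing $\check\theta_1^m$ would defeat PM2's
  purpose, so all its blocks are evaluated at $\check\theta_1^f$,
  consistent with the efficient-score construction. This choice is
  isolated in `pm2_test()` and validated empirically by the PM2–CST
  concordance and calibration tests.

## Numerical choices

* **Newton–Raphson** initialized at zero; convergence when
  $\lVert \text{score} \rVert_\infty \le 10^{-8}$; at most 50 iterations;
  step-halving when a step would decrease the log-likelihood. These are
  conventions (the method itself does not prescribe them) and are
  arguments of `fit_logistic_mle()`.
* **Polish step.** After the score-norm criterion fires, one extra Newton
  step is taken. Quadratic convergence drives the score from the $10^{-8}$
  tolerance to near machine precision, which is what lets the exact
  no-missing identity CST = PM1 = PM2 hold to $10^{-10}$ in floating
  point rather than merely to the fitting tolerance.
* **Separation.** A vanishing score cannot distinguish an interior MLE
  from quasi-complete separation (where coefficients diverge while fitted
  probabilities saturate), so fits whose coefficients exceed 20 in
  absolute value are flagged as separated and surfaced as
  `not_converged` test results, never as silent numbers.
* Fitted probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside
  the likelihood so rounding can never produce $-\infty$.
* Monomorphic-in-observed SNPs and singular variance blocks yield typed
  statuses (`monomorphic`, `degenerate_variance`); a genome scan records
  them per row and continues.

## A deliberate asymmetry, and its price

PM1's variance uses missing-weighted outer blocks around the full-sample
nuisance information. That asymmetry is intentional — it is what the
single-fit shortcut gives you without the efficient-score correction —
but it has a consequence worth knowing: PM1's statistic is **not
invariant to which allele is counted** when genotypes are missing.
Recoding $G \to 2 - G$ adds a multiple of the intercept column to $X_2$;
CST and PM2 are exact projections with respect to a single weighted inner
product, so the added component is annihilated and their statistics are
unchanged (the same holds for Wald, LRT and median imputation). PM1's
mixed-block quadratic form is not a projection, and the statistic changes
with the coding (the difference vanishes as the missing rate goes to 0 and
is asymptotically null-irrelevant, since the formula remains correctly
calibrated for either coding). The test suite pins the invariance of the
other five tests and documents PM1's exception; if coding-stable fast
p-values are needed, use PM2.

## The simulation laboratory

The generator emulates a retrospective case-control study of a rare
disease:

| parameter | default | meaning |
|---|---|---|
| `prevalence` | 0.01 | population disease probability |
| `e_freq` | 0.5 | binary covariate (e.g. sex) frequency |
| `or_e` | 1.2 | covariate odds ratio $e^{\beta_e}$ |
| `maf` | 0.10 / 0.30 (grid) | minor allele frequency, HWE |
| `or_g`, `or_ge` | 1 under the null | per-allele and interaction odds ratios |
| `n_case`, `n_control` | 1,000 or 5,000 | retrospective quotas |
| `missing_rate` | 0.02–0.10 (0.30 exaggerated) | MCAR masking probability |

The intercept $\beta_0$ is solved by monotone root-finding (to $10^{-10}$)
so that the population-averaged case probability over
$E \sim \mathrm{Bern}(0.5)$, $G \sim \mathrm{Bin}(2, \mathrm{maf})$
equals the prevalence. Retrospective sampling is implemented two ways:
literal rejection sampling from the population until the case and control
quotas fill, and the default *conditional* method that draws the six-cell
distribution of $(E, G)$ given $Y$ as a multinomial — the two are
distributionally identical (conditioning on the outcome is exact), and the
conditional form is what makes $2 \times 10^4$-replicate calibration runs
take about a minute instead of hours at 1% prevalence. A test compares the
two samplers' cell counts.

Missingness is MCAR by construction: $I_i \sim \mathrm{Bin}(1, 1-R)$
independent of everything. The generator therefore does **not** emulate
informative missingness (MAR/MNAR), linkage disequilibrium between
markers, population stratification, or genotyping-batch artefacts; a
green calibration here establishes correctness *under the stated model*,
not robustness to those violations.

Each replicate draws its RNG stream from a seed derived from
`(seed, replicate index)`, so replicates are reproducible independently
and the harness is trivially parallelizable. All requested methods run on
the *same* replicates (paired design), which is what makes small power
differences detectable: the power-ordering checks compare methods within
replicate and use the paired standard error of the rejection-indicator
difference.

The harness's fast inner loop (`replicate_pvalues()`) shares the global
null fit and the weighted blocks across methods and skips container
validation; a regression test asserts it reproduces the public
`run_test()` path p-value-for-p-value.

## Scale of the shipped experiments

The reference experiments use $10^6$ null replicates at
$\alpha = 5\times10^{-5}$ (Monte-Carlo SE $0.71\times10^{-5}$, 95%
interval $(3.6, 6.4)\times10^{-5}$) and 1,000 power replicates at
$\alpha = 5\times10^{-8}$. The packaged acceptance tests run the
desk-scale stand-ins: 20,000 calibration replicates at
$\alpha \in \{0.05, 10^{-3}\}$ per grid corner (two corners, one per df),
judged against exact binomial 99% intervals, and 1,000 power replicates
per sweep point at 30% missingness — the setting deliberately exaggerated
to make the PM1 power deficit visible. Full-replicate runs are available
through the `simulate` CLI (`--reps 1000000`); at roughly 3 ms per
replicate expect hours per grid corner on one CPU.

## Known limitations

* Covariate or phenotype missingness is rejected at load time, not
  modelled; complete-case exclusion happens once, before the global fit.
* MCAR is assumed everywhere; under informative missingness the
  complete-case score algebra (and hence all three tests) can be biased.
* No small-sample corrections: at 100 cases/100 controls the tests run
  slightly conservative, consistent with the asymptotic theory.
* PM1's allele-coding dependence under missingness, discussed above.
* X-chromosome coding, dosage input and relatedness filtering are out of
  scope; principal-component covariates are supported simply as columns
  of `E`.
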