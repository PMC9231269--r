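---
title: "Methods: two-sample univariable and multivariable MR for metabolic trait prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample univariable and multivariable MR for metabolic trait prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

## The problem and the model

Metabolomics platforms quantify hundreds of correlated circulating traits.
Observational associations between such traits and a downstream outcome are
confounded; Mendelian randomisation (MR) instead uses genetic variants as
instruments: a SNP that robustly shifts an exposure, and affects the outcome
only through that exposure, identifies the causal effect.

With summary statistics from two (possibly overlapping) GWAS samples, each
instrument $j$ contributes an estimated SNP–exposure effect
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and SNP–outcome effect $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$), both in SD units. The single-instrument estimate is the
Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
SE $\sigma_{Yj}/|\hat\beta_{Xj}|$. With $K$ instruments the
inverse-variance-weighted (IVW) estimate is the weighted regression of
outcome on exposure effects through the origin,

$$\hat\theta = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}\sigma_{Yj}^{-2}}
                    {\sum_j \hat\beta_{Xj}^2\,\sigma_{Yj}^{-2}},$$

with Cochran's $Q$ ($K-1$ df) flagging heterogeneity among the per-SNP
ratios. For $K_E$ correlated exposures jointly, the multivariable (MVMR)
estimator regresses $\hat\beta_{Yj}$ on the $L \times K_E$ matrix of
exposure effects (weights $\sigma_{Yj}^{-2}$, no intercept), estimating each
exposure's *direct* effect; its heterogeneity $Q$ carries $L - K_E - 1$
degrees of freedom.

The package implements this workflow end to end — trait-panel reduction,
instrument selection, harmonisation, univariable screening, multivariable
estimation, pleiotropy-robust estimators — plus a synthetic
summary-statistics generator with known ground truth used by every test.

## Workflow stages and the parameters that matter

1. **Panel reduction.** Derived ratios and composite measures are excluded
   (`is_ratio`/`is_composite` metadata flags), lipoprotein panels are
   reduced to one total-lipids measure per subclass
   (`lipoprotein_role` metadata), and one member of any pair with squared
   genetic correlation above `rg2_prune = 0.985` is removed. Nearly
   genetically identical traits cannot be separated in a joint model
   (multicollinearity), so pruning happens before estimation. Which member
   of a pair is dropped is decided by a deterministic priority list (default:
   input order); the source method leaves this unspecified, and determinism
   was preferred over any data-driven rule.
2. **Instrument selection.** Per trait: genome-wide significance
   `p_instrument = 5e-8`, then greedy LD clumping at `r2_clump = 0.01`
   (best p first, ties broken by SNP id). LD is taken entirely from a
   supplied r matrix — no physical-distance window, since the r² rule is the
   binding constraint when r is supplied directly. A *selection* GWAS may
   differ from the *effect* GWAS (two-source design): SNPs chosen in one
   sample, effect sizes extracted from another, which avoids winner's-curse
   bias when the exposure and outcome samples overlap.
3. **Harmonisation.** Outcome effects are aligned to the exposure's effect
   allele; swapped alleles negate the outcome beta, opposite-strand reports
   are complemented first. Palindromic SNPs (A/T, C/G) are unresolvable by
   letters: with minor-allele frequency above `maf_palindrome = 0.42` on
   either side they are removed as ambiguous; below that, strand is inferred
   by requiring the two allele frequencies to sit on the same side of 0.5,
   flipping the outcome effect on disagreement (frequency is used to *infer*
   strand, not as a second removal filter). Both sides are checked against
   the 0.42 limit — the conservative reading where the rule's side is
   unstated. Exposure effect signs are never altered.
4. **Univariable screen.** Wald ratio for one instrument, IVW otherwise;
   traits with no instruments are reported as missing, never dropped
   silently. Mean F $= \mathrm{mean}_j(\hat\beta_{Xj}/\sigma_{Xj})^2$
   measures instrument strength; leave-one-out refits flag single-SNP
   dependence. Traits with $p <$ `p_screen = 0.05` become MVMR candidates.
5. **Multivariable model.** Candidate instruments are pooled and re-clumped
   across traits at r² < 0.01 ranked by minimum p-value, so no retained
   instrument for one trait is in LD with any other's; effects for every
   retained SNP are looked up in every candidate's table, re-aligned to a
   single reference allele, and harmonised to the outcome. Direct effects by
   weighted least squares; conditional F per exposure (below); Q with
   $L-K_E-1$ df.
6. **Pleiotropy-robust estimators** on candidates with at least three
   instruments: MR-Egger, weighted median, weighted mode (details below).

## Standard-error convention

The IVW, Egger and MVMR standard errors use one convention everywhere:
the fixed-effect (unit residual scale) SE inflated by the residual standard
deviation when the fit is overdispersed, and never deflated
(`capped_multiplicative`; residual scale bounded below by 1). A pure
fixed-effect mode is exposed for calibration work — under a correctly
specified null the fixed-effect z-test is exactly nominal, while the capped
convention is deliberately conservative (its rejection rate can only be at
or below nominal). All 95% intervals use normal quantiles
($\pm 1.959964\,SE$), including Egger — no small-sample t correction, one
documented convention throughout.

## Conditional instrument strength in MVMR

Weak-instrument bias in MVMR depends on each exposure's strength
*conditional on the others*. For exposure $k$, the package minimises

$$Q_{x,k}(\delta) = \sum_j \frac{\big(\hat\beta_{jk} -
\delta^\top \hat\beta_{j,-k}\big)^2}{v_j(\delta)},\qquad
v_j(\delta) = \sigma_{jk}^2
  + \sum_{l,m\neq k}\delta_l\delta_m\rho_{lm}\sigma_{jl}\sigma_{jm}
  - 2\sum_{l\neq k}\delta_l\rho_{kl}\sigma_{jk}\sigma_{jl},$$

where the covariances between a SNP's effect estimates on different
exposures are approximated as $\rho_{lm}\sigma_{jl}\sigma_{jm}$ from a
phenotypic correlation matrix $\rho$ (supplied, or identity with a loud
warning). The minimisation iterates weighted least squares with the weights
held fixed (fixed-point tolerance $10^{-8}$, at most 100 iterations;
non-convergence and non-positive $v_j$ are hard errors). Conditional
F $= Q_{x,k}(\hat\delta)/(L - K_E + 1)$; the divisor is chosen so the
single-exposure case reduces *exactly* to the mean F-statistic — the
consistency anchor adopted where the literature defers the constant. Values
above 10 conventionally indicate adequate conditional strength.

Two numerical notes. First, $Q_{x,k}(\delta)$ is not coercive: as
$|\delta|\to\infty$ it tends to the companion exposures' total strength, so
an unconstrained global minimiser can drift to extreme $\delta$ where the
variance term deflates the criterion. The iterated-WLS fixed point is the
intended estimator; it coincides with the interior minimum whenever the
weights vary weakly with $\delta$ (weakly-overlapping exposures), which is
the regime the diagnostic is meant for. Second, exposures that are near
copies with $\rho \approx 1$ drive $v_j$ to zero — the package raises an
"invalid covariance approximation" error, which in practice means the
genetic-correlation pruning stage should have removed one of the pair.

## Pleiotropy-robust estimators

- **MR-Egger**: records are oriented so $\hat\beta_{Xj} \ge 0$ (negating
  both effects together, which leaves the causal slope invariant and makes
  the intercept well defined), then outcome effects are regressed on
  exposure effects *with* an intercept. The slope is consistent under the
  INSIDE assumption; the intercept estimates average directional pleiotropy.
- **Weighted median**: per-SNP ratios with first-order inverse-variance
  weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$; the estimate linearly
  interpolates the ratio at cumulative standardised weight 0.5 (with equal
  weights this is exactly the sample median). Consistent when at least half
  the weight comes from valid instruments.
- **Weighted mode**: maximiser of the weighted Gaussian kernel density of
  the ratios, bandwidth $h = \phi \cdot 0.9\min(SD, MAD)\,K^{-1/5}$ (MAD
  with the 1.4826 consistency constant; $\phi = 1$ by default). The argmax
  is located on a 512-point grid spanning the ratio range extended by $3h$,
  then refined by golden section — fully deterministic. All ratios identical
  is a degenerate bandwidth; the common ratio is returned.

Median and mode SEs come from a seeded *parametric* bootstrap (effects
redrawn from normals centred on the observed values, 1000 replicates by
default): with the small instrument counts typical per metabolite,
resampling SNPs nonparametrically is unstable. The same seed always
reproduces the same SE.

## The synthetic-data generator

Summary statistics are generated directly — no individual-level genotypes —
because the pipeline consumes only summary data and direct generation gives
exact control of instrument strength and overlap correlation. For
unit-variance traits, a per-allele effect estimated in $n$ samples at
minor-allele frequency $f$ has sampling SD $1/\sqrt{n \cdot 2f(1-f)}$. True
SNP–outcome effects are $\gamma_j = \Gamma_j^\top\theta + \alpha_j$
($\Gamma$ the SNP–exposure effect matrix, $\theta$ the causal effects,
$\alpha$ direct/pleiotropic effects). Within a SNP, sampling errors across
exposures are correlated via the phenotypic matrix $\rho$; the
exposure–outcome error correlation is `overlap_fraction` times the implied
phenotypic exposure–outcome correlation — a first-order model of shared
GWAS samples, sufficient to demonstrate (not precisely quantify) overlap
bias. Optional LD blocks give marginal effects $R\gamma$ and correlated
errors (separable SNP x trait covariance).

Defaults mirror the study conditions the workflow targets: exposure GWAS
n = 115,078, outcome GWAS n = 210,267, 30% sample overlap, minor-allele
frequencies uniform on [0.05, 0.5], genome-wide threshold 5e-8.

`make_metabolomics_panel()` builds the reference scenario used by the analysis
scripts and the acceptance script: 12 analysable traits — a glycolysis-like
trait with effect 0.30, amino-acid-like traits with 0.09 and 0.14, nine null
traits including a near-duplicate pair (rg² > 0.985, exercising pruning) and
one trait with no genome-wide-significant SNPs (exercising the
zero-instrument path) — plus a ratio-flagged trait and a within-subclass
lipoprotein component so the metadata filters operate, and palindromic SNPs
with minor-allele frequencies straddling 0.42. Per-SNP effects are 0.05 SD
per allele with 12 instruments per instrumented trait: a power calculation
at these sample sizes gives the weakest causal effect (0.09) a univariable
z of about 4.5, i.e. >99% probability of passing the 0.05 screen, so the
panel's causal traits are recoverable by design.

What the generator does *not* emulate: individual-genotype artefacts
(call-rate, imputation quality), allele-frequency differences between
samples, non-normal effect distributions, population stratification, and
winner's-curse selection (instruments are selected and estimated in the same
simulated exposure GWAS unless a two-source configuration is used). Passing
tests therefore validate the estimators and the pipeline logic under the
stated statistical model, not robustness to those artefacts.

## Calibration checks and problem sizes

The test suite verifies, at fixed seeds: IVW and MVMR-IVW against
independent normal-equation oracles (100 random fixtures, $10^{-10}$
relative error); exact estimator reductions (MVMR at $K_E=1$ = IVW,
conditional F at $K_E=1$ = mean F, equal-weight weighted median = sample
median, Egger on exact lines); parameter recovery at the target effect
scale $\theta = (0.29, 0.07, 0.08)$ with 60 instruments over 500
replicates (bias < 0.02, 95% CI coverage within [92%, 98%]); null
calibration of the fixed-effect IVW test and of the MVMR Q over 1000
replicates each (rejection 0.05 ± 0.015; the Q calibration uses 300
instruments, where the $L-K_E-1$ df rule implies a true rate of 0.054);
Egger-vs-IVW bias ordering under directional pleiotropy (500 replicates);
clumping, pruning and harmonisation against brute-force enumeration; and
byte-identical pipeline reruns under one seed. The Q-calibration scenario
sets all causal effects to zero: with nonzero effects the residuals
$\hat\beta_{Yj} - \theta^\top\hat\beta_{Xj}$ contain exposure measurement
error, a genuine (NOME-type) mis-specification of the Q model that inflates
rejection and is not a calibration failure.

## Known limitations

- The genetic-correlation estimator (weighted Pearson correlation of
  effect estimates over the instrument union) is a pragmatic summary-level
  stand-in; a correlation matrix from dedicated machinery (e.g. LD-score
  regression) can be supplied instead and is preferred when available.
- The conditional-F normalising constant and the behaviour of its
  $Q_x$ minimisation for strongly-overlapping exposures follow the
  consistency anchor above rather than a published closed form.
- The sample-overlap model is first-order; it reproduces the direction and
  rough size of overlap-induced correlation, not its exact magnitude.
- No Steiger filtering, MR-PRESSO, MVMR-Egger, or proxy-SNP lookup; the
  workflow deliberately matches the estimator set described above.
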