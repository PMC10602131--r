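---
title: "Screening for gene-environment interaction with summary statistics: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for gene-environment interaction with summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgxe)
```

## The model

Per variant, a genome-wide interaction study (GWIS) fits
$Y = \beta_0 + \beta_1 G + \beta_2 E + \beta_3 G\!\times\!E + \epsilon$ and a
(much larger) GWAS fits the marginal model $Y = \alpha_0 + \alpha G +
\epsilon$. With $\rho$ the mediation contribution of the genotype through
the exposure $E$, the two genotype effects are linked by

$$\hat\alpha \;=\; \theta\,\hat\beta_1 \;+\;
  \frac{\rho\sigma_E}{\sigma_G}\,\hat\beta_2 \;+\;
  \Big(\mu_E + \frac{\rho\sigma_E}{\sigma_G}\Big)\,\hat\beta_3 .$$

Variants with neither interaction nor mediation fall on the line
$\alpha = \theta \beta_1$; the bridging coefficient $\theta$ soaks up
systematic study differences (trait transformation, covariate sets,
structure correction) and equals 1 when the studies are homogeneous. A
variant's departure from the line is formally horizontal pleiotropy once the
polygenic contribution to the trait is treated as a pseudo exposure in a
Mendelian-randomization (MR) analysis, and is tested by

$$T_{MR\_GxE} \;=\;
  \frac{(\hat\alpha - \hat\theta\hat\beta_1)^2}
       {\widehat{\mathrm{var}}(\hat\alpha - \hat\theta\hat\beta_1)}
  \;\sim\; \chi^2_1,
\qquad
\widehat{\mathrm{var}} = s_\alpha^2 + \hat\theta^2 s_{\beta_1}^2
  - 2\hat\theta r s_\alpha s_{\beta_1},$$

where $r$ is the correlation of estimation errors induced by shared
subjects. $T_{MR\_GxE}$ tests the *combined* interaction and mediation
signal; the two-step procedure (screen genome-wide with $T_{MR\_GxE}$, then
apply the direct test $T_{direct}=\hat\beta_3^2/s_{\beta_3}^2$ to survivors
with a survivor-count Bonferroni threshold) targets interaction
specifically.

Assumptions worth keeping in view: effect estimates are asymptotically
normal; instruments are strong (genome-wide significant), mutually
independent after LD pruning, and mostly free of interaction and mediation
(the iterative pleiotropy removal guards the "mostly"); a single genome-wide
$r$ captures the overlap covariance for every variant; and
$\widehat{\mathrm{var}}$ treats $\hat\theta$ as a plug-in constant --- with
hundreds of instruments $\mathrm{var}(\hat\theta)$ is second order, which we
verified by simulation at the scales below.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| instrument p-value threshold | 5e-8 | — | genome-wide significance for strong instruments |
| pruning window / max r² | 500 kb / 0.1 | bp / — | near-independence of instruments |
| genomic-control correction | on, only if λ>1 | — | guard against structure-inflated instrument sets |
| allele-frequency mismatch | 0.15 (0.01 at shared positions) | — | harmonization QC |
| exposure-locus exclusion window | ±500 kb | bp | mitigate mediation through the exposure; the window is our choice (see below) |
| pleiotropy-removal threshold | 0.05/m | — | Bonferroni over the initial m instruments |
| IMRP iterations / tolerance | 10 / 1e-6 | — / θ units | removal stabilizes quickly in practice |
| screen threshold | 5e-8 (genome) or 0.05/m (panels) | — | stage-1 of the two-step procedure |
| locus window / signal r² | 1 Mb / 0.1 | bp / — | locus and independent-signal grouping |
| LDSC weights / intercept / blocks | 1/max(ℓ,1), free, 20 | — | standard heritability-regression conventions |

All are exposed as function arguments and command-line flags.

## What the simulators emulate

The **no-mediation design** generates m = 102 independent variants with
allele frequencies Uniform(0.05, 0.5), genotypes standardized to unit
variance (centered by default), main effects $\beta_{1j}\sim N(0,
\sigma^2_\beta)$, exposure $N(\mu_{E1},1)$ for GWAS-only subjects and
$N(\mu_{E2},1)$ for GWIS/overlap subjects, and phenotype
$Y=\sum_j G_j\beta_{1j} + 0.1E + 0.05\,G_1E + \epsilon$, $\epsilon\sim
N(0,1)$. Variant 1 carries the interaction (power), variant 2 is the
designated null (type-I error), and the last 100 variants are the
instruments. The **mediation-panel design** generates 20 variants with
allele frequency 0.3, standardized *without* centering; the focal variant
has main effect 0.1 and, depending on the model, mediation
($E = 0.05G + N(\mu, 0.9975)$, so the genotype accounts for exactly 0.25% of
$\mathrm{Var}(E)=1$) and/or an interaction of 0.1; the phenotype is
$Y = 0.1G + \gamma E\,(+\,0.1\,G E) + N(0,10)$ with $\gamma \in \{1,5\}$,
and non-overlapping GWAS subjects have their exposure mean scaled by 1.5.
(The generative equations list the exposure mean as 1 in the GWIS cohort; we
follow the explicit model equations where a surrounding sentence says 2, and
expose the mean as a parameter.) "N(0, 10)" is read as variance 10; the
residual variance is configurable.

What these simulations do *not* contain: LD between variants, binary traits,
relatedness, population structure, heterogeneous per-variant sample sizes,
or meta-analytic noise. Passing tests therefore certify the statistical
machinery (calibration, power ordering, estimator behavior) under the ideal
sampling model, not robustness to real-data pathologies; the
genomic-control correction and the bridging coefficient itself are the
run-time guards for those.

Problem sizes in the test suite and acceptance script were chosen to make
every Monte-Carlo comparison resolvable at its stated tolerance: 500--800
replicates at n = 20,000 for estimator means, 2,000 replicates for type-I
rates, 100--200 replicates for bridging-coefficient means.

## The overlap correlation r

On real data, $r$ is estimated once per trait pair as the correlation of
GWAS and GWIS z-scores over null variants (both p > 0.05) across the
genome — a selection that mildly truncates the bivariate normal and
attenuates the estimate, which is acceptable at genome scale. Inside the
replicate studies the panels hold only 20--102 variants, so a per-replicate
estimate would be far noisier than anything used in practice and would
destabilize $\widehat{\mathrm{var}}$. `run_replicates()` therefore estimates
$r$ once per run from a dedicated auxiliary panel of 1,000 null variants
generated under the same cohort, overlap, and exposure design — the
simulation analogue of the genome-wide estimate. Because every auxiliary
variant is null by construction, no p-value filter is applied there (the
filter exists to exclude real signals; on an all-null panel it would only
attenuate $r$). Per-replicate estimation and a fixed $r$ remain available as
options.

## The expectation of the bridging coefficient

With no interaction and no mediation among instruments, standardized
genotypes, and unit residual variance, the IVW slope has expectation (by
Slutsky, at many instruments)

$$E[\hat\theta] \;=\;
  \frac{\sigma_\beta^2 + \mathrm{cov}(\hat\alpha,\hat\beta_1)}
       {\sigma_\beta^2 + \mathrm{var}(\hat\beta_1)} .$$

`expected_theta()` implements two treatments of the numerator. The default
(`form = "covariance"`) uses the exact overlap covariance
$\mathrm{cov}(\hat\alpha,\hat\beta_1) = n_0\,\sigma^2_{sh}/(n_1 n_2)$, with
$\sigma^2_{sh}$ the residual phenotype variance shared by the two fits: in
the interaction model's normal equations the main-effect and interaction
errors are negatively correlated (correlation
$-\mu_E/\sqrt{\mu_E^2+\sigma_E^2}$), and this cancellation makes
$n\,\mathrm{cov}(\hat\alpha,\hat\beta_1) = \sigma^2_{sh}$ exactly for any
exposure mean. The alternative (`form = "independence"`) treats those errors
as uncorrelated, which replaces the factor by $(1+\mu_{E0}^2\sigma_{E0}^2)$.
The two forms coincide with no overlap and in the strong-instrument,
large-sample limit (both converge to 1, and both are bounded by 1 when the
overlap exposure is no more dispersed than the GWIS exposure), but they
differ materially at full overlap with weak instruments: at
$\sigma^2_\beta = 10^{-4}$, $n = 20{,}000$, full overlap, the covariance
form predicts 0.75 while the independence form predicts 1.0, and the
Monte-Carlo mean of $\hat\theta$ is 0.7485 ± 0.004 (150 replicates). We
therefore default to the covariance form and verify it against Monte-Carlo
means in the test suite. For comparisons against generated data the shared
residual variance should include the polygenic background of the other
variants, $\sigma^2_{sh} = \sigma^2 + (m-1)\sigma^2_\beta +
\beta_2^2\sigma_E^2$; the closed form's unit convention is recovered with
`sigma_shared2 = 1`. Because the weak-instrument regime is where the
finite-sample behavior is interesting (and where the closed form's
second-order approximations are smallest relative to Monte-Carlo noise),
the Monte-Carlo comparisons use $\sigma^2_\beta = 10^{-4}$.

## Evaluating type-I error in the panel design

In the two-variant convention of the no-mediation design, power is measured
at variant 1 (the planted interaction) and type-I error at variant 2 (a
zero-effect variant). We carry the same reading into the 20-variant panel:
type-I error is family-wise over the 19 zero-effect variants, and the focal
variant measures power. The distinction matters because the panel design
gives the instruments no real effects, so $\hat\theta$ is badly attenuated
(its expectation is about 0.5 under $\gamma=1$); the focal variant — which
carries a genuine main effect but no interaction or mediation — then sits
off the *estimated* bridging line even though it lies on the true one. That
departure is a property of weak-instrument $\hat\theta$ estimation, not of
the test's calibration on null variants, and on the 19 zero-effect variants
all three procedures hold their family-wise level (the MR screen and the
two-step procedure run conservative there, as two-stage procedures do).

## Numerical choices and degenerate inputs

Closed-form per-variant OLS (vectorized cross-moments, 4×4 Cholesky solves)
is used for the simulators' fits and is tested against `lm()`; singular
per-variant designs are excluded and logged. Chi-square(1) p-values are
upper-tail; the screen errors out if the plugged-in overlap correlation
makes $\widehat{\mathrm{var}}$ non-positive. Greedy LD pruning and locus
assignment process candidates in ascending p order with deterministic
tie-breaks (file order; equidistant variants join the earlier lead).
Duplicate-id matches keep the pair with the smaller frequency difference.
Harmonization is sign-consistent under allele swaps (tested as an
invariant). All replicate seeds derive from one base seed as `seed + index`.
The LDSC jackknife z-score is slightly heavier-tailed than normal (t-like
in the number of blocks, with a mild chi-square skew); at the default 20
blocks about 95% of pure-null panels fall below z = 2, which the calibration
test asserts together with unbiasedness of the slope and agreement of the
jackknife SE with the sampling SD.

## Open design points we fixed

* The exclusion window around exposure-associated loci is not specified by
  the sources for the QC recipe; we use ±500 kb (the pruning window scale)
  and expose it as a flag.
* Effect standardization is z-based ($b = z/\sqrt{n}$, $se = 1/\sqrt{n}$),
  unit-free and consistent with the standardized-genotype convention of the
  theory; it preserves every z-statistic exactly.
* The IMRP schedule (threshold 0.05/m, 10 iterations, tolerance $10^{-6}$)
  is our choice, exposed as parameters; with no pleiotropy it reduces to
  plain IVW after one iteration (tested).
* `theta_hat` SE defaults to model-based weighted least squares; a sandwich
  variant is available.
* The screen threshold switches from 5e-8 to Bonferroni 0.05/m below
  10,000 variants; both are explicit arguments.
* Per-chromosome heritability is totaled over non-negative estimates only,
  at the point-estimate level; the genome-wide single fit is always reported
  alongside.

## Known limitations

The screen detects combined interaction and mediation; only the two-step
procedure, plus exposure-locus exclusion, narrows the claim to interaction.
With very weak instruments $\hat\theta$ is attenuated and the MR-route
interaction estimate inherits a leakage term $\beta_1(1-\hat\theta)/\mu_E$
for variants with fixed non-zero main effects (invisible at n = 20,000 under
the default instrument strength, visible below n ≈ 5,000). The LDSC bound is
a lower bound and assumes the supplied LD scores describe the population of
the residual effects. No liftover, VCF parsing, or imputation-quality
filtering is provided.
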