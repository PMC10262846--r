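---
title: "Two-sample Mendelian randomization with tsmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with tsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, thought of as
a disease liability such as hypothyroidism) on an outcome (such as
rheumatoid arthritis) from GWAS summary statistics alone. A variant $j$ is
a valid instrument if it is (1) associated with the exposure, (2) not
associated with confounders of the exposure–outcome relation, and (3)
affects the outcome only through the exposure.

In the two-sample setting we observe, per variant, the estimated exposure
association $\hat\gamma_j$ with standard error $\sigma_{X j}$ from one
GWAS, and the outcome association $\hat\Gamma_j$ with standard error
$\sigma_{Y j}$ from another. Under the instrumental assumptions with
causal effect $\theta$ (log-odds scale),
$$\hat\Gamma_j \approx \theta\,\gamma_j + \alpha_j + \varepsilon_j,$$
where $\alpha_j$ is the direct (horizontally pleiotropic) effect, zero for
a valid instrument. Every estimator in the package is a different way of
pooling the per-variant Wald ratios $\hat\beta_j = \hat\Gamma_j /
\hat\gamma_j$ under different assumptions on the $\alpha_j$.

## Instrument selection

Instruments are selected from the exposure GWAS by

* genome-wide significance, $p < 5\times 10^{-8}$ (strict inequality);
* greedy LD clumping at $r^2 > 0.01$ within $\pm 5{,}000$ kb of the index
  variant — the window is read as two-sided, matching the semantics of the
  standard clumping tools; ties at equal $p$ break by chromosome, position,
  then variant id, so the output is independent of input row order;
* instrument strength: per-variant explained variance
  $$R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
  {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
   2\,\mathrm{EAF}(1-\mathrm{EAF})N\,\mathrm{SE}(\beta)^2},$$
  and $F = R^2 (N-2)/(1-R^2)$, retaining variants with $F > 10$. The same
  $F$ formula applied to the cumulative $R^2$ of a set gives the set-level
  strength. Records with missing allele frequency are dropped from this
  filter explicitly — never imputed.

Harmonization aligns outcome effects to the exposure's effect allele:
swapped alleles negate the outcome beta and complement its frequency;
strand flips are resolved by complementing; palindromic (A/T, C/G)
variants, whose strand cannot be determined from the alleles, are retained
only when both studies' allele frequencies lie on the same side of 0.5 and
both minor-allele frequencies fall below 0.3 (the common
palindrome-inference convention), and are otherwise dropped as
ambiguous. Instruments absent from the outcome may be
replaced by a proxy with $r^2 \ge 0.8$ supplied through a lookup table; no
live LD service is queried. Every instrument is accounted for in the audit
(retained + ambiguous + missing + incompatible = input).

## The five estimators

* **IVW (fixed effect)** pools ratios with weights $w_j =
  \hat\gamma_j^2/\sigma_{Y j}^2$ — first-order weights that ignore
  exposure-side uncertainty, the standard two-sample convention. This
  equals weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through
  the origin. The multiplicative-random-effects variant inflates the SE by
  $\max(1, \sqrt{Q/(J-1)})$, never below the fixed-effect SE, and is added
  to the suite when Cochran's Q is significant.
* **MR-Egger** frees the intercept in that regression (after orienting all
  exposure effects non-negative); the slope estimates $\theta$ under
  InSIDE, the intercept the average directional pleiotropy. SEs are scaled
  by $\max(1, \sqrt{Q_{egger}/(J-2)})$ and p-values use $t_{J-2}$ — the
  reference distributions are our choice, as none is stated in the
  convention we follow for the point estimates.
* **Weighted median**: ratios sorted, cumulative midpoint weights
  $s_j = \sum_{k<j} w_k + w_j/2$ with normalized weights, linear
  interpolation at 0.5; consistent if valid instruments carry at least
  half the weight.
* **Simple and weighted mode**: the argmax of a Gaussian kernel density of
  the ratios (uniform or inverse-variance weights) on a 512-point grid
  spanning $[\min - h, \max + h]$, with the modified Silverman bandwidth
  $h = \phi\, 0.9 \min(\mathrm{sd}, \mathrm{MAD})\, J^{-1/5}$, $\phi = 1$
  by default. If the bandwidth degenerates (identical ratios) the
  estimate is the ratio value carrying the most weight.

Bootstrap SEs for the median and modes use 1,000 parametric replicates
(effect pairs resampled from normals at their observed values); the SE is
the bootstrap standard deviation, and a seed is mandatory — an unseeded
bootstrap is a reproducibility bug, not a convenience.

No rescaling of exposure versus outcome effect sizes is applied: the
occasionally-suggested "correction factor" for exposure and outcome betas
with very different distributions has no well-defined trigger or form, so
the estimators consume the harmonized effects exactly as given.

The suite records two flags: direction consistency (all five estimates
share a sign) and significance (consistency plus all five $p < 0.05$) —
the decision rule used to declare a causal finding.

## Diagnostics and MR-PRESSO

Cochran's Q (IVW form, $J-1$ df; Egger residual form, $J-2$ df) tests
heterogeneity; the Egger intercept tests directional pleiotropy; the
pipeline runs MR-PRESSO when that intercept is significant at 0.05, with an
`always`/`never` override, since published analyses sometimes report PRESSO
despite a non-significant intercept. Single-SNP (per-variant Wald ratio)
and leave-one-out IVW tables support the forest and funnel displays; the
leave-one-out drive flag marks exclusions that change the estimate's sign
or move its p-value across 0.05.

MR-PRESSO follows the residual-sum-of-squares recipe: leave-one-out IVW
slopes give expected outcome effects; the observed weighted squared
residuals are compared against `n_sim` parametric simulations (with
leave-one-out slopes re-estimated per simulation). P-values use add-one
smoothing, $(1 + \#\{\cdot\})/(n_{sim}+1)$, so they are never zero; the
per-variant outlier test is Bonferroni-adjusted by $J$ and capped at 1 —
which means the adjusted p-value can never fall below
$J/(n_{sim}+1)$, so `n_sim` must exceed $J/\alpha$ for detection to be
possible at level $\alpha$. The distortion test compares the relative
change between all-SNP and outlier-corrected slopes against random
outlier-sized subset removals, two-sided.

## The synthetic-data generator

`simulate_pair()` draws true instrument effects $\gamma_j \sim
N(0.08, 0.02^2)$, direct effects per the pleiotropy mode (none; balanced
$N(0, \sigma_\alpha^2)$; directional $N(0.1, 0.05^2)$; or
InSIDE-violating with $\mathrm{corr}(\gamma, \alpha) = 0.5$, a fixed
documented choice), an optional fraction of instruments carrying the
direct effect, and observed effects with standard errors from the standard
GWAS approximation $\mathrm{se} = 1/\sqrt{2N\,\mathrm{EAF}
(1-\mathrm{EAF})}$. Defaults place a large exposure GWAS
($N = 3\times10^5$, biobank scale) against a smaller case-control outcome
GWAS ($N = 2.5\times10^4$): this is the asymmetry of real
exposure/disease-outcome pairs, and it is the regime in which first-order
IVW weights are appropriate — with comparable sample sizes the neglected
exposure-side noise contributes $\theta^2(\sigma_X/\sigma_Y)^2$ extra
ratio variance and the nominal 95% CI undercovers no matter how strong
the instruments are. LD blocks share a common noise factor with loading
$\sqrt{r^2}$ and tag the block head's effect attenuated by $\sqrt{r^2}$,
placed within the clumping window on two synthetic chromosomes; a
configurable fraction of variants receives palindromic alleles; a fraction
of outcome records is stored with swapped alleles (a pure representation
change harmonization must undo); planted outliers get $10\,\sigma_{Y}$
added to their outcome effect. Identical config and seed give
byte-identical output.

What the generator does *not* emulate: realistic LD from reference panels,
per-variant sample-size variation, winner's-curse selection bias in the
exposure effects, sample overlap between the two GWAS, and binary-trait
effective-sample-size corrections. Passing tests therefore demonstrate the
estimators' statistical behaviour under the model they assume, not
robustness to these additional features of real data.

`simulate_seq_class_table()` fabricates the 40-column sequence-class
perturbation score tables consumed by prioritization (background
$N(0, 0.1)$, spiked entries exact); the deep-learning framework that
produces such scores in practice is consumed, never re-implemented.

## Prioritization

Instrument sets from several experiments merge by union with provenance; a
variant's b score is its single-SNP Wald beta (largest $|b|$ across
experiments, sign kept), its sequence-class score the maximum absolute
entry of its 40-class row. Selection retains variants with class score
$> 1$ and $|b| > 0.5$ (both strict), ranked by class score, then $|b|$,
then id; the thresholded filter is canonical and `top_k` is only an
optional cap, since a thresholded "top 7" is what the decision rule
actually produces. The signed scores are preserved in the outputs (heatmap
table) while the gates use absolute values.

## Verification problem sizes

The package's acceptance checks use: 1,000 random records for formula
fidelity ($10^{-12}$); 100 random 3–20-variant sets against closed-form
oracles ($10^{-8}$); 500 replicates at $J = 50$, $\theta = 0.7$ for
recovery and coverage; 500 replicates with 40% directional-pleiotropy
instruments for the robustness ordering (weighted median less biased than
IVW; Egger intercept tracking the realized mean direct effect); 1,000
null replicates for type-I calibration of IVW, Q and the PRESSO global
test (PRESSO at $n_{sim} = 200$); 100 seeds for planted-outlier
detection at $n_{sim} = 1000$; plus byte-level determinism and
brute-force prioritization agreement. These sizes give Monte-Carlo
standard errors small enough for the stated bands while keeping a full
run in a few minutes on one CPU.

## Known limitations

* First-order IVW weights are assumed valid (outcome noise dominating);
  no NOME/I$^2_{GX}$ correction for Egger regression dilution is applied,
  so with weak instruments the Egger slope attenuates slightly.
* The distortion test's null uses random outlier-sized subsets of all
  variants, one fixed documented choice among several in circulation.
* Proxy lookup is table-driven only; no LD reference panel is bundled.
* Reverse-direction analyses reuse the same machinery with roles swapped;
  with a small outcome GWAS they typically terminate with no usable
  instruments, which the pipeline reports via a dedicated exit path
  rather than fabricating an estimate.
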