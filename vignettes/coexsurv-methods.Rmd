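---
title: "Methods: seed-gene co-expression prognostic signatures"
author: "coexsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gene co-expression prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexsurv)
```

## The analysis

`coexsurv` implements a signature-discovery workflow for survival cohorts
with matched bulk expression, built around two seed genes of interest
(the motivating application is the adenylate kinase isoforms AK1 and AK4
in lung adenocarcinoma, where the two genes are anti-correlated and carry
opposed prognostic value).

The pipeline has six statistical stages:

1. **Co-expression signature.** For a seed gene $s$, every other gene $g$
   gets the Pearson correlation $r_g = \mathrm{cor}(x_g, x_s)$ across
   samples, computed on log-scale expression (log2(x+1) of TPM/RSEM-style
   estimates).  The signature is $\{g : |r_g| \ge 0.3\}$, split into a
   positive and a negative arm.
2. **Survival scoring.** Each gene receives a univariate Cox
   proportional-hazards Wald $z = \hat\beta/\widehat{se}$, with expression
   standardized to mean 0 / SD 1 so $\hat\beta$ is a log hazard per SD.
   Genes with $|z| > 2$ are *prognostic*: adverse when $z > 0$, protective
   when $z < 0$.
3. **Signature ranking.** A signature's profile is its fraction of
   prognostic members plus the four (sign $r$, sign $z$) quadrant counts;
   signatures are ranked by that fraction.
4. **Consensus.** The prognostic members of the two seeds' signatures are
   intersected by gene symbol into a signed consensus signature; each
   consensus gene carries $r$ to both seeds, its $z$, and a direction.
5. **Enrichment.** The consensus, ranked by $z$, is interrogated by
   pre-ranked weighted Kolmogorov–Smirnov GSEA, by hypergeometric
   over-representation against a stated universe, and by the
   upstream-regulator activation score
   $z_{act} = (N_{consistent} - N_{inconsistent})/\sqrt{N}$ over a signed
   regulator→target network.
6. **Stratification.** Markers are dichotomized (IHC score 2–3 = high, or
   expression above the cohort median), survival is compared by
   Kaplan–Meier curves and the log-rank test, and combined two-marker
   groups are contrasted by Cox hazard ratios against the
   doubly-protective cell.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| correlation cutoff | 0.3 | minimum \|Pearson r\| for signature membership (dimensionless) |
| `strict` | `FALSE` | whether the boundary \|r\| = cutoff is excluded |
| z threshold | 2 | minimum \|Cox Wald z\| for a prognostic call |
| Efron ties | fixed | tie handling of the partial likelihood |
| `weight_p` | 1 | GSEA score-weighting exponent (0 = classic KS) |
| `n_perm` | 1000 | gene-label permutations for the GSEA null |
| activation threshold | ±2 | activation z declaring activated/inhibited |
| IHC rule | score ≥ 2 = high | staining intensity dichotomization |
| expression split | cohort median, ties → low | RNA marker dichotomization |
| time unit | months | all follow-up times, cutoffs and rates |

The 0.3 and ±2 cutoffs are the field's conventional operating points for
this kind of signature curation and are deliberately not data-adaptive; no
multiple-testing correction enters the prognostic call (a
Benjamini–Hochberg column is emitted for information only).

## Design choices

**Boundary inclusion.** Correlation exactly at the cutoff is *included* by
default.  A strict reading of "more than 0.3" excludes a measure-zero
boundary, so the choice is immaterial on continuous data; `strict = TRUE`
is provided for users who want the literal rule.  The prognostic call, by
contrast, is strict ($|z| > 2$), since z-scores from external curations
are often reported rounded and the convention there is strict.

**Survival z definition.** Published prognostic-gene databases report
meta-z values combined over many cohorts; on a single cohort we define the
z-score as the univariate Cox Wald statistic on standardized expression
with Efron tie handling.  This keeps the semantics (sign = direction of
risk, magnitude = evidence) while being exactly reproducible.  A Stouffer
meta-combiner over cohorts would be a natural extension and is out of
scope here.

**Monotone likelihood.** With perfect separation the partial likelihood
has no finite maximizer; the fit is flagged and the reported z clamped to
±37 (beyond any meaningful two-sided normal tail) rather than returning an
arbitrary iteration-limited estimate.

**Consensus is not sign-constrained.** The intersection keeps any gene
prognostic in both signatures regardless of whether its correlations to
the two seeds agree in sign; the (sign, sign) pattern is reported so users
can filter.  With anti-correlated seeds the dominant patterns are
(+,−)/(−,+), and the package's tests verify this on simulated cohorts.

**Enrichment p-values and FDR.** The GSEA null is gene-label permutation
(random same-size sets from the ranked universe), the natural null when
the input is a derived signature rather than raw expression with class
labels.  The permutation p is a one-sided tail among same-sign null
scores with a $+1$ continuity correction, NES divides by the mean |null
ES| of the same sign, and FDR is Benjamini–Hochberg across sets — simpler
and well-defined at modest permutation counts, and a documented divergence
from the original tool's FDR-by-null-NES.  Pathway over-representation is
a plain hypergeometric test, a declared stand-in for proprietary
pathway-scoring software whose internals cannot be reproduced.

**Reference group.** For combined two-marker hazard ratios the default
reference is the doubly-protective cell (`a-low/b-high` when marker *a* is
adverse and *b* protective), so reported ratios are risk increases.

## The synthetic cohort generator

Real cohorts of this kind (TCGA-scale RNA-seq with clinical follow-up)
cannot be redistributed, so every stage is exercised on simulated cohorts
with the exact statistical structure the analysis assumes:

* two latent factors $f_A, f_B \sim N(0,1)$ with correlation $\rho_{AB}$
  (default −0.42, the anti-correlation scale reported for the motivating
  seed pair); seed-gene rows equal their factor plus small noise;
* module gene $g$ is $s_g \lambda_g f + \sqrt{1-\lambda_g^2}\,\varepsilon$,
  so its population correlation with the seed is exactly $s_g \lambda_g$
  (default loading 0.6, half the genes negatively signed);
* a designated subset of module genes carries a per-SD log-hazard
  $\beta_g = \beta \cdot s_g$ (default $\beta = 0.5$ for the adverse
  module A and $-0.5$ for the protective module B), giving the per-sample
  linear predictor $\eta_i = \sum_g \beta_g x_{gi}$;
* event times are exponential proportional hazards,
  $T_i = -\log U_i / (\lambda_0 e^{\eta_i})$ with $\lambda_0 = 0.014$
  events/month (median survival near 50 months), censored by an
  independent exponential time and an administrative cutoff at 200 months
  of follow-up;
* optional decoy modules ride independent factors with no hazard, and the
  default cohort size is 521 samples.

The exponential baseline is chosen for its closed-form inverse transform;
Cox-based stages are invariant to the baseline shape.  Censoring is
independent of expression (the standard non-informative assumption).
Expression noise is Gaussian on the log scale, which is the scale all
correlations are computed on.  A final affine shift (+8, truncated at 0)
makes values resemble log2 abundances without touching any correlation.
Whether the two modules' hazard signs are fully or only predominantly
opposed is a configuration knob (`hazard_betas`, `hazard_frac`), not a
fixed assumption.

What the generator does **not** emulate: negative-binomial count noise,
library-size variation, batch effects, and gene–gene correlation beyond
the single-factor-per-module structure.  Passing tests therefore show the
statistics are implemented correctly and behave as designed under the
assumed model — not that the biological conclusions of any particular
cohort transfer.

The generator slightly generalizes the two-seed design with decoy modules
because ranking a hazard-bearing seed against realistic competitors
requires decoys that have genuine co-expression modules, not bare noise
genes.

## Numerical choices

* Orderings are deterministic everywhere: members by descending $r$ with
  ties broken by gene symbol; signature profiles by descending prognostic
  percent with seed-symbol tie-break; heatmap order by descending $r$ to
  the chosen reference seed.
* The GSEA running sum normalizes hit weights by their own cumulative
  total, so a set occupying the top of the list scores exactly 1.0 with no
  floating-point drift; the enrichment score takes the larger of
  max/|min| deviation, ties resolved positive.
* Zero-variance genes are dropped (correlation and Cox z are undefined
  for them), never assigned $r = 0$ or $z = 0$.
* Missing expression values are rejected at load time, not imputed: every
  downstream statistic assumes complete vectors.
* Samples present in only one of expression/survival are dropped with a
  counted message; survival records with missing or non-positive times
  are dropped with a counted warning; an event indicator outside {0, 1}
  is an error.
* Expression dichotomization sends ties at the threshold to `low`, so a
  median split differs by at most one sample between arms.

## Validation strategy and problem sizes

The test suite checks every statistic against an independent oracle:
Cox estimates against a nested grid search of the Efron partial
likelihood on small fixtures (n ≤ 8, ties and censoring included);
the enrichment score against a direct O(N) running-sum re-implementation
and against an independent GSEA implementation; the log-rank statistic
against the observed-vs-expected summation; over-representation p-values
against exhaustive enumeration on a small universe; Kaplan–Meier curves
against hand-computed product limits.

Distributional properties use simulated cohorts at sizes chosen to make
the checks sharp but quick: null calibration of the z-score on 2000
independent genes at 300 samples (tail fraction 0.0455 and a KS test
against N(0,1)); signature recovery at loading 0.6 and 2000 samples;
seed ranking against six decoy modules over 100 replicates at 1000
samples; combined-marker synergy over 50 replicates at 400 samples; and
hazard-ratio self-consistency with a planted extreme-cell gap of
log 2.68 at 500 samples per cell over 50 replicates.  The consensus
recovery check uses $\rho_{AB} = -0.7$ with loading 0.75 so the planted
cross-seed correlation (0.525) sits clearly above the 0.3 cutoff; at
weaker anti-correlation the cross-correlation $\lambda|\rho|$ falls at or
below the cutoff and recovery is boundary-limited by construction, not by
implementation.

## Known limitations

* The survival z is single-cohort; no meta-analysis across cohorts.
* No multivariable or stratified Cox (stage, age adjustment).
* The upstream-regulator score uses only edge signs, not literature
  weights; users supply the network.
* GSEA FDR is BH on permutation p-values, not the original
  FDR-by-null-NES.
* The simulator's factor model controls correlations directly and does
  not reproduce count-level noise; conclusions about real-data behaviour
  require real data.
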