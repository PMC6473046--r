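---
title: "Co-twin control methylation analysis and gene-set truncated product tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-twin control methylation analysis and gene-set truncated product tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinset)
```

## The design and the model

Monozygotic (MZ) twins share their genome, age, sex and early familial
environment. Regressing *within-pair differences* of an outcome on
within-pair differences of an exposure therefore cancels all confounding
that is shared within a pair — the co-twin control design. `twinset`
implements this design for promoter CpG methylation (percent scale) and
three glucose traits: HOMA-IR, fasting glucose (mg/dL) and HbA1c (%).

For pair $i$ and CpG $c$, with $\Delta$ denoting member1 − member2
(ascending member id), the single-CpG model is

$$\Delta y_i \;=\; \alpha + \beta\,\Delta m_{ic} + \gamma^\top \Delta z_i
 + \delta\,\mathrm{age}_i + \varepsilon_i ,$$

fit by ordinary least squares; the two-sided p-value for $\beta$ uses the
t distribution with $n - k$ degrees of freedom ($k$ design columns).
Insulin resistance is the Matthews index
$\mathrm{HOMA\text{-}IR} = (\mathrm{glucose}/18.0)\times\mathrm{insulin}/22.5$,
derived from fasting glucose (mg/dL, hence the conversion divisor 18.0 to
mmol/L) and fasting insulin (µU/mL). Whether the original assays used
mg/dL or mmol/L inputs is not documented anywhere we rely on; the
divisor-18 convention is this package's choice and is stated as such.

Modelling decisions that were genuinely open:

* **Intercept.** The difference-scale model keeps an intercept. Under a
  random member ordering its estimate is ~0, but it guards against any
  systematic ordering artifact. A consequence worth knowing: per-pair
  member *relabeling* is then not an exact symmetry of a single fit — only
  the full sign-flip group (relabel a pair $\equiv$ flip its sign in the
  null engine) is exact, and that is the property the tests assert.
* **Age.** The intra-pair age difference is identically zero in MZ twins,
  so "adjusting for age" is only meaningful at pair level; age enters as a
  pair-level column.
* **Covariates.** Default adjustment set: pack-years of smoking, alcohol
  (g/week), physical activity score, BDI-II, BMI, HDL-c, LDL-c and
  systolic blood pressure. Diastolic pressure is carried in the sample
  table but not adjusted for by default (only SBP belongs to the standard
  adjustment set; both are generated so the choice stays configurable).
* **Missing data.** Complete-case per model: a pair missing any column a
  model uses is dropped from that model only, with a logged count.
* **p-value floor.** Raw p-values are floored at 1e-300 so log-products
  remain finite in the joint tests.

Multiplicity is controlled by Benjamini–Hochberg step-up q-values, per
trait across all scanned CpGs (and, for the gene-based stage, across the
five genes within each trait). `bh_fdr()` implements the literal step-up
expression $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$; q-values published
alongside the reference association table we bundle do not reproduce from
the printed raw p-values under standard BH, so `twinset` documents this and
uses standard BH rather than reverse-engineering the discrepancy.
"Significant at $\alpha$" always means the *strict* inequality
$p < \alpha$: the bundled reference table contains a row printed as
exactly 0.050, and only the strict rule reproduces the published counts
(6 CpGs for HOMA-IR, 8 for fasting glucose, 3 for HbA1c).

## The (weighted) truncated product method

Joint inference combines the single-CpG p-values of a gene (gene-based) or
of all 77 CpGs (gene-set/pathway) with the truncated product statistic

$$W \;=\; \prod_{i=1}^{L} p_i^{\,w_i\, I(p_i \le \tau)},$$

computed in log space. Unweighted, $w_i \equiv 1$; weighted, raw weights
$|\hat\beta_i|$ are normalized to mean 1 so that weighted and unweighted
statistics live on comparable scales and the weighting is invariant to the
trait's units. The truncation defaults to the canonical $\tau = 0.05$ and
is exposed as an argument.

For *independent* uniform p-values the unweighted null CDF has the closed
form

$$P(W \le w) = \sum_{k=1}^{L} \binom{L}{k} (1-\tau)^{L-k}
  \Big[\, I(w \le \tau^k)\, w \sum_{s=0}^{k-1} \frac{(k\ln\tau - \ln w)^s}{s!}
  \;+\; I(w > \tau^k)\, \tau^k \Big],$$

which `tpm_analytic_pvalue()` evaluates stably in log space (each $k$-term
via a log-sum-exp over $s$), adding the point mass $(1-\tau)^L$ at $W = 1$
so that $P(W \le 1) = 1$. At $\tau = 1$ this is exactly Fisher's method:
$-2\ln W \sim \chi^2_{2L}$, and the tests require agreement with the
chi-squared tail to 1e-10.

CpGs in the same promoter are correlated, so the analytic form is only a
reference and the operational null is permutation-based.

### The sign-flip permutation null

Under the null of no methylation effect given covariates, the trait
difference of an MZ pair is exchangeable in sign. `signflip_null()`
multiplies each pair's $\Delta y$ by an independent ±1 and refits every CpG
(methylation and covariate differences untouched). Because all CpGs share
each replicate's flipped outcome, the inter-CpG correlation of the
p-values — the thing the analytic null ignores — is preserved. Flipping
the raw $\Delta y$ rather than covariate-model residuals is approximate
when covariates matter; a Freedman–Lane-style option (`flip = "residual"`)
flips the covariate-only-model residuals instead.

The refits use Frisch–Waugh–Lovell residualization: the nuisance design
(intercept, covariate differences, age) is projected out of the outcome
replicates and all CpG columns once, which is algebraically identical to
refitting the full OLS per CpG and makes the B × 77 scan a pair of matrix
products. Tests assert exact equality with the one-at-a-time fit.

The permutation p-value uses the add-one rule
$p = (1 + \#\{b: W_b \le W_{\mathrm{obs}}\})/(B+1)$, so it is valid at
finite $B$ and floored at $1/(B+1)$. $B$ defaults to 9,999 for headline
runs; the test suite uses 199–499. Comparisons happen on $\log W$, so
products of many tiny p-values cannot underflow into spurious ties at 0.
All $B$ sign vectors are drawn in one block from the master seed —
single-threaded, order-independent, bit-reproducible.

**Weights under the null.** The weighted statistic's weights are
data-derived, so each null replicate gets its *own* weights
($|\hat\beta_b|$ from the flipped fit, mean-normalized within the unit).
Re-using the observed weights for the null rows is tempting but badly
anti-conservative — small observed p-values carry large observed
$|\hat\beta|$ by construction; in our null simulations it rejects at rate
0.45 instead of 0.05 — whereas the per-replicate scheme is exchangeable
and calibrates correctly (and the package's standalone
`tpm_permutation_pvalue()` primitive, which applies fixed weights, is kept
for unweighted use and diagnostics). The weighted statistic has no closed
form, so `weighted = TRUE` always implies the permutation null.

**Pathway pooling.** The gene-set test pools all CpG-level p-values into
one TPM test per trait, the reading most faithful to combining "all CpGs"
across the gene set; combining the five gene-level combined p-values
instead is available as `pathway_level = "gene"` (analytic route only).
A one-gene pathway reduces exactly to that gene's test. Gene and pathway
tests share one null-replicate matrix per trait, which preserves their
mutual correlation and halves the compute.

## What the synthetic cohort emulates

`generate_twin_cohort()` produces, from a seeded `sim_config()`:

* **84 pairs, 15 flagged for overt diabetes** — the exclusion rule (drop a
  pair if *either* member is flagged, concordant or discordant) leaves the
  69 analyzable pairs the design assumes.
* **77 CpGs in five circadian genes** — CLOCK 30 and PER2 9 are fixed by
  the assay being modelled; the remaining 38 are split BMAL1 18, PER1 10,
  PER3 10 as a configurable default (BMAL1 carries the most reference rows
  after CLOCK). Annotation rows get GRCh37-style coordinates around each
  gene's TSS with signed offsets spanning roughly +150 to −450 bp.
* **Methylation structure** — member value = gene mean + pair-shared
  component (fraction `pair_icc` = 0.5 of the variance) + individual
  deviation, both components equicorrelated within a gene
  (`rho_within_gene` = 0.3) and independent across genes;
  `sigma_meth` = 1.2 percentage points. Gene means sit in the two regimes
  the reference data shows: ~0.7–1.3 % for CLOCK/BMAL1/PER1/PER2 and ~44 %
  for PER3. Values are clipped to [0, 100] with a logged count — for the
  low-methylation genes this truncation is a *feature* of the regime
  being emulated, and it attenuates observed correlations slightly
  (convergence checks therefore use the mid-scale PER3 block).
* **Traits** — intra-pair differences are built as
  $\Delta y = \sum_c \beta_c \Delta m_c + \text{covariate terms} + \text{noise}$
  and split around Table-1-scale means (glucose 97.2 ± 11.2 mg/dL, HOMA-IR
  1.87 ± 1.34 with a right-skewed lognormal pair baseline, HbA1c
  5.5 ± 0.5 %). Default difference-noise SDs are 1.3 (HOMA-IR), 11
  (glucose) and 0.5 (HbA1c) — chosen once so that member-level marginal
  SDs land on the Table-1 scale. Fasting insulin is set so the *derived*
  HOMA-IR reproduces the generated one exactly, keeping planted effects on
  HOMA-IR linear through the whole pipeline. Member-level positivity
  floors (0.05 HOMA-IR, 40 glucose, 3 HbA1c) almost never bind and are
  logged when they do.
* **Covariates** — Table-1-order means/SDs, half the variance pair-shared,
  independent of methylation by default; a single optional confounding
  link (`confounding = list(cpg=, covariate=, coef=)`) lets tests isolate
  covariate-adjustment behaviour. Gaussian noise throughout: the analysis
  is OLS-based and heavy-tail emulation is out of scope.

What the generator does **not** emulate: bisulfite chemistry and
read-level pyrosequencing error, cell-type composition, zygosity error,
genuinely non-Gaussian trait tails, or the unknown real correlation
topology of the assayed promoters. Passing tests therefore certify the
statistical machinery under the stated generative assumptions, not the
biology of any real cohort.

## Problem sizes and numerical choices in the test suite

The suite (and `scripts/acceptance.R`) uses sizes chosen to balance
Monte-Carlo resolution against desk-scale runtime, stated here as the
package's own choices: correlation-convergence checks at 5,000 pairs
(±0.05 bands); ~2,000 pooled null p-values for the uniformity KS test;
gene-set calibration over 1,000 global-null cohorts of 69 pairs at
B = 499 (exact binomial 95% acceptance band around 0.05); parameter
recovery over 500 replicates of 200 pairs (planted β = 0.5 on HOMA-IR,
mean within 3 MC SEs, CI coverage within binomial bounds); the analytic
null against 10⁶-draw uniform simulations on a
(L ∈ {1,2,5,10}) × (τ ∈ {0.05, 0.5, 1}) grid within 3 MC SEs; OLS against
a normal-equations + t-CDF oracle at 1e-10; BH against the brute-force
step-up oracle exactly (the reason `bh_fdr()` computes $p\,m/j$ literally
rather than delegating to `p.adjust`, which evaluates the algebraically
identical $(m/j)\,p$ and differs in the last ulp).

## Limitations

Real cohorts of ~69 pairs leave the single-CpG scan underpowered for the
small effects typical of methylation, which is the method's own
motivation for joint tests. The trait-flip null is approximate in the
presence of strong covariate effects (use the residual-flip option to
probe sensitivity). The analytic TPM null assumes independence and should
not be used for inference on correlated CpGs; it is retained as a
reference and for the Fisher reduction. Weighted and unweighted pathway
results can disagree materially when effect sizes are heterogeneous
across traits' scales; the mean-1 normalization mitigates but does not
remove this.
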