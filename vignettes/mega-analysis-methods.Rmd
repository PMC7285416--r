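---
title: "Methods: mega-analysis of multi-study case/control expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mega-analysis of multi-study case/control expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megax)
```

## The problem

A *mega-analysis* asks whether a gene is differentially expressed between
cases and controls across a collection of independent expression studies,
recomputing the effect size from each study's raw matrix rather than
pooling published summary statistics. megax implements that workflow for
bulk microarray-style collections — the packaged example is a 12-study
lung squamous cell carcinoma (LSCC) collection totalling 285 controls and
375 cases — together with the downstream stages that interpret a driver
gene's pooled behaviour: study-covariate regression, signed
literature-relation networks, and gene-set over-representation.

## Effect sizes

For study $i$ the effect of a gene is the log2 fold change on log2-scale
intensities,
$$y_i = \bar{x}_{\text{case}} - \bar{x}_{\text{control}},$$
with the Welch standard error
$SE_i = \sqrt{s^2_{\text{case}}/n_{\text{case}} +
s^2_{\text{control}}/n_{\text{control}}}$ using unbiased sample
variances. The Welch form was chosen because inverse-variance pooling
needs a per-study variance and it makes no equal-variance assumption;
a standardized-effect alternative (Hedges-style) is deliberately not the
default since the collection's effect scale is the LFC itself.

Preprocessing conventions, all chosen for bit-for-bit reproducibility:

* **Scale detection** (`detect_scale()`): a matrix is taken to be log2
  when all values lie in $[-10, 30]$; real log2 array intensities live in
  roughly $[0, 16]$, linear intensities in the thousands, so the band is
  generous on both sides. The boundary is inclusive.
* **Linear data** are transformed as $\log_2(x + 1)$; the pseudo-count
  keeps zeros finite and is harmless at array intensity magnitudes.
* **Probe collapsing** (`collapse_duplicates()`): rows sharing a gene
  symbol collapse to the row with the highest mean expression (the usual
  "most expressed probe" rule); ties keep the first occurrence so the
  result does not depend on row order twice over.
* **Missing values**: a gene with any `NA` in a study is excluded from
  that study's effect table (with a `message`), rather than silently
  computed on a reduced sample. This is the conservative reading when a
  deposited matrix has scattered missing intensities.
* Effects where both group variances are zero keep $SE = 0$ but are
  flagged `degenerate`; they are rejected by the pooling stage, which
  requires $SE > 0$.

## Pooling, heterogeneity, and model selection

With fixed-effects weights $w_i = 1/SE_i^2$ and pooled mean $\hat\mu_F$,
Cochran's statistic is
$$Q = \sum_i w_i (y_i - \hat\mu_F)^2, \qquad df = k - 1,$$
$$I^2 = 100 \cdot \max\!\left(0, \frac{Q - df}{Q}\right), \qquad
\hat\tau^2_{DL} = \max\!\left(0,
\frac{Q - df}{\sum w_i - \sum w_i^2 / \sum w_i}\right).$$
The DerSimonian–Laird moment estimator was chosen because it is the
classic $Q$-based estimator matching the $Q$/$df$/$I^2$ vocabulary of the
selection rule below; REML or Paule–Mandel alternatives are out of scope.
Random-effects weights are $1/(SE_i^2 + \hat\tau^2)$. In both models the
pooled standard error is $1/\sqrt{\sum w}$, the 95% CI is
$\hat\mu \pm 1.959964\,SE$, and the p-value is the two-sided normal test
of $\hat\mu/SE$ — the standard choice for inverse-variance pooling.
Study weights are reported normalized to a maximum of 1, the convention
used in this pipeline's forest plots.

**Model selection** (`mega_analyze()`): the fixed-effects model is used
exactly when $Q \le df$ — equivalently when the truncated $I^2$ (and
hence $\hat\tau^2$) is zero — otherwise the random-effects model. The
$Q$-test p-value is reported for information but plays no role in the
rule.

## The partial mega-analysis

`partial_mega_analyze()` pools only the "top datasets" of a gene: the
$\lfloor k \cdot \text{fraction} \rfloor$ studies with the largest
$|y_i|$ (default fraction 0.5; 11 studies at 50% keep exactly 5).
Ranking uses the absolute effect size, not $|y_i/SE_i|$; ties are
resolved stably in favour of earlier input rows, and at least 2 studies
must survive. The floor rounding is the only rule consistent with a
5-of-11 selection at 50%.

This procedure **conditions on the observed effects**, so it is biased by
construction: under a null gene ($\delta = 0$, $\tau^2 > 0$) the partial
$|\hat\mu|$ is stochastically larger than the full-analysis $|\hat\mu|$
(the test suite demonstrates this at 1000 replicates). The package
implements the procedure faithfully and documents the bias rather than
correcting it; partial results should be read as "effect within the most
responsive half of the collection", not as an unbiased population effect.

## Covariate regression

`fit_mlr()` regresses the per-study LFC of one gene on study-level
factors (sample size, country, study age, …) by ordinary least squares.
Numeric factors enter as-is; categorical factors use treatment contrasts
and are tested jointly with a marginal $F$ test (`drop1`), so each
declared factor yields exactly one p-value (for a single-column factor
this equals the coefficient $t$ test). Unweighted OLS is the default —
the study-level effects are the observations of interest — with
$1/SE^2$-weighted least squares behind a flag.

With a dozen studies a multi-level country factor nearly saturates the
design. The fit refuses outright when the parameters cannot be
identified or no residual degrees of freedom remain, errors on
rank-deficient designs naming the aliased terms, and warns when fewer
than 3 residual df are left. Failing loudly was preferred to silently
dropping columns because a near-saturated meta-regression is exactly the
regime where a quiet alias produces plausible-looking nonsense.

## Networks from signed literature relations

Relations are `(source, target, polarity, relation_kind, provenance)`
edges with polarity $\pm 1$: `regulation` edges from a driver gene to a
target, and `disease_association` edges between a disease and a gene
(in either direction). Gene identifiers are opaque, case-sensitive
symbols; the packaged fixture deliberately preserves the printed symbol
`MI21` (presumably MIR21) rather than silently aliasing it.

* **Diagnostic network** (`build_diagnostic_network()`): genes pushed in
  *opposite* directions by driver and disease. A *positive marker* is
  disease-up / driver-inhibited, a *negative marker* disease-down /
  driver-activated. When pooled results are supplied, each marker is
  labelled `consistent` / `inconsistent` by whether
  $\mathrm{sign}(\hat\mu)$ from the **full** mega-analysis matches the
  disease polarity ($|\hat\mu| < 10^{-9}$ is `untested`); inconsistent
  genes stay in the object but are excluded from the default report
  (`consistent_markers()`).
* **Prognostic network** (`build_prognostic_network()`): driver → gene →
  disease chains, splitting genes into disease *promoters* (driver ⊣
  gene, gene ⊕ disease) and *inhibitors* (driver ⊕ gene, gene ⊣
  disease). Expression directions are attached as annotation only — an
  upstream regulator may legitimately move *with* the disease, so no
  consistency filter is applied here.

Assembly is set-semantic (row order never matters); exact duplicate
edges collapse, while duplicate edges with conflicting polarity are an
error. On the packaged LSCC fixtures the diagnostic network has 12 genes
(8 positive + 4 negative markers) and the prognostic chain 3 promoters
(TNF, NOS2, ACE) and 1 inhibitor (STK11). The prognostic fixture's
five entities include the driver PPARG itself plus these four genes.

## Over-representation analysis

What this pipeline calls "GSEA" is over-representation of a fixed gene
list, not rank-based enrichment: with universe size $N$, set size $K$
(after intersecting the set with the universe), query size $n$ and
overlap $k$, `enrich()` reports the hypergeometric upper tail
$P[X \ge k]$, the Jaccard similarity $|q \cap s| / |q \cup s|$, and
BH-FDR q-values over all tested sets (`bh_fdr()`, the standard step-up
rule). The default universe is the union of the collection's members —
the deliberately simplest reproducible background; it is overridable,
and analyses against curated collections should pass an explicit
universe. The packaged GMT is *synthetic* (GO-style names over the
fixture network genes): published set sizes and backgrounds for the
original tables are not recoverable, so packaged enrichment results are
illustrations, not reproductions.

## The synthetic generator

`simulate_collection()` draws, for gene $g$ in study $s$,
$$\delta_{gs} = \delta_g + \text{covariate shifts}(s) +
N(0, \tau^2),$$
control samples $N(\mu_g, \sigma^2)$ and case samples
$N(\mu_g + \delta_{gs}, \sigma^2)$ on the log2 scale, with per-gene
baselines $\mu_g \sim U(4, 10)$ (mid-range log2 intensities) and
residual SD $\sigma = 1$ by default — a typical per-sample spread for
log2 array data. Covariate effects enter additively on $\delta$: a
slope per unit for numeric covariates, a named per-level shift for
categorical ones, which makes the covariate-regression stage testable
against known truth. `simulate_effect_table()` draws the marginal
distribution of the matrix-level LFC directly
($y_i \sim N(\delta + \text{shifts}, \tau^2 + SE_i^2)$ with
$SE_i = \sigma\sqrt{1/n_{c,i} + 1/n_{t,i}}$); the two routes agree in
distribution (KS-checked in the suite).

Randomness derives from a single integer seed via per-study substreams
keyed by the study index, so any one study can be regenerated without
simulating the rest. What the generator does **not** emulate: probe-level
artifacts, batch structure, heavy-tailed noise, gene-gene correlation,
platform differences. Tests passing on this generator therefore
demonstrate correctness of the statistical machinery under its stated
model, not robustness to everything real GEO series contain.

## Numerical behaviour and known limitations

* **Verified calibration** (problem sizes chosen to keep the default
  suite in minutes): with 11 studies of 30/30 samples, $\delta = -1$,
  $\tau^2 = 0.2$ and 2000 replicates, the random-effects pooled mean is
  within 0.005 of the truth; the DL $\hat\tau^2$ mean is within 1% of
  truth at $k = 50$; OLS per-factor type-I error sits in $[0.03, 0.07]$
  at $\alpha = 0.05$ over 500 replicates; and a $-1.0$ country shift on
  3 of 11 studies is detected in well over 80% of replicates.
* **CI undercoverage at small $k$**: the z-based DL interval ignores the
  uncertainty of $\hat\tau^2$; at $k = 11$ with $\tau^2/SE^2 \approx 3$
  its measured coverage is ~92% rather than 95% (in the no-noise limit
  it is exactly $P(|t_{k-1}| < 1.96) \approx 92.2\%$). This is a known
  property of the classical estimator the package intentionally
  implements; Hartung–Knapp-type corrections are out of scope. Treat
  95% CIs at small $k$ as approximate.
* Pooled estimates match brute-force inverse-variance oracles to
  $10^{-12}$ and an independent DL implementation (metafor) to
  $10^{-10}$; hypergeometric p-values match exhaustive enumeration to
  $10^{-12}$ for universes up to 12 genes.
* The expression TSV dialect (two header rows: sample IDs, then
  group labels) writes doubles with 17 significant digits, so
  write/read cycles are exact and rewriting a read file is
  byte-identical.

## Worked example

```{r example, eval = FALSE}
studies <- simulated_study_table(k = 11, n_control = 30, n_case = 30)
truth <- simulation_truth(c(PPARG = -1.0), tau2 = 0.2, seed = 7)
effects <- compute_collection_effects(simulate_collection(truth, studies))
mega_analyze(effects)            # heterogeneity-driven model choice
partial_mega_analyze(effects)    # top-50% subset
```
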