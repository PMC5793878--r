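---
title: "Methods: differential methylation, target integration and survival stratification"
author: "methdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, target integration and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdrift)
```

# Overview

`methdrift` implements an analysis chain for replicated whole-genome
bisulfite sequencing (WGBS) designs with two or three groups — a typical use
case being a dietary intervention in mice: a low-fat control group (`LF`), a
high-fat group (`HF`) and a formerly obese group returned to the control diet
(`FO`).  The chain runs from per-CpG methylated/unmethylated read counts to:

1. site-level differential methylation by a Rao-Scott corrected
   likelihood-ratio test (RSLRT);
2. differentially methylated regions (DMRs) by merging and region-level
   re-testing with Benjamini-Hochberg control;
3. positional annotation and overlap enrichment against interval sets with
   matched random controls;
4. integration of DMRs with differential-expression tables through a
   distance-decayed regulatory-potential score (KS function tests and
   rank-product target calling);
5. persistence of methylation changes after an intervention (retention
   index, rule-based classes, k-means clusters);
6. single-sample gene-set enrichment (ssGSEA) with median-split
   stratification and Kaplan-Meier/log-rank survival comparison.

A beta-binomial simulator with a complete ground-truth table makes each
stage testable end to end without external data.

# The site-level test

At one CpG, group $g$ contributes replicates $j$ with methylated counts
$m_{gj}$ out of $t_{gj}$ reads.  Pooling counts within groups gives
proportions $\hat p_g = \sum_j m_{gj} / \sum_j t_{gj}$ and the binomial
likelihood-ratio statistic for equality of the two group proportions,

$$G^2 = 2\left[\ell(\hat p_1) + \ell(\hat p_2) - \ell(\hat p_0)\right],$$

with $\hat p_0$ the overall pooled proportion.  Pooling ignores biological
variability between replicates, so $G^2$ is anti-conservative whenever
replicates are overdispersed.  The Rao-Scott correction divides $G^2$ by a
*design effect* $d \ge 1$, the factor by which clustering inflates the
variance of the pooled proportion, and refers $G^2/\bar d$ to
$\chi^2_1$, where $\bar d$ is the coverage-weighted mean of the two group
design effects.  The reported *weighted coverage* is the effective sample
size $T_1/d_1 + T_2/d_2$; it is the quantity the site filter thresholds at
$\ge 10$.

## Estimating the design effect

`estimate_design_effect()` implements the classical per-unit estimator: the
heterogeneity chi-square of the replicates around the pooled proportion
divided by its degrees of freedom, clamped at 1,

$$d = \max\!\left(1,\; \frac{1}{n-1}\sum_j
  \frac{(m_j - t_j\hat p)^2}{t_j \hat p(1-\hat p)}\right).$$

With $n = 5$ replicates this estimator has only 4 degrees of freedom, and a
ratio statistic with so noisy a denominator behaves like an F rather than a
chi-square variable: in simulation its 5%-level type-I error rises to ~9%
at moderate overdispersion.  `site_scan()` therefore *moderates* the design
effect by default: a single genome-wide intra-group correlation $\rho$ is
estimated by the method of moments (pooling the heterogeneity statistics of
all CpGs, tens of thousands of degrees of freedom) and converted to
per-site design effects via the beta-binomial relation

$$d_g = 1 + \rho\,\frac{\sum_j t_{gj}(t_{gj}-1)}{\sum_j t_{gj}}.$$

Because $\hat\rho$ is essentially noiseless, the chi-square reference is
recovered; measured type-I error at the 0.05 level stays within
$[0.049, 0.061]$ for $\rho \in \{0, 0.02, 0.05, 0.1\}$ under the default
design (5 vs 5 replicates, 30x coverage).  `moderate = FALSE` restores the
pure per-site estimator for users who prefer the classical form; the two
agree as replicate numbers grow.  A genuinely site-specific dispersion
landscape is averaged over by the global $\hat\rho$; this is the usual
moderation trade-off and is conservative wherever the local dispersion is
below the genome average.

Degenerate sites (both groups fully methylated or fully unmethylated) give
$G^2 = 0$ and $p = 1$ — they carry no evidence, and are not errors.  No
continuity correction is applied.

# DMR calling

The region procedure follows three stages with fixed, strict thresholds:

* **Site filter** — a CpG is differentially methylated (DM) when
  $p < 0.05$, $|\Delta| > 0.10$ (methylation difference) and weighted
  coverage $\ge 10$.
* **Merging** — same-direction DM CpGs within 5,000 bp on one chromosome
  are chained into candidate regions.  Hyper- and hypomethylated CpGs never
  share a region: a mixed-direction region would have an uninterpretable
  methylation difference.  Singleton chains remain candidates and are
  removed later by the two-CpG rule.
* **Region test** — member-CpG counts are summed per replicate and the
  RSLRT is repeated on the aggregate (with the same moderated dispersion),
  followed by BH adjustment across *all* candidate regions of both
  directions jointly.  A region passes when $p_{adj} < 0.01$, the effect is
  large ($|\Delta| > 0.30$ *or* fold change $> 5$) and it contains at least
  2 DM CpGs.

Two choices here were genuinely open.  First, region aggregation uses the
member DM CpGs only (the region *is* the merged DM CpGs, and the
two-CpG rule refers to members); `all_cpgs = TRUE` aggregates every CpG in
the span instead.  Second, a fold change of proportions needs a zero guard:
we use $(\max(p_1,p_2)+\varepsilon)/(\min(p_1,p_2)+\varepsilon)$ with
$\varepsilon = 0.01$ (one percentage point), exposed as `eps`.

# Annotation

`distance_to_nearest_tss()` measures from the DMR midpoint to the nearest
transcription start site, signed by the gene's strand (positive =
downstream), zero if the TSS falls inside the DMR, with deterministic
gene-id tie-breaks.  `generate_matched_controls()` re-places each DMR
uniformly on its own chromosome with its own length, avoiding the DMRs
themselves — length- and chromosome-matched, but *not* GC- or CpG-density
matched, which is a known limitation when the annotation itself tracks CpG
density.  `overlap_enrichment()` counts $\ge 1$-bp intersections (exact on
0-based half-open coordinates) and reports both an empirical p value
against the control sets and an upper-tail hypergeometric p value whose
universe is the DMRs plus all control regions.

# Regulatory-potential integration

Each gene's regulatory potential sums a distance-decayed kernel over the
DMRs whose center lies within 100 kb of its TSS:

$$S = \sum_{\text{DMRs}} e^{-(0.5 + 4\Delta)}, \qquad
  \Delta = \frac{|\text{center} - \text{TSS}|}{10^5},$$

so a DMR on the TSS contributes $e^{-0.5} \approx 0.607$ and one at the
window edge $e^{-4.5} \approx 0.011$.  Window and decay scale are exposed
(`window`, `scale`) but default to the conventional 100 kb.

Function tests rank all genes by $S$ (descending, average ties) and compare
the rank distribution of up- (resp. down-) regulated genes against the
non-differential background with a one-sided Kolmogorov-Smirnov statistic
$D^+$.  Because $S$ is zero for every gene without a nearby DMR, the rank
vector is massively tied; the p value is therefore computed by exact
permutation enumeration when $\binom{n+m}{n} \le 20000$ and by the
asymptotic one-sided tail $\exp(-2D^2nm/(n+m))$ otherwise, rather than
through a generic KS routine that assumes continuity.

Target calling uses the rank product over **all** genes carrying both
evidence dimensions: $RP = (r_S/N)(r_E/N)$ with $r_S$ ascending by
decreasing potential and $r_E$ ascending by differential-expression p
value.  Ranking all genes (not only the significant ones) is deliberate:
the point of the integration is that strong regulatory potential can
rescue genes whose expression trend does not reach significance, so the
target list is not a subset of the DEG list.  `de_only = TRUE` restricts
the family when a DEG-only analysis is wanted.

# Persistence after an intervention

For each DMR the three group methylation levels are pooled over member
CpGs and replicates, and the follow-up level is placed on the
control-to-case axis:

$$r = \frac{m_{FO} - m_{LF}}{m_{HF} - m_{LF}},$$

clipped to $[-0.5, 1.5]$ so single noisy overshoots cannot dominate
summaries.  $r = 1$ is full retention of the methylation change, $r = 0$
full reversal; $r$ is undefined (flagged `NA`) when case and control levels
coincide.  The rule-based classes use $r \ge 0.7$ (retained) and
$r \le 0.3$ (lost); both thresholds are arguments.  Alongside the rule,
`cluster_dmrs()` offers the data-driven view: seeded k-means (default
$k = 6$, 25 restarts) on the $(m_{LF}, m_{HF}, m_{FO})$ profiles, with
clusters relabelled `C1..Ck` by descending mean retention.  With both
directions present, six clusters resolve the direction-by-persistence
structure (2 directions x 3 retention archetypes); with one direction,
$k = 3$ recovers the archetypes directly.

# ssGSEA and survival stratification

`ssgsea_score()` orders one sample's genes by expression and accumulates
the difference between the rank-weighted in-set distribution
($\rho^\alpha$ weights, $\alpha = 0.25$, normalised by the in-set weight
sum) and the unweighted out-of-set ECDF.  At $\alpha = 0$ the statistic is
the unweighted rank statistic and is exactly symmetric under permutation;
with weighting it carries a small positive offset by construction, which is
irrelevant for the median-split use below.  Scores are compositional: a
strong shift of one gene set moves the ranks — and thus the scores — of
other sets in the opposite direction.  No cohort-level rescaling is
applied; a reference-group split point can be supplied via `split` in
`stratify_samples()` instead of the default cohort medians (ties at the
median fall to "low" deterministically).

Kaplan-Meier estimation and the two-group log-rank test are delegated to
the `survival` package; the package's tests verify them against
hand-tabulated product-limit and observed-minus-expected arithmetic.

# The synthetic-data generator

`simulate_methylome()` generates what the analysis assumes, with every
parameter in `sim_config()`:

* **Design** — 5 replicates per group, negative-binomial coverage with
  mean 30 and size 10 per CpG and replicate (so a per-group average
  coverage well above 25x), groups `LF`, `HF`, `FO`.
* **Background** — per-CpG methylation drawn once and shared across
  groups from a two-mode beta mixture (modes 0.05 and 0.85, equal weight,
  concentration 40), reproducing the strongly bimodal marginal landscape
  of real methylomes: lowly methylated regulatory loci against a highly
  methylated bulk.
* **Replicate noise** — beta-binomial with intra-group correlation
  $\rho = 0.05$ by default; $\rho$ is exactly the quantity the Rao-Scott
  design effect absorbs.
* **Planted DMRs** — disjoint intervals of 3-8 kb (at least 15 kb apart,
  at least 4 CpGs) in which the case group shifts by $\Delta = 0.4$.
  Hypermethylated DMRs are planted on low-mode background and
  hypomethylated DMRs on high-mode background, mirroring that methylation
  gains occur at lowly methylated distal regulatory elements — and
  keeping the planted shift representable, since a +0.4 shift on a 0.85
  background would clip at 1.
* **Persistence** — the `FO` level is $m_{LF} + r(m_{HF} - m_{LF})$ with
  $r \in \{1, 0, 0.5\}$ for retained/lost/intermediate DMRs, assigned by
  quota (40/30/30% by default).
* **Scale** — CpGs are spaced ~1 kb apart (one ~50 Mb chromosome for the
  default 50,000 CpGs).  This is a desk-scale compression: the CpG count
  is reduced ~400-fold relative to a mammalian genome, and keeping the
  real ~120 bp spacing at that count would make the fixed 5 kb merge
  window span dozens of sites, chaining the site filter's false
  positives into spurious region extensions that no full-scale analysis
  would see in that proportion.  Each simulated CpG is better read as a
  locally pooled testable unit.
* **Expression** — genes coupled to planted DMRs (the nearest gene within
  100 kb, uniquely assigned) receive a log fold change of $\mp 2$
  (hyper-coupled down, hypo-coupled up); 15% of uncoupled genes carry
  weaker background differential expression ($|lfc| = 1$, random sign),
  because real expression programmes contain many changes not explained
  by methylation; the rest are null.  Observed effects add Gaussian noise
  (sd 0.3) and p values are the corresponding normal tails, BH-adjusted.
* **Survival** — a latent per-sample score $z \sim N(0,1)$ shifts the
  driver gene set's expression by `effect`$\cdot z$ and scales an
  exponential event rate by $e^{-\text{effect}\cdot z}$, with uniform
  censoring; low-score samples die sooner.

What the generator does **not** emulate: sequence context and CpG-island
structure, coverage biases that track GC content, site-specific dispersion,
strand asymmetries, correlated methylation beyond the planted blocks, and
realistic gene/DMR spatial clustering.  Passing recovery tests on this
generator therefore demonstrates the correctness and calibration of the
statistical machinery under its stated model — not performance on any
particular real genome.

# Numerical choices

* 0-based half-open coordinates everywhere internally (BED-compatible);
  a `zero_based = FALSE` flag accepts 1-based coverage dialects.
* CpGs are treated strand-collapsed (one record per CpG dyad).
* Records with zero total coverage are dropped at read time and counted.
* $G^2$ is clamped at 0 against floating-point negatives; p values are
  reported as exactly 1 at $G^2 = 0$.
* BH adjustment spans all candidate regions of a comparison, both
  directions jointly.
* Ties: average ranks in all rank statistics; gene-id ordering breaks
  distance ties; scores at the stratification median go to "low".
* Seeds: every stochastic routine takes an explicit seed (or carries one
  in its config) and reproduces byte-identical output.

# Problem sizes used in the test suite

The packaged checks run the chain at 10,000-50,000 CpGs, 5 vs 5
replicates, 30x coverage, 50-80 planted DMRs, 4,000 genes and 200-sample
survival cohorts — large enough for the calibration and recovery
properties to be sharp (site-level type-I error within half a percentage
point of nominal; DMR recall/precision above 0.9 at 50% reciprocal
overlap; persistence misclassification below 5%), and small enough that
the whole suite runs in well under a minute.

# Known limitations

* The moderated test assumes a single genome-wide dispersion; strongly
  heterogeneous dispersion landscapes call for local smoothing, which is
  out of scope.
* No smoothing or HMM across CpGs: region boundaries are exactly the span
  of the member DM CpGs.
* Control regions are not matched on GC/CpG density.
* No covariate adjustment in the site or region tests, and no
  multivariable survival modelling.
* Non-CpG methylation contexts are out of scope.
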