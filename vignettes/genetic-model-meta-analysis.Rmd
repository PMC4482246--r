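---
title: "Genetic-model meta-analysis from genotype counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-model meta-analysis from genotype counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The problem

Candidate-SNP association studies publish, per study, six numbers: the
genotype counts of cases and controls. A synthesis across studies must
(i) collapse the three genotype classes into two-level contrasts, (ii)
estimate a crude odds ratio per study, (iii) pool across studies while
accounting for between-study heterogeneity, and (iv) probe the robustness
of the pooled estimate (subgroups, leave-one-out, small-study bias).
`genemeta` implements that pipeline end to end and ships the genotype
counts of two published PSCA polymorphism syntheses (32 studies of
rs2294008 C>T, 14 of rs2976392 G>A) as worked fixtures. Only raw counts
are stored; every derived quantity (allele frequency, HWE p-value, every
odds ratio) is recomputed, which protects against transcription errors in
derived columns.

## Per-study model

Each genetic model maps counts to a 2×2 table. The homozygous and
heterozygous contrasts drop the third genotype class entirely (they
compare two genotype groups, not a partition); recessive and dominant
merge it; the allele contrast doubles persons to alleles, treating the
two alleles of an individual as independent observations. That
independence is an approximation (it ignores within-person correlation
under HWE deviation), but it is the convention under which published
allele-comparison odds ratios are computed, and the one required to
reproduce them.

The estimate is the cross-product odds ratio with the Woolf standard
error on the log scale. Degenerate inputs: if any cell is zero, the
Haldane–Anscombe correction (default 0.5) is added to **all four** cells
before estimation and the estimate is flagged `corrected`; the correction
is never applied otherwise, so studies with full cells are untouched. A
row that is entirely zero in one arm is rejected at ingestion. 95% limits
use z = 1.96 rather than `qnorm(0.975)`: the bundled results were printed
from software using the two-digit constant, and the difference (4e-5
relative) is invisible at any realistic precision.

## Hardy–Weinberg screening

Control genotypes are tested against the proportions
\((1-p)^2, 2p(1-p), p^2\) with \(p\) estimated from the same counts, by
the asymptotic chi-square goodness-of-fit test on 1 df (three classes,
one estimated parameter), without continuity correction — the convention
that reproduces the published per-study HWE p-values (e.g. the one
deviating control series in the rs2294008 fixture, p = 0.011). The exact
(enumeration) HWE test is deliberately out of scope. The reported allele
frequency is the variant (risk) allele frequency, not folded to the
minor allele, so values above 0.5 occur.

Screening exposes two policies. `flag` (default) keeps every study and
annotates deviations; `exclude` drops studies with control HWE p below
`alpha` (default 0.05). Published syntheses commonly state an HWE
inclusion criterion yet retain borderline studies; `flag` reproduces that
practice, and `exclude` makes the stricter reading available. A
monomorphic control series gets chi2 = 0, p = 1 and a `monomorphic` flag
rather than an error.

## Pooling

Fixed effects use Mantel–Haenszel weighting with the
Robins–Breslow–Greenland variance for the confidence interval — the
standard companion because it stays valid both with many small strata
and with few large ones. Inverse-variance fixed effects are also
provided; on large-count tables the two agree to well under 0.01 (the
test suite documents this on the fixture, without asserting equality).

Random effects are DerSimonian–Laird: Cochran's Q is computed from
inverse-variance weights on the log-OR scale (the conventional DL
construction; the weighting choice matters only in the third decimal
here, and this one reproduces the published heterogeneity p-values),
τ² is the moment estimator truncated at zero, and pooling weights are
\(1/(SE_i^2 + \tau^2)\). When τ² = 0 the DL result equals the
inverse-variance fixed result exactly, a identity the tests assert.

`pool()` exposes three policies. `auto` implements the conventional
decision rule: random effects when the heterogeneity p-value is below
0.10, Mantel–Haenszel otherwise. `force_random` applies DL everywhere —
the configuration that reproduces the bundled PSCA tables, whose source
analysis used random effects for all models after observing significant
heterogeneity; for homogeneous strata (the bladder subgroup) τ² ≈ 0 and
DL collapses toward the fixed result, so printed values are matched
under either policy. `force_fixed` applies Mantel–Haenszel everywhere.
A single-study stratum passes through unchanged under every policy
(method `single_study`), which is how single-study subgroup rows such as
the African-ethnicity stratum are reproduced digit for digit.

Two studies in the rs2294008 fixture (the US gastric and esophageal
series of one publication) share a control group. The pooled variance
treats all studies as independent, as the source analysis evidently did;
with 32 studies the induced covariance is negligible, but users pooling
small tables with shared controls should be aware of it.

## Subgroups and sensitivity

`subgroup_pool()` stratifies on any metadata field by exact label match
and pools each group independently. For cancer type only, strata with
fewer than three studies are merged into `"Others"` before pooling —
the small-stratum rule used in published tables; other variables keep
raw labels. The multiset union of studies across groups always equals
the parent table (asserted as a property test). The engine accepts any
user-supplied stratified table, so strata whose counts are not published
per subgroup (e.g. histological subtypes) can be analysed when the user
has the counts.

`leave_one_out()` re-pools k times with one study omitted, records the
range of pooled ORs, and raises a `qualitative_change` flag when any
omission moves the 95% interval across OR = 1 relative to the baseline —
the operational meaning of a single study driving the significance
conclusion.

## Publication bias

Egger's test is the classic unweighted form: OLS of the standard normal
deviate \(y_i/SE_i\) on precision \(1/SE_i\), two-sided t test of the
intercept on k − 2 df. A precision-weighted variant exists in the
literature; the unweighted form is the original one and reproduces all
ten published p-values of the fixture within 0.003. Begg's test computes
Kendall's τ (tau-b, so ties are defined deterministically) between the
variance-standardized deviations from the fixed-effects mean and the
sampling variances, with a continuity-corrected normal approximation for
the p-value; the Kendall score itself is validated against exhaustive
permutation enumeration on small instances in the tests. Both tests
require k ≥ 3; `funnel_data()` exports per-study coordinates for visual
inspection without further statistics.

## The simulator

`sim_config()` defines the generative model: per study, a control
variant-allele frequency drawn uniformly from `p0_range`, control
genotype probabilities at exact HWE proportions, a study-level per-allele
log odds ratio \(\theta_i \sim N(\theta, \tau^2)\), case genotype
probabilities proportional to the control probabilities times
\((1, e^{\theta_i}, e^{2\theta_i})\) (multiplicative per-allele model
under the rare-disease approximation), and multinomial genotype counts at
uniformly drawn arm sizes. Defaults (arm sizes 200–2000, allele
frequencies 0.2–0.6) mirror the bundled tables, whose control series run
from 125 to 9363 subjects with risk-allele frequencies 0.25–0.62.

Design choices: the rare-disease approximation equates controls with the
source population, matching the case-control odds-ratio interpretation
and avoiding a prevalence nuisance parameter. The multiplicative
per-allele model is the generative truth, and the five analysis models
are projections of it — the true homozygous OR is \(e^{2\theta}\), the
dominant and recessive ORs are frequency-dependent mixtures. Per-study
random streams are split deterministically from the root seed (study *i*
uses seed `root + 7919·i`), so study *i*'s data do not change when *k*
grows, and replicate experiments shift the root seed by 104729 per rep.

What the generator does **not** emulate: genotyping error, population
stratification, shared control series, selective publication, covariate
confounding. Passing parameter-recovery tests therefore show that the
estimators are correct under the stated sampling model — not that real
meta-analyses are free of those biases.

`recovery_experiment()` runs the allele-model pipeline over replicate
simulated meta-analyses and reports mean pooled OR, empirical SD of the
pooled log-OR, 95% CI coverage of the truth, null rejection rate and the
mean τ² estimate. The test suite exercises it at k = 20 studies of
1000 + 1000 subjects with θ = log 1.3 over 500 replicates (about half a
minute), plus smaller homogeneity and consistency checks (k = 10–15,
60–80 replicates); these sizes give Monte-Carlo error comfortably inside
the asserted coverage band [0.92, 0.98].

## Numerical conventions, in one place

- z = 1.96 for every 95% interval.
- Q from inverse-variance weights; τ² truncated at 0; I² = max(0, (Q−df)/Q), 0 when Q = 0.
- HWE chi-square without continuity correction, 1 df.
- Zero-cell correction 0.5 on all four cells, applied only when a zero occurs.
- Mantel–Haenszel cells used as given (no correction); the single-zero-cell
  pathology (Σbc/n = 0) is an explicit error.
- Heterogeneity threshold of the `auto` policy: p < 0.10.
- Cancer-type strata with fewer than 3 studies merge into `"Others"`.

## Known limitations

Crude (unadjusted) odds ratios only — no covariate adjustment, no
trend (Armitage) test, no meta-regression, no Hartung–Knapp or
REML/Paule–Mandel τ² alternatives, no trim-and-fill. Shared control
series are pooled as independent. The allele model's
alleles-as-observations assumption is inherited from the field's
convention, not endorsed as optimal.
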