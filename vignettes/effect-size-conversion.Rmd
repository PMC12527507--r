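---
title: "Computing, converting and reconciling effect sizes with esconvert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing, converting and reconciling effect sizes with esconvert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esconvert)
```

## The problem

Primary studies report the same comparison in many statistical dialects:
means with SDs, SEs or confidence intervals; medians with quartiles or
ranges; t, F, p or eta-squared from the group comparison; change-from-baseline
summaries; covariate-adjusted means; 2x2 tables, event proportions, reported
odds or risk ratios; event counts with person-time; correlations. A
meta-analyst must turn whatever subset a study reports into one effect size
measure, and when a study reports several overlapping subsets, must pick one
estimate - defensibly - and check that the alternatives agree.

`esconvert` treats this as a single mechanical problem. A fixed column schema
(`es_schema()`) names every recognized input statistic. A formula registry
maps each *input route* (one recognized combination of columns) to each
*measure* it can produce, possibly through several methods. `convert_df()`
walks the registry row by row, computes every candidate, selects a main
estimate, and reports how much the candidates disagree.

## Measures and scales

Eleven measures are supported: Cohen's d (D), Hedges' g (G), the raw mean
difference (MD), odds ratio (OR), risk ratio (RR), incidence rate ratio
(IRR), correlation (R), Fisher's r-to-z value (Z), variability ratio (VR),
coefficient of variation ratio (CVR) and number needed to treat (NNT). Every
estimate carries one *transform scale* on which `value ± 1.96·se` is formed:
the log scale for ratio measures, Fisher's z for correlations, identity
otherwise. The 1.96 normal multiplier is used uniformly - not a t quantile -
so identity- and ratio-scale intervals are constructed identically and
conversions invert exactly. NNT is the one exception to the symmetric
template: its value is the reciprocal of an absolute risk difference (ARD),
its CI transforms the ARD interval, and when that interval spans zero the NNT
interval runs through infinity and is reported as missing rather than
invented.

## The registry

```{r}
unlist(es_registry_counts())
head(es_registry("RR"), 9)
```

Core formulas, in the package's notation:

* **SMD family.** `d = (m1 - m2)/Sp` with the pooled SD, and
  `Var(d) = (n1+n2)/(n1 n2) + d^2/(2(n1+n2))`; `g = J d` with the rational
  approximation `J = 1 - 3/(4 df - 1)` (accurate to four decimals for
  df >= 10; the exact gamma-ratio buys nothing at meta-analytic sample
  sizes). Test statistics convert through `d = t sqrt(1/n1 + 1/n2)`,
  `t = sqrt(F)`, the inverse-t of a two-tailed p, and
  `d = 2 sqrt(eta2/(1-eta2))`. F, p and eta-squared carry no sign, so those
  routes demand an explicit `es_direction`; a missing direction is an error,
  never a silent "positive". One-tailed p-values must be doubled by the user
  before input - the two-tailed convention dominates reporting and a guess
  would be invisible.
* **Order statistics.** Means use the optimal weighted estimators of Luo et
  al. (2018); SDs use the normal-quantile formulas of Wan et al. (2014) for
  the three scenarios (range only, IQR only, both). Both assume approximate
  normality, so these routes are classed as approximations and tagged in the
  output.
* **Change scores and ANCOVA.** The change-score route builds per-group
  change SDs from the pre/post correlation, which the user must supply - no
  default is assumed, because an invisible 0.5 would silently halve or
  double variances. The ANCOVA route standardizes adjusted means by a
  user-supplied unadjusted-scale pooled SD rather than back-computing it
  from the residual SD and R-squared: fewer silent assumptions.
* **Binary outcomes.** Woolf lnOR and lnRR SEs from the 2x2 cells, with the
  Gart 0.5 continuity correction applied to all four cells only when a cell
  is zero. Reported ratios rebuild the log-scale SE from the CI width over
  3.92; a CI that excludes its own point estimate is rejected as a data
  error. Rate ratios use `Var = 1/e1 + 1/e2`; a single zero event count is
  replaced by 0.5. Person-time units cannot be validated and must match
  between groups.
* **Cross-measure conversions.** d and lnOR interconvert through the
  Hasselblad-Hedges factor `pi/sqrt(3)` (default) or Cox's 1.65; d and r
  through `r = d/sqrt(d^2 + a)` with `a = (n1+n2)^2/(n1 n2)` (4 when sizes
  are unknown). Six OR-to-RR methods are registered (Zhang-Yu with supplied
  or dataset-median baseline risk, rare-disease identity, 2x2
  reconstruction, via the SMD, and sqrt(OR)); their SEs propagate by the
  delta method on lnOR. Three OR-to-r methods are registered (via d with
  either factor, and the cosine approximation to the tetrachoric
  correlation).
* **Dispersion.** lnVR and lnCVR with the usual small-sample corrections;
  the lnCVR variance omits the mean-SD correlation term because the schema
  carries no within-study raw data - a documented limitation, not an
  oversight.

Multi-method conversions expose their method as an engine option
(`es_options(d_to_or=, or_to_rr=, or_to_r=)`) so a row always yields exactly
one candidate per route and results stay reproducible.

## Selecting a main estimate

Three approaches (`es_selected`): a user hierarchy such as
`"means_sd > t > p"`; the shipped pre-defined hierarchy per measure
(`"auto"`); or the extreme candidate (`"smallest"`/`"largest"`) for
sensitivity analysis. Every pre-defined hierarchy - stored as editable text
under `inst/hierarchies/` - obeys one tested principle: direct raw
statistics outrank reported estimates, which outrank test statistics, which
outrank approximations (order-statistic and cross-measure routes).
"Smallest" and "largest" compare absolute deviation from the null on the
comparison scale (0 for differences and z, log 1 for ratios, ARD 0 for NNT);
plain signed comparison would make "largest" mean "most positive", which is
not what a sensitivity analysis wants when effects can be negative.

## Consistency of overlapping inputs

For rows with two or more candidates, five indicators are computed on the
comparison scale: the smallest and largest candidate, their difference, the
sample SD of all candidates (n-1 denominator - the candidates are treated as
a sample of the routes one might have extracted), and the percentage overlap
of the 95% CIs of the smallest and largest candidates. Overlap is
intersection length over the *shorter* interval's width (so containment
reads 100%, and the value is bounded in [0, 100]); a union denominator is
available via `es_options(overlap_denominator = "union")`. Ratio-measure
indicators are reported on the log scale, where differences and SDs are
additive; the output carries a scale column.

Two flags automate error screening: `sign_flip` when two candidates have
opposite signs but magnitudes equal within 1% - the signature of a forgotten
direction reversal - and `large_divergence` when CI overlap falls below 25%
(or the min-max difference exceeds a user threshold, disabled by default) -
the signature of a typo such as extracting 3.1 for 2.1.

## Aggregating dependent estimates

`aggregate_df()` collapses each cluster (same `study_id` by default) into
one independent estimate. Modes `"outcomes"` and `"times"` describe
same-participant dependence (several instruments; several time points) and
share the correlated-composite formula - the mean of the estimates with
`Var = (1/m^2)[sum V_i + r sum_{i != j} sqrt(V_i V_j)]` - differing only in
what the user-supplied correlation `r_dep` means (inter-outcome correlation
vs autocorrelation). `"subgroups"` describes independent participant subsets
and uses inverse-variance pooling. `r_dep` has no default: the composite
variance moves between `V/m` and `V` as r runs from 0 to 1, which is far too
consequential to assume silently. Ratio measures aggregate on the log scale,
correlations on z; NNT is refused (aggregate the risk differences instead).

## Comparing double extractions

`compare_datasets()` aligns two tables on user-chosen key columns (duplicate
keys are fatal and named), compares shared columns cell by cell - numeric
cells after parsing, so "2.0" equals "2", with an optional absolute
tolerance that defaults to 0 because extraction values should match exactly
- and reports only differences, plus the rows present on one side only.
Reports render as csv, txt or a small self-contained html page with
unchanged cells in grey and discrepancies highlighted.

## The synthetic-data generator

`generate_fixture()` emulates the summary statistics a systematic reviewer
would extract, not raw trial data: per study it simulates two-group normal
summaries (true SMD 0.3 with between-study SD 0.1, group sizes 40-120, SDs
8-12), a 2x2 table (true lnOR log 2, control risk 0.1-0.3, groups 150-400),
Poisson event counts with person-time, or a correlation, and then writes
*every* representation of that study into one row - t derived from the
simulated means and SDs, the OR CI from the simulated cells, and so on.
Within the "smd", "smd2" and "binary" families the overlapping inputs are
exact algebraic transforms of one another, so candidate estimates coincide
and CI overlap is complete; the "median" family reports order statistics of
an actually simulated sample next to its moments, so its routes agree only
approximately - exactly the behaviour the approximation class is meant to
signal. A `corruption` fraction injects classic extraction errors (a
sign-flipped t, an inverted reported OR) with bookkeeping attributes, so
flag-detection can be tested against ground truth.

What passing these tests does *not* show: the generator draws clean,
mutually consistent summaries under normal/binomial models. Real extraction
data contain rounding, one-tailed p-values mislabelled as two-tailed,
mismatched person-time units and skewed outcomes, none of which the fixture
emulates; the consistency indicators are designed to surface such problems,
not to be immune to them.

## Numerical choices and validation sizes

Degenerate inputs error early with named fields: zero pooled SD, zero CI
width, q1 = q3, pre/post correlation at 1, equal risks (infinite NNT), empty
2x2 margins. Ties in selection break by registry order, deterministically.
Delta-method derivatives use a central difference with step 1e-5 on the log
scale - the transforms are smooth and this is accurate to ~1e-10.

The variance formulas are validated by simulation at sizes chosen to give
tight Monte-Carlo error while running in seconds: empirical Var(d) against
the formula at n = 50/50, true d = 0.5, over 10,000 replicates (5%
tolerance); the empirical SD of lnOR against the mean Woolf SE for binomial
200/200 at risks 0.2/0.1, 10,000 replicates (5%); and the median-IQR SD
estimator against truth at n = 1001 over 2,000 replicates (3%, reflecting
the estimator's own small bias). The fixture-based pipeline checks use 21
studies across all seven families and a 40-study corruption fixture.

## Limitations

Pooling, heterogeneity and forest plots are out of scope - the output is
meant to feed a meta-analysis package, not replace one. Glass's delta,
Peto's OR, cluster-adjusted SMDs, partial correlations from regression
models and single-group dispersion measures are not implemented. The
pre-defined hierarchies follow the raw > reported > test > approximation
principle but are ultimately a convention; users with a protocol should
encode it as an explicit hierarchy. XLSX files can be read (via readxl) but
not written; write CSV and convert externally if a spreadsheet is required.
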