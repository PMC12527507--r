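# esconvert

Systematic reviewers extract whatever statistics primary studies happen to
report — means with SDs, SEs or CIs, medians with quartiles or ranges, t/F/p
values, eta-squared, change-from-baseline summaries, ANCOVA-adjusted means,
2×2 tables, event proportions, reported odds/risk ratios, event counts with
person-time, correlations — and must turn them into one effect size measure
before any meta-analysis can run. Doing this by hand is slow and error-prone,
and when one study reports several overlapping statistics for the same
estimand, picking one of the resulting estimates arbitrarily invites
cherry-picking.

`esconvert` automates the whole step. A registry of formulas (177 registered
measure–route–method conversions over 21 input routes, inspect it with
`es_registry()`) computes eleven effect size measures — Cohen's *d*, Hedges'
*g*, MD, OR, RR, IRR, *r*, Fisher's *z*, VR, CVR, NNT — from any recognized
combination of input columns. For every dataset row the engine:

1. computes **all** candidate estimates, one per applicable input route;
2. selects a **main** estimate by a user-defined hierarchy, a shipped
   pre-defined hierarchy, or the smallest/largest candidate (for
   sensitivity analysis);
3. reports five **consistency indicators** across the candidates (min, max,
   difference, SD, and the % overlap of the extreme candidates' 95% CIs) and
   flags likely extraction errors — equal-magnitude opposite-sign candidates
   (a forgotten direction reversal) and low-overlap divergence (a typo).

Separate helpers aggregate dependent effect sizes within studies
(correlated-composite or inverse-variance formulas, `aggregate_df()`) and
diff two independently extracted datasets cell by cell after key-based row
alignment (`compare_datasets()`).

Core conventions: every estimate is built as `value ± 1.96·se` on its
transform scale (log for ratio measures, Fisher's z for correlations,
identity otherwise) and back-transformed; *d* uses the pooled-SD
standardization with `Var(d) = (n1+n2)/(n1·n2) + d²/(2(n1+n2))`;
`g = J·d` with `J = 1 − 3/(4df−1)`; 2×2 tables use Woolf SEs with the Gart
0.5 zero-cell correction; medians/quartiles/ranges become moments via the
Wan (2014) SD and Luo (2018) mean estimators; d↔lnOR uses the
Hasselblad–Hedges factor π/√3; six OR→RR methods (Zhang–Yu by default) and
three OR→r methods are registered.

## Worked example

```r
library(esconvert)

studies <- data.frame(
  study_id = c("Arnow 2009", "Bell 2014", "Cohen 2011"),
  n1 = c(52, 61, 40), n2 = c(48, 59, 40),
  m1 = c(23.1, NA, 14.2), m2 = c(26.4, NA, 15.9),
  sd1 = c(6.2, NA, 4.1),  sd2 = c(5.8, NA, 4.4),
  t_value = c(-2.746, NA, NA),
  p_value = c(NA, 0.041, NA),
  es_direction = c("negative", "negative", "negative"))

convert_df(studies, "G", es_selected = "hierarchy",
           hierarchy = "means_sd > t > p")
#> Effect size conversion: measure G, 3 row(s), selection 'hierarchy'
#>
#>     study_id   value     se   ci_lo   ci_up route_used n_candidates
#> 1 Arnow 2009 -0.5447 0.2023 -0.9413 -0.1482   means_sd            2
#> 2  Bell 2014 -0.3749 0.1830 -0.7336 -0.0161          p            1
#> 3 Cohen 2011 -0.3959 0.2237 -0.8343  0.0425   means_sd            1
#>   ci_overlap_pct flags
#> 1        99.9159
#> 2             NA
#> 3             NA
```

Arnow 2009 reports both means+SDs and a t statistic: two candidates are
computed, the hierarchy picks the means route, and the 99.9% CI overlap
shows the two representations agree (the t was itself derived from the
means, so this is expected). Bell 2014 reports only a two-tailed p-value
with its direction; Cohen 2011 only means+SDs. A `value` of −0.54 means the
treated group scored about half a pooled SD below control, with 95% CI
[−0.94, −0.15].

Dependent estimates (e.g. two depression scales in Bell 2014) collapse to
one row per study:

```r
aggregate_df(data.frame(study_id = c("Bell 2014", "Bell 2014", "Cohen 2011"),
                        measure = "G",
                        value = c(-0.41, -0.29, -0.38),
                        se = c(0.18, 0.18, 0.22)),
             dependence = "outcomes", r_dep = 0.6)
#> Aggregated effect sizes: 2 cluster(s), dependence 'outcomes'
#>
#>    study_id measure value    se   ci_lo   ci_up n_aggregated dependence
#>   Bell 2014       G -0.35 0.161 -0.6656 -0.0344            2   outcomes
#>  Cohen 2011       G -0.38 0.220 -0.8112  0.0512            1   outcomes
```

`make_template("G", path = "sheet.csv")` writes an extraction sheet with
exactly the columns any G-producing route can use, one description per
column; `compare_datasets(a, b, key_cols = "study_id")` reconciles double
extraction. A command-line wrapper for all of these lives in
`inst/cli/esconvert.R`.

See the vignette (`vignettes/effect-size-conversion.Rmd`) for the formulas,
the selection and consistency conventions, and the design decisions.

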