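# metaboaging

Analysis pipeline for time-course metabolomics studies of vertebrate
aging with three ordered age groups, plus the population-level mortality
analysis that goes with them.

Short-lived fish models of aging (killifish-type cohorts) are sampled at
an early-life, an aged, and an extremely old time point.  Two questions
drive the analysis this package implements:

1. **Which metabolites change with age, and in what shape?**  Some
   metabolites rise or fall monotonically; others *invert* — higher (or
   lower) in the aged group than in both early life and extreme old age —
   which is the signature of processes that revert to an early-life
   state in the oldest animals.
2. **When does mortality decelerate?**  Cohort mortality rises
   exponentially (Gompertzian) through the ageing phase and then
   plateaus late in life; the two inflection points of the log10
   cumulative-mortality curve delimit the three life-history phases.

## What it computes

* **Trend taxonomy** (`run_trend_analysis`): per metabolite, one-way
  ANOVA + Tukey HSD on the log2 profile across groups A < B < C, then
  classification into 17 trend types in 5 groups by the sign pattern of
  (x̄_B − x̄_A, x̄_C − x̄_B) — up, down, bell, u_shape — and the pattern of
  significant limbs; no significant comparison at all means no_change.
* **Co-abundance network** (`correlation_edges`): Pearson r across all
  samples for every metabolite pair; edges where r > 0.7 and
  Benjamini–Hochberg adjusted p < 0.01 (strict, positive correlations
  only, as printed).
* **Modules and influence** (`mcl_cluster`, `centralities`, `ivi`): a
  from-scratch Markov Clustering implementation, and the Integrated
  Value of Influence composite
  IVI = norm[(DC′+LH′)·(NC′+CR′)·(BC′+CI′)] over six range-normalized
  centralities, ranking metabolites by network influence
  (`rank_influential`).
* **Mortality deceleration** (`cumulative_mortality`,
  `ese_inflection`, `find_inflections`): log10 cumulative mortality and
  inflection detection with the extremum surface estimator (signed
  areas between the data polyline and its chords), with curvature
  confirmation on smoothed second differences.
* **Lipid aggregation** (`parse_lipid_name`, `class_totals`): shorthand
  parsing (TG(52:2) etc.), acylcarnitine chain bins (short C2–C6,
  medium C7–C12, long C13–C22), and per-class totals of significantly
  altered species.
* **Fiber morphometry** (`classify_fibers`, `sample_per_category`):
  cross-sectional-area categories (small <1000 μm², medium 1000–2600,
  large >2600) and seeded per-category sampling.
* **Synthetic data** (`generate_abundance`, `generate_survival`,
  `generate_fiber_areas`): planted trend mixtures, latent-factor
  correlation modules with hubs, three-phase Gompertz-plateau survival
  cohorts, lognormal fiber areas — all pure functions of (spec, seed).

See `vignettes/metaboaging-methods.Rmd` for the models, parameter
defaults and numerical choices.

## Worked example

```r
library(metaboaging)

# 300 metabolites at the default planted mixture, 5 correlation modules,
# 3 age groups x 7 replicates
specs <- trend_mixture(300)
sim <- generate_abundance(specs, n_per_group = 7,
                          modules = replicate(5, module_spec(20),
                                              simplify = FALSE),
                          seed = 11)
tab <- deduplicate(sim$table)

trends <- run_trend_analysis(log_transform(tab, base = 2))
trends
#> Trend analysis of 300 metabolites across groups 22wk < 37wk < 52wk (alpha = 0.05 )
#> no_change        up      down      bell   u_shape
#>     0.710     0.050     0.057     0.133     0.050

net <- correlation_edges(log_transform(tab, base = 10),
                         trend_calls = trends)
net
#> Co-abundance network: 300 nodes, 1950 edges
mcl_cluster(net)
#> MCL clustering: 121 modules over 300 nodes ( 10 iterations, converged )

cent <- centralities(net)
rank_influential(ivi(cent), cent, trends, k = 5)$top
#>   rank metabolite_id       IVI DC trend_group
#> 1    1      met_0042 100.00000 20   no_change
#> 2    2      met_0028  29.89324 19   no_change
#> ...

cohort <- generate_survival(three_phase_survival_spec(n = 10000, seed = 7))
find_inflections(cumulative_mortality(cohort))
#> Inflection points at weeks: 31, 44
#> Life-history phases:   1 |  31 |  44 | 112
```

Reading the output: the recovered trend-group proportions track the
planted mixture (71% no-change, 13% bell) up to classification error;
metabolites sharing a planted trend correlate strongly and surface as
dense network neighborhoods, which is why bell-trend metabolites carry
high degree; and the two inflection points split the cohort's life span
into early-life (to week 31), ageing (31–44) and late-life phases —
the second point sitting at the planted mortality-deceleration week
(45) within the weekly grid resolution.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end on synthetic data — simulation,
deduplication, log transforms, trend classification, network + MCL +
IVI ranking, lipid class totals, mortality inflection detection, fiber
categorization — prints the headline numbers of each stage, and writes
the JSON report to `--out`.
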