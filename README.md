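# hdbindex

Does a country's food supply contain enough of each food group for everyone
to eat a healthy diet? `hdbindex` answers that question against the
**Healthy Diet Basket (HDB)**, the six-food-group reference diet used by UN
agencies and the World Bank for global diet monitoring. It is aimed at
nutrition and food-policy analysts working with food-balance-sheet (FBS)
style data: national panels of daily per-capita dietary energy by commodity.

## The index

The HDB sets kilocalorie benchmarks Q_i per person per day for six food
groups (2330 kcal total, the energy needs of a reference adult woman):

| Food group              | Target (kcal/day) |
|-------------------------|------------------:|
| Starchy staples         | 1160 |
| Fruits                  | 160 |
| Vegetables              | 110 |
| Animal-source foods     | 300 |
| Legumes, nuts and seeds | 300 |
| Oils and fats           | 300 |

Given available supply q_i in each group, the **Healthy Diet Basket Index
(HDBI)** is one minus the mean proportional shortfall below target:

    HDBI = 1 − (1/6) Σ_i (Q_i − q_i)/Q_i   over groups with q_i < Q_i

Shortfalls are equally weighted and are never offset by excess in another
group, so HDBI ∈ [0, 1]: 1 means every benchmark is met; supplying all
energy as starchy staples alone scores 0.167. Free sugars sit outside the
basket and are checked against the WHO guideline that they stay below 10%
of dietary energy.

Around the index, the package provides the full analysis pipeline: readers
for old- and new-era FBS export dialects (merged at the 2010 methodology
cutover with no splicing), a user-overridable commodity-to-group mapping,
population-weighted regional supplies, unweighted country means of HDBI by
decade with t-based 95% confidence intervals, scenario projections that
apply percentage-change trajectories to a 2010 base-year supply, and a
synthetic FBS generator with ground truth for testing.

## Worked example

```r
library(hdbindex)

# All energy from staples and pulses ("rice and beans"):
compute_hdbi(c(starchy_staples = 2030, legumes_nuts_seeds = 300,
               fruits = 0, vegetables = 0, animal_source_foods = 0,
               oils_fats = 0))
#> Healthy Diet Basket Index: 0.333
#> Shortfalls below target:
#>     starchy_staples              fruits          vegetables animal_source_foods
#>                   0                   1                   1                   1
#>  legumes_nuts_seeds           oils_fats
#>                   0                   1
```

Both targets that are met (staples, legumes) contribute zero shortfall; the
four empty groups each contribute a full shortfall, so the index is
1 − 4/6 = 0.333 — sufficient calories, but far from a healthy-diet supply.

A full synthetic run, from generated FBS files to decade summaries and
projections:

```r
out <- tempfile()
run_pipeline(
  list(out_dir = out, seed = 1,
       sim = list(n_regions = 7, countries_per_region = 7)),
  stages = c("simulate", "ingest", "score", "aggregate", "project", "report")
)
read.csv(file.path(out, "region_decade_hdbi.csv")) |> head(3)
#>                      region decade mean_hdbi    ci_low   ci_high n_countries
#> 1       East Asia & Pacific  1960s 0.4501147 0.4419146 0.4583148           7
#> 2     Europe & Central Asia  1960s 0.7711671 0.7503555 0.7919787           7
#> 3 Latin America & Caribbean  1960s 0.6482740 0.6291192 0.6674287           7
```

Each row is a region-decade point: the unweighted mean of member countries'
decade-average HDBI with its 95% confidence interval across countries. The
same run writes country scores, population-weighted regional supplies, a
total-energy table, and projected HDBI per scenario under
`projection_summary.csv`. A command-line wrapper for the same stages ships
at `inst/cli/hdb.R`.

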