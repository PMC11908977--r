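---
title: "Measuring food-supply adequacy against the Healthy Diet Basket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring food-supply adequacy against the Healthy Diet Basket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdbindex)
```

## The model

National food balance sheets (FBS) account for a country's annual food
supply — production plus imports, minus exports, stock changes, non-food
uses and pre-retail losses — expressed as daily per-capita dietary energy by
commodity. The Healthy Diet Basket (HDB) condenses national food-based
dietary guidelines into kilocalorie benchmarks $Q_i$ for six food groups
totalling 2330 kcal/day. For observed supply $q_i$ the adequacy index is

$$\mathrm{HDBI} = 1 - \frac{1}{6}\sum_{i=1}^{6}\frac{Q_i - q_i}{Q_i}
\quad \text{over groups with } q_i < Q_i,$$

the mean adequacy across groups, with three deliberate properties:

* **No credit for excess.** A group at or above target contributes zero
  shortfall; surplus staples cannot compensate for missing vegetables. The
  index is therefore flat in $q_i$ above $Q_i$ and linear with slope
  $1/(6Q_i)$ below it.
* **Equal weighting.** Each group carries one sixth of the index regardless
  of its energy share, mirroring mean-adequacy-ratio practice for
  nutrients.
* **A conservative reading.** Supply is compared to per-capita targets
  under an implicit assumption of perfect distribution. Real distributions
  are unequal, so a measured shortfall is a lower bound on the true access
  shortfall; no buffer above the targets is added because no defensible
  buffer size exists. There is likewise no penalty for excess availability
  — the index measures sufficiency, not overconsumption.

Free sugars are not part of the basket. Where sugar and total energy are
available the package reports the sugar share of dietary energy against the
WHO guideline of less than 10%; the boundary is strict, so a share of
exactly 0.10 is flagged as exceeding the limit.

### Boundary and degenerate cases

Supply exactly at target contributes zero shortfall (the strict inequality
in the sum makes the boundary term vanish either way). Country-years that
genuinely lack a food group are scored as $q_i = 0$ with a warning rather
than an error, because sparse FBS panels do omit groups; a `strict` flag
turns this into an error for curated inputs. The index is reported at full
precision and only rounded (to 3 decimals) for display.

## From commodities to groups

Commodities map to the six groups plus two reserved labels: `SUGAR` and
`EXCLUDED` (spices, beverages, stimulants, infant foods, alcohol,
miscellany). Excluded items count toward neither any group nor the reported
total energy, which covers the six groups plus sugars. The bundled mapping
is a best-effort assignment for the standard FBS item list and is data, not
code — any row can be overridden by supplying a different file. Two
assignments deserve note, since reasonable conventions differ and the
choice is exposed as configuration:

* plantains are treated as starchy staples while bananas are fruits;
* oilcrops eaten directly as foods (coconuts, olives, oilseeds) sit with
  legumes/nuts/seeds, while extracted oils and animal fats form the oils
  and fats group; alcohol is excluded entirely.

Unmapped commodities are excluded with a warning by default (item lists
churn across FBS revisions), or raise an error in strict mode.

## Eras, aggregation and uncertainty

FBS methodology changed in 2010, leaving a level discontinuity between the
old and new data eras. The package takes years before the cutover from the
old-era table and years from the cutover onward from the new-era table,
performing **no** splicing or level adjustment — data are used as
published, and the era label is preserved on every record so users can
condition on it.

Two distinct aggregation pathways are implemented and named separately
because they answer different questions:

* `regional_supply()` / `total_energy()` are **population-weighted**: a
  region's per-capita supply is $\sum_c pop_c q_{c,i} / \sum_c pop_c$, the
  physically meaningful per-capita availability, used for supply series and
  energy totals. This conserves energy exactly: region per-capita supply
  times region population equals the sum of country energy.
* `decade_summary()` and `project_summary()` are **unweighted country
  means**: every national food system counts equally, which is the natural
  unit when the question is how many countries' supplies align with
  guidelines.

For decade summaries each country first contributes its average HDBI over
the years it has within the decade (no minimum-year threshold by default;
configurable), and the regional mean across countries carries a two-sided
95% confidence interval. The interval is a t-interval on the mean across
countries ($n-1$ degrees of freedom, countries as the unit of analysis):
with only "95% confidence intervals" to go on, the t-interval is the
standard small-sample choice, and the implementation keeps the interval
method isolated so a normal or bootstrap variant can be swapped in. With a
single country the interval is reported as undefined rather than zero.
Decades run 1961–1969, then full ten-year spans, with the final partial
decade covering 2020–2022 by default.

## Scenario projection

Projections consume percentage-change trajectories from partial-equilibrium
agricultural models (scenario × SSP × RCP), giving per-group proportional
changes $\delta_i(t)$ relative to a base year (2010 by default). Projected
supply is $q_i(t) = q_i(2010)\,(1 + \delta_i(t))$ — deltas are read as
**cumulative change from base**, matching how such model output is
published, with a chained year-on-year interpretation available behind a
flag. Free sugars and excluded items are held at base (the modeled
investment scenarios target the six groups), units without trajectories —
typically high-income countries — are held at base, and multi-country model
aggregates are formed from member countries with base-year population
weights, skipping any aggregate with a missing member rather than
misstating its per-capita level. When all members of an aggregate share
identical deltas, projecting then aggregating equals aggregating then
projecting; the suite asserts this commutativity to $10^{-12}$.

## The synthetic generator

There is no bundled real-world data, so the generator produces panels with
the statistical structure the analysis assumes, plus ground truth:

* **Trends**: per-region per-group logistic curves between a start and an
  end level. Logistic curves capture the plateau/transition shapes of
  dietary change and are easy to invert for recovery tests, which is why
  they were chosen over splines. The seven default archetypes emulate
  familiar regional narratives — rapid East-Asian diversification with
  staples declining off a peak, affluent plateaus with oils and sugar far
  above target, a staple-centred pattern with legumes declining from high
  levels, slow change with deep shortfalls outside staples.
* **Country scatter**: fixed lognormal offsets (default 10%) around the
  region curve, so countries within a region differ persistently.
* **Commodity structure**: each group's energy splits across 2–6 synthetic
  commodities with country-specific Dirichlet shares (concentration 3),
  plus sugar and excluded commodities so the mapping and exclusion logic is
  genuinely exercised.
* **Noise**: multiplicative lognormal per country-year-commodity,
  mean-one ($e^{\sigma Z - \sigma^2/2}$, default $\sigma = 0.05$), since
  FBS quantities are positive with roughly proportional errors. At
  $\sigma = 0$ the records sum back to the truth exactly, which anchors the
  pipeline-identity tests.
* **Populations**: exponential growth with country-specific rates
  (0.3–2.8%/yr), chosen so population-weighted and unweighted aggregation
  measurably disagree in tests.

Default problem sizes — 7 regions × 7 countries over 1961–2022 for the
pipeline-identity checks, and 5 regions × 10 countries for the
noise-recovery check — are large enough that decade means average roughly
ten years and ten countries of noise while keeping the whole suite quick to
run. The generator targets structure, not FAOSTAT realism: it does not
reproduce real marginals, country histories, reporting error, informal
trade, or the level discontinuity between eras (records are merely labeled
by era). Passing tests therefore demonstrate that the machinery is correct
and stable under the assumed structure, not that any substantive historical
finding is reproduced; applying the pipeline to real FBS exports is what
the reader should do for substantive results, and the readers accept those
files directly.

## Numerical choices and limitations

All kilocalorie values pass through ingestion and merging bit-identically;
sums and weighted means are plain floating-point reductions, and the tests
compare them against brute-force recomputation at $10^{-9}$–$10^{-12}$.
Randomness in the generator flows from a single integer seed, and the
pipeline writes a manifest recording seed, versions and row counts.

Known limitations: yearly national supply data cannot speak to subnational
or seasonal variation, nor to access and distribution; consumer-level waste
is not modeled, so availability overstates intake; the index carries no
penalty for excess energy or for unhealthy transformations of basket
commodities; and the bundled commodity mapping, while overridable, is a
convention — results for groups whose assignment is genuinely ambiguous
(plantains, directly-eaten oilcrops, alcohol) should be checked for
sensitivity to the mapping.
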