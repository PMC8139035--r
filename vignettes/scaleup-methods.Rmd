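---
title: "Methods: cost-consequence projection of mental health service scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-consequence projection of mental health service scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhscaleup)
```

## The model

`mhscaleup` projects the costs and health consequences of scaling up a
package of mental, neurological and substance-use (MNS) disorder
interventions — basic and intensive care packages for anxiety, depression,
bipolar disorder and epilepsy — from a baseline coverage level to a policy
target over a multi-year horizon (by default 2020–2030, the planning window
of Iran's national socio-mental health service programme whose published
projection tables ship with the package as reference fixtures).

The accounting is deliberately simple and fully deterministic. For each
intervention $i$ and calendar year $t$:

1. **Caseload.** Prevalent cases of the disorder are
   $P_{d}(t) = \sum_{g} N_g(t)\, \pi_{dg} / 1000$, summing over the 34
   age–sex groups $g$ (two sexes × 17 five-year GBD age bands), where
   $N_g$ is the population count and $\pi_{dg}$ the prevalence per 1,000.
   Treated cases are $T_i(t) = P_d(t)\, e_i\, c_i(t)/100$ with $e_i$ the
   eligible fraction (the share of prevalent cases the intervention
   targets — moderate cases for the basic tier, severe for the intensive
   tier) and $c_i(t)$ the coverage percentage.
2. **Coverage.** $c_i(t)$ either comes verbatim from a published per-year
   table row (authoritative when present) or is interpolated from baseline
   $b_i$ to target $T_i$ under one of four patterns (below).
3. **Costs.** Each treated case-year incurs a commodity (drug and supply)
   amount and staff time in minutes per cadre at a per-minute salary, both
   in Iranian rial at base-year prices, compounded forward by the annual
   inflation series. Programme overheads (management, supervision,
   training) accrue per year independently of caseload. The three
   components are booked separately, mirroring the
   intervention/programme/labor rows of national planning tables.
4. **Impact.** Each treated case-year *above what baseline coverage alone
   would have treated* averts $w_d \cdot f_i$ of a year lived with
   disability, where $w_d$ is the disorder's disability weight and $f_i$
   the intervention's effect size. The sum over interventions and years is
   the healthy life years (HLY) gained, equivalently DALYs averted.
5. **Cost-effectiveness.** The horizon cost in USD divided by total HLY
   gained is compared with GDP-per-capita thresholds (WHO-CHOICE
   convention): below 1×GDP is very cost-effective, 1–3×GDP
   cost-effective, above 3×GDP not cost-effective. The published rule for
   this setting quotes only the 1×GDP band; the three-band scheme
   satisfies both the quoted rule and the "cost-effective" labelling of
   the published results.

### Scale-up patterns

All four patterns pin both endpoints exactly and are non-decreasing:

* `linear` — equal annual increments, computed as
  $b + (T-b)\,t/N$ with the multiplication before the division so that
  printed one-decimal rows (e.g. 1, 3.9, 6.8, …, 30) reproduce exactly;
* `front_loaded` — a power curve $b + (T-b)(t/N)^p$, default $p = 0.5$.
  Gains concentrate early, the pattern recommended for middle-income
  settings where delivery infrastructure already exists. The planning
  tool that produced the published trajectories does not document its
  closed form, and the printed front-loaded rows do not match any simple
  power or gap-closure law exactly; the package therefore treats the
  power law as its own defined contract (endpoints, non-increasing
  increments, pointwise dominance over linear) and supplies published
  rows verbatim via `coverage_from_table()` whenever exact replication
  matters. No attempt is made to calibrate $p$ to recover the published
  rows;
* `s_shaped` — the smoothstep polynomial $3x^2 - 2x^3$; increments rise
  then fall;
* `exponential` — normalized $\,(e^{kx}-1)/(e^k-1)$ with $k = 3$;
  increments never decrease, gains concentrate late.

At interior years the patterns are ordered pointwise
(front-loaded ≥ linear ≥ exponential), which propagates through the
accounting: with common parameters, earlier coverage accrues more
above-baseline treated case-years, hence more healthy life years — and at
lower unit prices when inflation is positive — so the cost-per-HLY ratio
orders front-loaded < linear < exponential. The published sensitivity
ratios (801 < 959 < 1199 USD) exhibit exactly this ordering, and the test
suite checks that it emerges on synthetic runs.

A note on the published coverage table: its two depression rows are
exactly linear while the anxiety/bipolar/epilepsy rows are front-loaded in
shape, with no stated rationale for the mixture. The package reproduces
the printed rows verbatim rather than guessing intent.

## Key parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| horizon | calendar years | 2020–2030 | published planning window |
| eligible fraction $e_i$ | share of prevalent cases | per-intervention, e.g. 1.0 for bipolar intensive | severe cases of bipolar disorder are all referred to intensive care; basic tiers target moderate cases |
| disability weight $w_d$ | dimensionless [0, 1] | drawn 0.1–0.7 (disorder-specific sub-ranges) | not published for this package; generator records the drawn truth |
| effect size $f_i$ | fraction of disability time averted | drawn 0.2–0.5 | effectiveness parameters live inside the original planning tool and are unpublished; same recorded-truth approach |
| exchange rate | IRR per USD | 194,881 | the June-2020 market rate used for all published dollar figures |
| GDP per capita | USD | 5,550 | the 2018 threshold value used for classification |
| PPP factor | Intl\$ per USD | 9.63 | implied by the published USD/Intl\$ ratio pair (801 → 7,714); note it is inconsistent with the GDP pair (5,550 → 12,937, ≈2.33) — the original conversion-tool settings are unrecoverable, so the factor is a free input and Intl\$ figures are reported but never asserted |
| discount rate | per year | 0 | published sums are undiscounted; a hook exists |
| inflation series | per year | observed 2010–2019 drawn 8–42%, extrapolated | see below |

## Design choices on genuinely open points

**Money is integer rial internally.** All cost arithmetic is carried in
integer minor units of the local currency, rounded half-up (half away from
zero, the planning-table convention — `round_half_up()`, not base R's
round-half-to-even) at the (intervention, year) level only. This makes
every conservation identity exact: per-year totals equal component sums
bit-for-bit, horizon totals equal the sum of annual totals. Conversion to
USD and Intl$ happens only at report time.

**Rounding level.** Person counts round half-up once per (disorder, year)
or (intervention, year); age-sex-group-level values stay at full
precision. Coverage percentages are kept at full precision and rounded to
one decimal only for display.

**Prevalence-based caseloads.** The total-cost identity is
population × prevalence × coverage × unit cost, so prevalent cases drive
both costs and impacts. Incidence is carried in the data model (the
epidemiological inputs were adjusted for both rates) but used only for
internal consistency of the generator; dynamic prevalence with treatment
feedback is out of scope, matching the annual-accounting structure of the
published tables.

**Within-year convention.** Each above-baseline treated case in a calendar
year is credited a full year of averted disability — no half-year
correction, because the published accounting is annual. The first horizon
year's coverage equals baseline, so its impact is identically zero (the
published 2020 impact column is all zeros). Mortality-mediated gains are
folded into the effect size rather than modelled with life tables.

**Inflation extrapolation.** The original study extrapolated 2020–2030
inflation from observed 2010–2019 rates without stating the method. The
package uses the geometric mean of the observed $1+r$ factors applied
uniformly across the horizon — the simplest defensible reading, isolated
in one function so a linear-trend alternative can be swapped in. A
constant observed series extrapolates to itself.

**Exchange-rate handling.** The source methods mention both a single
June-2020 rate and an extrapolated exchange-rate series; the two produce
very different dollar totals under high inflation. The package defaults to
the single fixed rate and offers a per-year series mode
(`exchange_rate_series` in the economic settings; `exchange_mode: series`
in a config). With the fixed default and realistic rial inflation,
synthetic USD totals run a few times larger than the published ones, whose
internal conversion evidently offset inflation with depreciation; the
series mode reproduces that offset. The contradiction is recorded, not
resolved.

**Programme-cost scaling.** National management is booked once;
provincial management, supervision and training scale with the
administrative-unit count (31 provinces). Scaling the national overhead by
the unit count would double-count it.

**Per-capita cost.** Horizon USD total divided by the horizon-start
population. The published 16.42 USD does not state its denominator; at 83
million this reproduces the printed value within 0.1%, and the package
documents it as an approximate check only.

**Classification boundaries.** A ratio exactly equal to a band edge is
assigned to the higher (less favourable) band, so "less than one GDP per
capita" is read strictly.

**Scenario semantics.** The eight-scenario sensitivity design is encoded
exactly as described in the source: pattern swaps (exponential, linear),
epidemiological confidence-bound swaps (every rate cell replaced by its
lower/upper bound), and coverage overrides by tier (`coverage_1` baseline
40→50% for basic, `coverage_2` target 30→40% for intensive, `coverage_3`
basic target →60%), everything else inherited from base. Where the
published sensitivity table shows coverage scenarios touching disorders
the named tier would not (epilepsy impacts changing under a basic-tier
change and not under the intensive one), the package's generative path
applies each override uniformly to the named tier across all disorders and
documents that as its own assumption; the published columns themselves are
reproduced as fixture identities.

## The synthetic generator

Absolute published impact levels (e.g. 1,147,236 depression HLYs) depend
on effectiveness and transition parameters internal to the original
planning tool and never printed, so they are checked as identities on the
shipped reference tables, not predicted ab initio. Everything else is
exercised end-to-end on synthetic data with the study's structure:

* **Population:** a smooth age pyramid with a young-adult bulge, 34
  groups, integer counts allocated by largest remainder so each year sums
  exactly to its total (83 million in 2020, 1.2% annual growth).
* **Epidemiology:** prevalence per 1,000 with plausible age/sex gradients
  (depression rising with age and female-skewed, anxiety peaking in young
  adulthood, bipolar low and adult-onset, epilepsy flat with a childhood
  bump), multiplicative lognormal noise, confidence half-widths 5–15% of
  the point value, incidence proportional to prevalence. The generator
  declares its own plausibility window for weighted adult depression
  prevalence so tests can recompute it from the emitted table.
* **Unit costs:** commodity plus cadre-minutes decompositions calibrated
  to the per-case magnitudes implied by the published 2020 cost row
  (roughly 15–20 USD per basic case-year, with the intensive tier 2–3×
  the basic tier of the same disorder, guaranteed strictly more
  expensive).
* **Economics:** seeded observed inflation in the 8–42% range
  (bracketing the actual 2010–2019 decade in Iran), the fixed exchange
  rate, and the threshold values above.

What passing synthetic tests do **not** show: fidelity to the original
tool's internal effectiveness, remission or mortality parameters; realism
of any single drawn effect size; or dollar totals under the
depreciating-exchange regime the published tables imply. They do show that
the accounting is exact, linear where it should be, monotone in coverage,
additive across interventions, reproducible from a seed, and that known
disability-weight × effect-size products are recovered exactly from the
output (the model is deterministic, so recovery is algebraic, checked
per-intervention; a per-disorder regression would be collinear for
depression, whose two intensive interventions share a trajectory).

## Problem sizes and run times

The default test-suite configuration — 34 groups × 11 years × 7
interventions, eight scenarios, property loops of 20–40 randomized cases —
was chosen so the whole suite and the acceptance script each complete in
well under a minute on a laptop; all identities asserted are
size-independent.

## Known limitations

* No cohort state-transition dynamics (remission, case fatality,
  episodicity): health gains are a static multiplicative model.
* No probabilistic sensitivity analysis; the eight deterministic scenarios
  are the design.
* Private-sector service volumes are assumed away (single-provider
  perspective), as in the source.
* Demographic projection is exogenous: the population table is an input,
  not a fertility/migration model.
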