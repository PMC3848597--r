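---
title: "Measuring agreement between recall and retail-audit sales volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement between recall and retail-audit sales volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slsagree)
```

## The measurement problem

Sales volumes of anti-malarial medicines and rapid diagnostic tests (RDTs)
through private commercial outlets can be measured two ways. **Recall (RC)**
asks the provider at the second of two visits, two weeks apart, how much of
each product was sold in between. A **retail audit (RA)** never asks about
sales directly: it records stock at both visits plus deliveries and
disposals in between, and infers sales from the stock-flow identity

$$\mathrm{RA} = S_1 + D - W - S_2,$$

where $S_1, S_2$ are the stocks at the two visits, $D$ the deliveries and
$W$ the disposals. Recall is cheap but relies on memory; the audit is
burdensome and intrusive (providers may refuse to have stock counted, or
state it from memory). Neither is a gold standard, so the question is not
which is *correct* but whether they *agree* well enough to be used
interchangeably — a method-comparison problem, answered here with the
Bland–Altman approach on per-outlet totals.

## Standardization

Volumes are compared in a common unit: **adult equivalent treatment doses
(AETDs)** for anti-malarials — one AETD is the quantity of a drug making up
one full adult treatment course — and single test units for RDTs, which are
never AETD-converted. The units-per-AETD factor for each product is supplied
by the analyst through the product catalogue (`products.csv`), typically
derived from WHO treatment guidelines or the literature; the package
deliberately embeds no dosing database. An anti-malarial whose factor is
unknown is *AETD-incomputable*: it is excluded from volume estimation and
logged, never silently dropped.

Raw stock arrives through three channels — full packs, loose units, and
tablets in partially full tins whose content is estimated from the height of
the tablet column relative to a full tin. The tin estimate is rounded half
up to a whole tablet because physical stock is integer; the measurement unit
of the ruler is immaterial since only the ratio of heights enters. AETD
volumes themselves are carried as real numbers (a sale can be a fraction of
a course) and are never rounded.

## Exclusion rules and accounting

A product-level observation enters the agreement analysis only when both
methods produced a valid estimate:

* a nonresponse code (refused, not remembered, missing) in **any** of the
  four RA components voids the RA estimate — the formula needs all four
  terms;
* a nonresponse code on the recall question voids the RC estimate;
* a strictly negative RA estimate indicates a data-collection error and is
  excluded; zero is a legitimate estimate (an outlet may sell nothing), so
  only values < 0 are screened out;
* AETD-incomputable products are excluded as above.

No imputation is performed anywhere. Every record is accounted for exactly
once as analyzed or excluded-with-reason; the run manifest asserts
`read = analyzed + excluded` on every run. The response accounting
(`response_accounting()`, rendered by `render_table1()`) tabulates, per
outlet level and category, collected/refused/not-remembered/missing counts
for each method component, with percentages of products surveyed to one
decimal place, and reports RA calculability both excluding and including
negative estimates. The retail-only "missing" code observed in this kind of
survey is modelled as whole-record missingness and carried as a distinct
status without further interpretation.

Valid product-level estimates are summed to one RA and one RC total per
outlet within each category; anti-malarials and RDTs are never pooled (their
units differ), and wholesale and retail strata are always analyzed
separately. The two categories are treated as independent within an outlet:
an outlet can contribute an RDT pair even when its anti-malarial side was
wholly excluded.

## The agreement model

For outlets $i = 1,\dots,n$ with totals $\mathrm{RA}_i, \mathrm{RC}_i$,
the analysis uses $d_i = \mathrm{RA}_i - \mathrm{RC}_i$ and, lacking a gold
standard, proxies the outlet's true volume by the pair mean
$m_i = (\mathrm{RA}_i + \mathrm{RC}_i)/2$. The bias of measurement is
$\bar d$, its spread the sample standard deviation $s$ (denominator
$n - 1$), and the 95% limits of agreement are

$$\mathrm{LoA} = \bar d \pm 1.96\, s.$$

The multiplier is the literal normal quantile 1.96, not a $t$ quantile, so
the limits are exactly symmetric about the bias. Interval estimates are a
design choice (conventions in published agreement analyses vary between $z$
and $t$): the bias CI uses $\bar d \pm t_{n-1}\, s/\sqrt n$ — the
small-sample-safe convention — and each limit's CI uses the classical
variance approximation $3 s^2 / n$, i.e.
$\mathrm{LoA} \pm t_{n-1}\, s\sqrt{3/n}$. Published intervals computed with
other conventions are therefore matched only approximately, and the test
suite never treats them as exact oracles.

The bias only summarizes agreement if it is constant over the measurement
range. Proportional bias is checked as the Pearson correlation between $d$
and $m$ with the usual $t$-test on $n-2$ degrees of freedom (Pearson, to
match the correlation printed by the common Stata mean-difference-plot
implementation). Approximate normality of the differences is assessed with
histogram bins and a Shapiro–Wilk statistic, as an advisory note that never
blocks the analysis.

### Outlier screening

A single outlet whose volume dwarfs all others can dominate every statistic.
The screen flags an outlet when its pair mean exceeds $k$ times the largest
pair mean among the remaining outlets (default $k = 3$, `Inf` disables),
repeating on the reduced set until stable. Because any such rule is
ultimately judgmental, the screen never silently discards data: whenever
anything is flagged, the analysis is reported both without and with the
flagged outlets.

## The synthetic-survey generator

Field SLS record sets are not publicly available, so the package generates
its own, in two layers that mirror how the data arise.

**Truth layer** (`simulate_truth()`). Outlets come in two strata (wholesale,
retail; retail split over pharmacy / drug shop / mobile / grocery / village
shop types). Per stocked product, true two-week sales are drawn from a
zero-inflated negative binomial, reflecting a market where most outlets sell
little or nothing in two weeks but a long right tail exists; defaults put
retail outlet totals mostly between 0 and 20 AETDs, with a rare (p = 0.01)
outlet whose volumes are inflated tenfold, emulating the dominant ~100+ AETD
outlets such surveys encounter. Deliveries arrive with probability 0.3;
disposals are nearly never (p = 0.01) — providers in this market essentially
never throw stock away. Stocks are constructed so the stock-flow identity
holds *exactly*, making the ledger a row-level oracle for the RA estimator.

**Measurement layer** (`apply_measurement()`). Recall for true volume $v$ is
$\max\{0,\ \delta + \beta v (1 - \gamma v) + \varepsilon\}$,
$\varepsilon \sim N(0, \sigma_{rc}^2)$: $\delta$ an additive shift (negative
$\delta$ = under-recall = positive RA−RC bias), $\beta$ a multiplicative
factor, $\gamma$ a volume-dependent attenuation that induces proportional
bias, with optional heaping to whole units and truncation at zero (providers
cannot recall negative sales — the asymmetry this creates at tiny volumes is
intentional). Stocks are physically counted or stated from memory with
distinct error scales ($\sigma_{stated} > \sigma_{counted}$); loose retail
tablets are sometimes represented as tins measured by height. Nonresponse —
recall refusals and not-remembered answers, stock-count refusals,
whole-record missingness — is injected at per-level rates. Default rates
follow the response pattern documented for this kind of survey (wholesale:
16.3% of recalls not remembered, 10.6% refused, 7.7% of stock counts
refused, 51% of stocks counted; retail: 2.8% not remembered, 8.4% stock
refused, 7% whole-record missing, 97% counted). Default bias settings
($\beta = 0.85$, $\gamma = 0.005$, $\sigma_{rc} = 2$ AETD) encode mild
under-recall growing with volume. All randomness derives from one master
seed through fixed per-channel substreams, so one error channel can be
re-scaled under common random numbers — this is what makes the
monotone-degradation property (more recall noise never shrinks the sd of
differences) testable.

**What the generator does not emulate**: supply-chain links between the
simulated wholesalers and retailers, spatial or cluster sampling structure,
temporal dynamics beyond the single two-week interval, stock-outs, price or
cost data. Passing tests therefore demonstrate that the *pipeline arithmetic
and statistics* behave as specified under controlled error mechanisms — not
that any particular field data set satisfies those mechanisms.

## Numerical and degenerate-input choices

* The RA stock-flow difference is computed on base units and converted to
  volume once. Because the AETD divisor is constant within a product, this
  is algebraically identical to converting each term first, and it keeps the
  error-free conservation check exact in floating point rather than exact to
  rounding error.
* Tin estimates round half up (away from the even-rounding of `round()`),
  since a count of physical tablets is being reconstructed.
* Fewer than 2 outlet pairs in a stratum, or zero variance in the
  differences or means, yields explicit structured statuses
  (`"insufficient pairs"` errors, `"degenerate"` correlation status), never
  silent `NaN`s; strata that cannot be analyzed are skipped with a warning
  while others proceed.
* Recall truncation at zero biases recovery experiments when true volumes
  are small relative to $|\delta| + 3\sigma_{rc}$; the additive-bias
  recovery study below therefore uses a high-volume market in which
  truncation is negligible. That is a property of the scenario design, not a
  limitation of the estimator.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: exact
rational arithmetic for tin estimation; hand-computed stock-flow cases;
`stats::cor.test` as the independent route for the proportional-bias
correlation; frozen closed-form values for the CI formulas; and the
generator's truth ledger for end-to-end conservation (bias and sd exactly 0
on error-free data, ~1,200 records). Two simulation studies are run both in
the tests and in `scripts/acceptance.R`: (1) additive-bias recovery — recall
shifted by 4 AETDs under sd-9.7 noise, 100 outlets per replicate, 500
replicates; the true bias must fall inside the estimated 95% CI in at least
93% of replicates; (2) proportional-bias detection at 60 outlets —
volume-dependent attenuation ($\gamma = 0.02$) must produce $r > 0$ with
$p < 0.05$, while a constant additive shift must not. In-sample LoA coverage
is checked at 95% ± 1% on 10,000 normal differences. These sizes keep the
whole suite under a minute per study while leaving the binomial noise of the
coverage estimates well inside the asserted margins.

## Limitations

Only the simple single-measurement Bland–Altman form is implemented: no
regression-based or log-transformed variants, no repeated-measures
agreement. The interval estimates for the limits of agreement use the 1986
variance approximation rather than exact methods. The generator's
counted-vs-stated error magnitudes are illustrative — field data quantify
only the *shares* counted, not the error scales — so conclusions about which
error channel dominates should not be read off the defaults.
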