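# slsagree

Agreement analysis of two ways of measuring medicine sales volumes in
commercial outlets: **provider recall** (RC — the shopkeeper states what was
sold over a two-week interval) versus a **retail audit** (RA — sales inferred
from stock flow over the same interval). The package targets researchers who
run sales-level surveys (SLS) of anti-malarial medicines and malaria rapid
diagnostic tests (RDTs) in private-sector outlets — wholesalers, pharmacies,
drug shops, groceries, mobile providers — and need to know whether the cheap
method (recall) can stand in for the expensive one (audit).

## What it computes

Quantities are first standardized: anti-malarial volumes are expressed in
**adult equivalent treatment doses** (AETD — the quantity of a drug making up
one full adult treatment course), RDT volumes in single test units. Stock
held loose in tins is estimated from the tablet-column height relative to a
full tin. For each outlet *i* and product, the audit estimate is the
stock-flow difference

```
RA = stock(SLS1) + delivered − disposed − stock(SLS2)
```

Records are screened: anti-malarials whose AETD conversion is unknown,
records with a nonresponse code (refused / not remembered / missing) in
either method, and strictly negative RA estimates (data-collection errors)
are excluded, each with a logged reason. Valid product-level estimates are
summed to one RA and one RC total per outlet and category, and agreement is
assessed with the Bland–Altman procedure on the per-outlet differences
d(i) = RA(i) − RC(i):

- bias = mean(d), with a t-based 95% CI: bias ± t(n−1) · sd/√n,
- limits of agreement LoA = bias ± 1.96 · sd, each with a 95% CI using the
  Bland–Altman variance approximation 3·sd²/n,
- proportional bias as the Pearson correlation between d(i) and the pair
  mean m(i) = (RA(i) + RC(i))/2, with a t-test p-value,
- a Shapiro–Wilk normality advisory and the mean-difference plot
  (equality line, bias line, dashed LoA lines).

Wholesale and retail outlets, and anti-malarials and RDTs, are always
analyzed as separate strata. Outlets whose volume dwarfs all others
(configurable dominance rule, default 3× the next-largest pair mean) are
flagged and the analysis is reported both with and without them.

Because real SLS record sets are not public, the package includes a
synthetic-survey generator (`simulate_truth()`, `apply_measurement()`) whose
truth ledger satisfies the stock-flow identity exactly and whose measurement
layer adds configurable recall bias (additive, multiplicative,
volume-dependent), counted-vs-stated stock error, nonresponse and outlier
outlets — so every pipeline stage is testable against known ground truth.

## Worked example

```r
library(slsagree)

market <- market_config(seed = 42)          # outlet strata + true sales process
truth  <- simulate_truth(market)            # ground-truth stock-flow ledger
survey <- apply_measurement(truth, measurement_config())  # field records

analysis <- analyze_survey(survey, attr(truth, "products"))
print(analysis$strata$wholesale_antimalarial$result)
```

```
Bland-Altman agreement (RA - RC), n = 32 outlets
  bias: 1.31 (95% CI 0.12 to 2.49)
  limits of agreement: -5.13 to 7.75
    lower LoA CI: -7.18 to -3.08; upper LoA CI: 5.69 to 9.80
  proportional bias: r = 0.448 (p = 0.0101)
  no departure from normality detected
```

Reading: across the 32 wholesale outlets with both estimates, the audit
measured on average 1.31 AETDs more than recall over the two weeks (the CI
excludes 0, so recall under-reports on average), and for 95% of outlets the
two methods are expected to disagree by between −5.13 and +7.75 AETDs.
The positive correlation between differences and volumes (r = 0.448) warns
that the bias is not constant: the methods diverge more at higher-volume
outlets, so the mean difference alone understates the disagreement there.

Response accounting in the survey-report layout:

```r
render_table1(analysis$accounting)[1:4, c("measure", "wholesale_antimalarial")]
#>                           measure wholesale_antimalarial
#>           Total products surveyed           108 (100.0%)
#>  Sales volume data collected (RC)             84 (77.8%)
#>                  - Not remembered             16 (14.8%)
#>                         - Refused               8 (7.4%)
```

`write_results(analysis, "out/")` writes `results.csv`, `accounting.csv`,
`exclusions.csv`, `manifest.json` and one `ba_<level>_<category>.png`
mean-difference plot per stratum. A thin command-line wrapper is installed
at `system.file("cli", "sls.R", package = "slsagree")` with `simulate`,
`analyze` and `report` subcommands.

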