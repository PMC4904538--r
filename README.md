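# mesoapportion

Apportionment of asbestos-related mesothelioma risk across an
individual's exposure history.

When a mesothelioma has been judged asbestos-related, physicians and
other experts are often asked — typically in a compensation context —
how much of it to attribute to a particular asbestos-containing product,
workplace or time period. That attribution is not simply proportional to
dose: it depends on when each exposure occurred relative to diagnosis,
on the airborne fiber concentration during each period, and on the fiber
type's potency for causing mesothelioma. `mesoapportion` performs that
calculation for a whole exposure history and reports each entry's share.

## The model

Each above-background exposure period *i* (a calendar year, or part of
one) contributes an absolute mesotheliogenic risk

    risk_i = c_i × p_i × (m_i / 12) × T_i^e ,
    T_i   = max(0, Y − (y_i + L))          (optionally capped at M − L)

where *c* is the relative 8-hour TWA concentration, *p* the fiber
type's relative mesotheliogenic potency (commercial chrysotile ≡ 1),
*m* the months of exposure, *y* the exposure year, *Y* the diagnosis
year, *L* the latency lag (default 10 years — the initial period
carrying essentially no mesothelioma risk), *e* the time exponent
(default 2), and *M* an optional plateau on time since exposure,
reflecting cohort evidence that pleural mesothelioma rates stop rising
roughly 40–45 years after exposure. With the defaults, an identical
exposure twice as far in the past carries a fourfold risk. The
percentage contribution of entry *i* is `risk_i / Σ risk × 100`;
because only ratios enter, any common rescaling of concentrations,
potencies or months cancels out, so relative values suffice.

Relative potency constants from the fiber-type literature are available
via `preset_potency()` (chrysotile:amosite:crocidolite of 1:100:500 for
lifetime and 1:35:200 for occupational exposure scenarios, plus an
illustrative generic amphibole:chrysotile 50:1) and `mixed_potency()`
for blended exposures (e.g. 90 % chrysotile + 10 % amphibole →
0.9·1 + 0.1·50 = 5.9 ≈ 6).

## Worked example

A hypothetical case diagnosed in 2013: work with a mixed-fiber
"product A" (potency 6) at Plant A for 4 months of 1965 and 2 months of
1966 plus a half-month re-exposure in 1969, and chrysotile-only work
around miscellaneous asbestos materials (potency 1) from 1966 to 1970.

```r
library(mesoapportion)
history <- rbind(
  expand_range(1966, 1970, months = 12, concentration = 1, potency = 1,
               group = "misc. products"),
  exposure_history(year = c(1965, 1966, 1969), months = c(4, 2, 0.5),
                   concentration = 1, potency = 6,
                   description = c("Plant A", "Plant A", ""),
                   group = "product A")
)
history$months[history$year == 1966 & history$group == "misc. products"] <- 10
history$months[history$year == 1969 & history$group == "misc. products"] <- 11.5

apportion(history, case_config(2013, rounding = "truncate"))
```

```
Mesothelioma year diagnosis: 2013

Year  Months  Concentration  Potency  Description     Group description     Result   Percent
Group description: misc. products
1966  10      1              1                        misc. products          1140    10.96%
1967  12      1              1                        misc. products          1296    12.46%
1968  12      1              1                        misc. products          1225    11.78%
1969  11.5    1              1                        misc. products          1107    10.64%
1970  12      1              1                        misc. products          1089    10.47%
                                                      Subtotal                5857    56.30%

Group description: product A
1965  4       1              6        Plant A         product A               2888    27.76%
1966  2       1              6        Plant A         product A               1369    13.16%
1969  0.5     1              6                        product A                289     2.78%
                                                      Subtotal                4546    43.70%

                                                      Total                  10403   100.00%
```

Reading it: the 1965 product A stint — only four months, but early, so
its time weight is 38² = 1444 — alone accounts for 27.76 % of the total
mesotheliogenic risk, and product A as a whole for about 44 %, despite
contributing far less exposure time than the miscellaneous work. The
`Result` column is the absolute risk score (here floored to integers,
the original program's printout convention; the default `exact` mode
keeps full precision), and `Percent` is each entry's share of the
total.

The same history ships as `example_exposures()`, and
`render_report(report, format = "csv")` / `"json"` export the report
losslessly. A command-line front end is installed at
`system.file("cli", "mesoapportion.R", package = "mesoapportion")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mesoapportion.R", package="mesoapportion"))')" \
    --input history.csv --diagnosis-year 2013 --mode truncate
```

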