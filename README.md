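# growsel

Growth-curve fitting and genetic-hypothesis selection for seedling
phenotypes in reciprocal-hybrid designs.

## What problem does this solve?

Crossing a large-seeded and a small-seeded bean accession in both directions
yields reciprocal F1 seeds with an *identical nuclear genotype* but the seed
size of their *maternal parent*. Measuring early seedling traits on the two
parents and the two reciprocal F1s lets you ask, trait by trait, whether
growth is governed by the maternal seed-size phenotype (the reserves in the
cotyledons) or by the embryo's genotype. `growsel` is for quantitative
geneticists and plant phenotyping groups who want to run that analysis — or
validate one — end to end.

The package provides:

* three trajectory families with analytic gradients — expolinear
  `Y(t) = (Cm/Rm) log(1 + exp(Rm (t − tb)))`, Gompertz
  `Y(t) = Wf exp(−exp(−k (t − TT)))`, and sigmoidal decay
  `Y(t) = Min + (Max − Min)/(1 + exp(rate (t − TT)))`;
* a maximum-likelihood **generalized non-linear least squares** engine with
  AR1 within-plant correlation and heteroskedastic variance functions
  (exponential-of-day, or one ratio per destructive harvest), written for
  this package and cross-validated against `nlme::gnls`;
* five genetic grouping hypotheses (GEN4, GEN3, MAPHE, MAHY, UNI) fitted as
  shared-parameter levels and compared by **AICc** with Akaike weights,
  evidence ratios and support bands;
* end-point Tukey HSD comparisons with compact letter displays, seed shape
  descriptors (circularity), and derived allocation statistics (root length
  per gram of seed, reserve remobilization efficiency);
* a synthetic-data generator emulating the study design (repeated
  measurements every other day to day 12; destructive harvests), with the
  published per-class estimates as default truth.

## Worked example

Simulate a total-root-length dataset at the study scale (14 plants per
line, days 2–12) under the maternal seed-size hypothesis, then fit all five
hypotheses and compare:

```r
library(growsel)
d <- simulate_trajectories(sim_config("TRL", plants_per_line = 14, seed = 1))
report <- run_full_analysis(d)
report$traits$TRL$selection
#> Model selection by AICc (n = 336)
#>  scheme df  logL AICc  dAICc    wAICc        ER support
#>   MAPHE  9 -1504 3027   0.00 9.96e-01 1.000e+00  strong
#>    GEN4 15 -1503 3038  11.01 4.05e-03 2.460e+02 discard
#>    MAHY 12 -1580 3185 158.01 4.85e-35 2.053e+34 discard
#>    GEN3 12 -1585 3196 168.44 2.64e-37 3.769e+36 discard
#>     UNI  6 -1623 3258 230.61 8.34e-51 1.194e+50 discard
```

The maternal-phenotype model (MAPHE, two levels) wins decisively: it has
virtually all the Akaike weight, and only GEN4 — which *nests* MAPHE at the
cost of six extra parameters — is even on the table. The best model's
estimates:

```r
report$traits$TRL$fits$MAPHE
#> Generalized non-linear least squares fit (TRL)
#>   family: expolinear   scheme: MAPHE  levels: large/small
#>   covariance: AR1 + varExp
#>   logLik = -1504.438 on 9 parameters (n = 336 obs, 56 plants)
#>  parameter level estimate     se     ll95     ul95
#>         Cm large 145.8627 3.8648 138.2878 153.4375
#>         Rm large   0.9342 0.0470   0.8422   1.0263
#>         tb large   6.1274 0.1048   5.9219   6.3328
#>         Cm small  85.4492 4.5334  76.5639  94.3345
#>         Rm small   0.6665 0.0415   0.5852   0.7478
#>         tb small   6.0446 0.2417   5.5708   6.5184
```

`Cm` is the linear-phase growth rate (cm/day): the large-seed class builds
total root length nearly twice as fast as the small class, and every 95%
interval brackets its generating value (truth was Cm 149.52/84.86,
Rm 0.92/0.65, tb 6.22/6.14). `render_report(report, "out/", "csv")` writes
the selection and estimate tables; `"json"` gives a machine-readable
report.

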