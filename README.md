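# frugitrack

Radio-telemetry home-range and habitat-selection analysis for
central-place foraging bats in fragmented agricultural landscapes.

Small frugivorous bats such as *Dermanura watsoni* roost in natural
forest fragments and forage across mosaic landscapes of forest, degraded
vegetation, farmland, pasture and settlements. VHF tracking of such
animals produces paired compass bearings from two observers, which must
be turned into locations, home ranges, and inference about habitat use.
`frugitrack` implements that full chain for movement ecologists:

* **Telemetry processing** — biangulation of paired bearings (azimuths
  θ as rays `o + t(sin θ, cos θ)`), filtering by bearing separation
  (15–165°), forward-ray and transmitter-range (400 m) rules,
  stationary-run deduplication, session partitioning.
* **Home ranges** — percent minimum convex polygons (95% MCP = HR_tot;
  per-session 95% MCPs = daily ranges), fixed k-LoCoH isopleths with
  k = round(√n) and focus-area (disjoint component) detection, and the
  compactness ratio 4πA/P² that indexes how linear a range is.
* **Habitat selection** — Manly design-III selection ratios
  wᵢ = Σⱼuᵢⱼ / Σⱼu₊ⱼπᵢⱼ over five land-cover classes with simultaneous
  Bonferroni confidence intervals, the log-likelihood χ², exact Fisher
  tests of near- vs far-focus-area composition, and Holm correction.
* **Daily-range models** — random-intercept Gaussian models of log daily
  range fitted by profiled maximum likelihood, all-subset AICc ranking
  (K = fixed effects + 2 variances), Akaike weights, Δ2 top sets,
  conditional/full model averaging with unconditional SEs, relative
  importance, conditional R², and VIF screening.
* **A synthetic study generator** — fragmented landscapes, goal-biased
  correlated-random-walk tracks of resident and commuting bats, and
  noisy two-observer bearings, so the whole pipeline can be exercised
  against known ground truth.

The published per-bat summary table for 16 tracked bats ships as
`dermanura_homeranges()` and drives the desk-level re-analyses.

## Worked example

```r
library(frugitrack)

# desk re-analysis of the published 16-bat home-range table
tab <- dermanura_homeranges()
gs <- geometry_summary(tab)
#> HR_tot: 11.3 +/- 9.1 ha (range 1.7-30.6), n = 16
#> log(HR_tot) vs compactness: r = -0.73, 95% CI (-0.90, -0.37), p = 0.0012
```

Mean total home range is 11.3 ha with enormous spread (1.7–30.6 ha), and
the strong negative correlation says that the larger a bat's range, the
more linear its shape — the geometric fingerprint of directed commuting
flights rather than uniformly expanded foraging.

```r
# a complete synthetic study through the whole pipeline
st <- generate_study(n_bats = 4, commuter_fraction = 0.25,
                     sessions = 3, seed = 11)
res <- run_pipeline(st$bearings, st$map, st$roosts)
res$home_ranges
#>   bat_id hr_tot_ha n_fixes compactness n_focus_areas
#> 1   bat1      2.43      99       0.912             2
#> 2   bat2      3.04      90       0.919             3
#> 3   bat3      3.07     106       0.892             1
#> 4   bat4     15.19     103       0.566             1
res$selection
#>   category   wi   se ci_low ci_high
#> 1  natural 1.42 0.27   0.75    2.08
#> 2 degraded 0.29 0.19   0.00    0.76
#> 3 farmland 0.00 0.00   0.00    0.00
#> 4  pasture 0.00 0.00   0.00    0.00
#> 5    urban 0.00 0.00     NA      NA
```

`bat4` is the commuter: a 15 ha range with compactness 0.57 against the
residents' ~3 ha at ~0.9. The selection table pools use (fixes inside
each bat's 50% LoCoH focus areas) against per-bat availability circles:
natural forest is used above availability, pasture and farmland are
avoided, and urban is unused (no interval). At this toy size (4 bats)
the simultaneous intervals are wide; the 16-bat default preset gives the
natural category an interval excluding 1.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (simulate → triangulate → home ranges → selection →
models), printing what each stage found and writing its tables under
`results/`.

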