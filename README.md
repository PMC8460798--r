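# emergephen

Thermal-time models of autumn *Poa annua* (annual bluegrass) seedling
emergence in managed turfgrass.

Annual bluegrass is the most troublesome weed of turfgrass systems; its
seedlings emerge in a concentrated autumn flush, and both chemical and
non-chemical control work best when timed to that flush. **emergephen**
models cumulative emergence as a function of *cooling degree days*
accumulated from the summer solstice with a 21 °C base,

    CDD(d) = sum over t from Jun 21 to d of max(0, 21 − T̄_t),

and fits two monotone curves to the (CDD, cumulative fraction) points of a
site-year:

* early-season emergence (0–50 % of the yearly total): a Gompertz curve
  `y = a·exp(−b·exp(−c·CDD))`;
* yearly cumulative emergence: the saturating exponential
  `y = −a + b·(1 − exp(−c·CDD))` of ruminal-degradation kinetics.

Fitted curves are inverted by bracketed root-finding to management
benchmarks (the CDD — and calendar date — at which 50 % or 75 % of yearly
emergence is predicted), fits are scored by R², MAE and MSLE, candidate
environmental drivers are screened by Pearson correlation, and
peak-emergence windows are detected together with concurrent 7-day soil
temperature and rainfall summaries. A seeded simulator (weather,
seedbank-multinomial counts on the field monitoring cadence, predictor
panels) provides ground truth for every stage.

## Worked example

```r
library(emergephen)

# a full season with known truth: Gompertz(a = 0.485, b = 12.141, c = 0.081)
# driving a 10,000-seed seedbank
cfg    <- sim_config(seed = 42)
report <- run_pipeline(run_config(simulation = cfg))
report
#> Emergence analysis report (season 2019, anchor 2019-06-21, base 21 C)
#>   site_01: total 4877 seedlings over 24 visits
#>     gompertz: a=0.9473 b=12.26 c=0.08333 (R2 1.000)
#>     saturating_exp: a=0.03677 b=1.054 c=0.02114 (R2 0.976)
#>     cdd_at_50: 33.7 degree days (2019-10-05)
#>     cdd_at_75: 64.9 degree days (2019-10-15)
#>     peak window 2019-09-30 to 2019-10-27: 99% of yearly total
#>   rapid change: weeks 40-43
```

Reading this: the simulated seedbank of 10,000 seeds yielded 4,877
seedlings (the truth's asymptote is 0.485). The yearly curve, normalised
by the observed total, puts 50 % of the season's emergence at 33.7 cooling
degree days — October 5 in this simulated year — against a closed-form
truth of `log(12.141/log 2)/0.081 ≈ 35.4` on the truth's own scale.
Emergence changes fastest in weeks 40–43, i.e. mid-October, where a
cooling temperate autumn drives any thermal-time flush.

Individual stages are ordinary functions returning classed objects with
the usual methods:

```r
w    <- simulate_weather(cfg)
tts  <- thermal_time(w, base_temp = 21, anchor_date = "2019-06-21")
recs <- simulate_emergence(w, cfg)
curve <- build_emergence_curve(recs, tts, 2019)
fit   <- fit_emergence(curve, "saturating_exp")
summary(fit); plot(fit)
cdd_at_fraction(fit, c(0.5, 0.75))
```

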