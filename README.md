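# fireardl

Attribution of grassland area burned to climatic drivers in monthly time
series, for fire ecologists and environmental modellers who need more than
ordinary least squares: climatic records mix stationary and stochastically
trending (unit-root) series, and regressions that ignore this produce
spurious relationships. `fireardl` implements the complete inferential
chain that handles it properly:

1. **Unit-root testing** — ADF, Phillips–Perron, KPSS and DF-GLS per
   variable in levels and first differences, with a deterministic
   majority-rule classification into I(0) / I(1) / I(2)+ and a hard stop
   at I(2), where the ARDL framework is invalid.
2. **Lag selection** — log-likelihood/LR, FPE, AIC, SBC and HQ over a
   common estimation sample; consensus is the parsimonious SBC choice.
3. **ARDL bounds cointegration test** — the F-statistic for joint nullity
   of all lagged-level coefficients, compared against *simulated* lower
   (all-I(0)) and upper (all-I(1)) critical bounds; seeded and
   bit-reproducible.
4. **Error-correction model estimation** — least squares of

   Δy_t = α₀ + δ₀ y_{t−1} + Σ_j δ_j x_{j,t−1} + Σ_i α_i Δy_{t−i}
        + Σ_{j,l} β_{j,l} Δx_{j,t−l} + ε_t

   where δ₀ ∈ (−1, 0) is the error-correction (adjustment) speed and
   θ_j = −δ_j/δ₀ the long-run elasticity of driver j, with delta-method
   standard errors, a diagnostic battery (Breusch–Godfrey, ARCH-LM,
   Ramsey RESET, Jarque–Bera, Durbin–Watson) and recursive CUSUM
   stability bands.
5. **Counterfactual shock simulation** — stochastic propagation of the
   fitted recursion under a ±1 SD shock to one driver, summarised as a
   75/90/95% percentile fan with an equilibrium-shift verdict.

A synthetic monthly fire–climate generator with known integration orders,
cointegrating vector and adjustment speed (`xilingol_dgp_config()`) makes
the entire chain testable end to end without observational data.

## Worked example

Simulate an 18-year, eight-driver panel, run the full pipeline, and shock
wind speed by one standard deviation:

```r
library(fireardl)

config <- run_config(
  input = xilingol_dgp_config(n_months = 216),
  response = "area_burned",
  scenarios = list(shock_scenario("wind", n_simulations = 5000)),
  seed = 1)
report <- run_pipeline(config)
report
#> fireardl pipeline report (seed 1)
#>   gate integration: passed - all variables I(0) or I(1)
#>   gate cointegration: passed - bounds decision: cointegrated (F = 38.21)
#>   consensus lag: 1
#>   ECT coefficient: -0.6175  R2: 0.723
#>   bounds F: 38.21 -> cointegrated
#>   CUSUM crossed: FALSE
#>   shift[wind_pos]: 0.6692
```

Both gates pass: every series is integrated below order two, and the
bounds F-statistic (38.21) clears the simulated upper 5% bound, so a
long-run level relationship exists. The error-correction coefficient
−0.62 says 62% of any disequilibrium is corrected each month (the
generator's truth is −0.6). The long-run elasticities recover the
generator's cointegrating vector (wind 2.0, max. temperature 1.0,
sunlight 0.5, carbon emission 0.3):

```r
long_run_multipliers(report$ecm)
#>      regressor estimate std_error
#> 1        t_min -0.03269    0.0438
#> 2 rel_humidity  0.00229    0.0590
#> 3        t_max  1.11118    0.1298
#> 4       precip  0.04015    0.0597
#> 5     sunlight  0.56309    0.0811
#> 6         wind  1.91549    0.1564
#> 7          cem  0.23910    0.0419
#> 8          vpd  0.02211    0.0718
```

Because the model is log–log, coefficients read as elasticities
(`elasticity_statement(1.915, 1)`: "a 1% change in the regressor moves
the response by 1.9%"). The shock fan shows the counterfactual:

```r
report$simulations$wind_pos
#> Shock-response fan: +1 SD permanent shock to 'wind' at t = 10 (5000 simulations)
#>   pre-shock mean: 1.822
#>   equilibrium shift: 0.6692
#>   significant: 75%:TRUE  90%:TRUE  95%:TRUE
```

A permanent +1 SD wind shock raises log area burned by 0.67 at the new
equilibrium — exactly θ_wind × shock in the deterministic limit — and the
shift is significant at all three band levels. `plot(report$simulations$wind_pos)`
draws the dot-and-band fan chart.

A command-line front end wrapping the same functions ships at
`inst/cli/fireardl.R` (subcommands `simulate-data`, `unit-root`, `lags`,
`bounds`, `fit`, `shock`, `run-all`).

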