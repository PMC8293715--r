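# elevrange

Does species range size increase with elevation? `elevrange` implements the
full analytical pipeline used to test **Rapoport's rule** in plot-based
surveys of mountain floras: per-species elevational range estimation,
Stevens' per-plot mean range-size profiles, a Monte-Carlo **mid-domain
effect** null model, per-plot environmental predictor construction, and a
statistical layer of standardized OLS, simultaneous autoregressive (SAR)
error models and repeated random-forest permutation importance. It is aimed
at macroecologists and biogeographers working with plot x species presence
matrices along elevational gradients, and ships a seeded synthetic-community
generator so every stage is testable without field data.

## The statistics at the core

* **Range size**: for species *i*, `R_i = max(e_occ) - min(e_occ)`, the
  difference between the highest and lowest plot elevation where it was
  recorded (singletons have `R_i = 0`).
* **Stevens profile**: for plot *j* and species group *G*,
  `S_j = mean{ R_i : i in G present in j }`, missing (never zero) when no
  species of *G* occurs in *j*. Rapoport's rule is supported when the OLS
  slope of `S_j` on elevation is positive (and significant, by default).
* **Mid-domain null**: each simulation places every empirical range size
  once, midpoint uniform on the feasible interval
  `[low + R/2, high - R/2]`; the per-plot mean size of covering ranges,
  averaged over 1,000 simulations, is the MDE predictor. An exact
  Poisson-binomial expectation (`mde_expected_profile()`) serves as the
  simulator's oracle.
* **Drivers**: eight per-plot predictors — MAT, MAP (mean climate), MATR,
  TS (climate variability), TC, PC (present-minus-LGM change), MDE, POP
  (disturbance) — related to `S_j` by standardized single-predictor OLS,
  by ML SAR error models `y = Xb + u`, `u = lambda W u + e` (symmetric
  kNN weights), and by `%IncMSE = 100 (MSE_perm - MSE_oob) / MSE_oob`
  averaged over repeated random forests.

## Worked example

```r
library(elevrange)

cfg  <- synthetic_config(seed = 42)      # 96 plots, 1800-5400 m, 545 species
comm <- generate_community(cfg)
comm$occ
#> occurrence_data: 96 plots x 545 species; 10601 presences
#> elevations 1800 - 5400 m a.s.l.

ranges <- species_ranges(comm$occ)
prof   <- stevens_profile(comm$occ, ranges, comm$traits, group = "overall")
rapoport_regression(prof)
#>     group slope_m_per_m      se  p_value adj_r2 n_plots supported
#> 1 overall         0.243 0.00284 5.53e-91  0.987      96      TRUE

simulate_mde(setNames(ranges$size, ranges$species_id), c(1800, 5400),
             c(1850, 3600, 5350), n_sims = 1000, seed = 42)
#>   plot_id elevation_m mde_predicted_mean_m mde_se_m n_effective_sims
#> 1    P001        1850                810.2   3.2432             1000
#> 2    P002        3600                927.6   0.5695             1000
#> 3    P003        5350                806.4   3.0950             1000
```

The fitted slope (0.243 m of mean range per m of elevation) recovers the
generator's planted 0.25 m/m, and the reshuffling null shows the expected
mid-domain peak (928 m at the center vs ~808 m near the edges): even with
range size trends absent, boundary constraints alone raise mean range size
mid-gradient, which is why the MDE prediction is carried as a covariate in
the driver analysis.

The complete analysis — synthetic inputs, range profiles, null model,
environmental table, regression tables and importance ranking — lives in
the numbered drivers under `analysis/` (`01_simulate.R` ... `05_inference.R`,
writing to `results/`), or can be run in one call:

```r
run_pipeline(run_config(seed = 1), "results/run")
```

which writes `range_profile.csv`, `env_table.csv`, `table1.csv` (OLS),
`table2.csv` (SAR), `importance.csv`, `rapoport.csv` and a manifest with
per-file checksums; identical configurations reproduce identical files.
User data (plot table, 0/1 occurrence matrix, species traits, station
climate, villages, LGM layers as CSV) runs through the same pipeline with
`run_config(mode = "data", paths = ...)`.

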