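# hyporheos

Streambeds are ecotones: a benthic community in the surface sediments gives
way, somewhere in the first decimetres, to a distinct hyporheic community —
and where that transition sits depends on whether water is welling up from
the aquifer (UW) or being pushed down from the stream (DW). `hyporheos` is
an R package for the full analysis chain of such studies:

* **Heat-tracer hydrodynamics** — estimate diurnal temperature amplitudes
  per sensor and day by harmonic least squares, locate the thermal
  extinction depth, invert amplitude ratios of adjacent sensors for the
  vertical thermal-front velocity (the Hatch amplitude method), and
  classify sites as UW (negative velocity) or DW (positive, i.e. downward
  flux).
* **Size-structured community metrics** — biovolume from body dimensions,
  carbon biomass (protozoa at 0.14 pg C/µm³; invertebrates via fresh mass ×
  0.25 × 0.4), temperature-corrected allometric turnover rates, and
  non-cohort secondary production *P*ᵢ = B̂ × r × Δt summed over weekly
  intervals, plus Shannon–Wiener diversity per 5-cm layer.
* **Community delineation** — Bray–Curtis dissimilarities, a hand-rolled
  ANOSIM with 1000-label-permutation significance, a top-down adjacent-pair
  scan that places the benthos/hyporheos boundary at the shallowest
  significant pair, and UPGMA layer clustering with Newick export.
* **Mixed models** — random-intercept (site) models for log₁₀ biomass,
  log₁₀ production and diversity, WAIC model selection over all
  marginality-respecting term combinations, flat-prior direct posterior
  simulation (5000 draws; means, 95% credible intervals, *P*(β < 0)),
  conditional R², and a Pearson dispersion check.
* **Synthetic data with ground truth** — forward simulators for sensor
  lances (known flux) and layered communities (known decay rates, DW
  effect, planted compositional boundary), so every stage above can be
  benchmarked against truth.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods for fitted objects and `autoplot()` / `plot_*()`
figures.

## Worked example

Recover the flux at a synthetic upwelling site, then delineate the
community boundary of a synthetic downwelling assemblage:

```r
library(hyporheos)

sc <- thermal_scenario(velocity_v = -0.35, site_id = "site_3",
                       noise_sd = 0.01, duration_days = 7, seed = 42)
fits <- fit_diurnal_harmonic(simulate_temperature(sc))
classify_sites(flux_profile(fits))
#> # A tibble: 1 × 4
#>   site_id mean_velocity n_estimates condition
#>   <chr>           <dbl>       <int> <chr>
#> 1 site_3         -0.350          28 UW
```

The simulated truth was −0.35 m/day; averaging the 28 converged
pair-by-day inversions recovers it to three decimals, and the negative
sign classifies the site as upwelling. The diurnal signal dies out between
the 27.5 and 37.5 cm sensors (`thermal_extinction_depth(fits)`), shallower
than at a downwelling site, because upward flow opposes the penetrating
heat wave.

```r
comm <- simulate_community(delineation_scenario(seed = 42))
delineate_boundary(comm, "DW", n_perm = 999, seed = 7)
#> <boundary_result> DW mode = adjacent
#>   boundary at the 15-cm interface (strata 2 | 3), R = 1.000, p = 0.0010
#>   mean Bray-Curtis similarity across the boundary pair: 0.00
```

The scenario plants the DW community turnover at 15 cm; the adjacent-pair
ANOSIM scan finds exactly that interface (ANOSIM R = 1 with the minimum
attainable p at 999 permutations), with essentially no compositional
similarity across it.

```r
b <- biomass_concentration(comm)
fit <- fit_assemblage_model(dplyr::mutate(b, depth = depth_mid_cm),
                            "biomass_mg_l", log10_transform = TRUE)
simulate_posterior(fit, n = 5000, seed = 9)$summary
#> # A tibble: 5 × 5
#>   term        estimate conf.low conf.high prob.negative
#>   <chr>          <dbl>    <dbl>     <dbl>         <dbl>
#> 1 (Intercept)  -3.03   -3.22      -2.85          1
#> 2 depth        -0.0177 -0.0247    -0.0108        1
#> 3 hydroDW       0.149   0.00740   0.288          0.0184
```

Biomass declines with depth (*P*(β_depth < 0) = 1) and is higher under
downwelling, matching the structure the generator planted.

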