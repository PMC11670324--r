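# anoxbal

Carbon and reductant balance accounting for anoxic soil incubations.

`anoxbal` is for biogeochemists and microbial ecologists who run anoxic
slurry microcosms (peat, sediment, rice paddy soil) and need to answer the
bookkeeping questions those experiments pose: how much of the carbon and of
the reducing power released by a consumed substrate is recovered in the
fermentation products and gases that were measured, which products dominate,
what the soil emits in situ, and whether a hypothesised reaction network
could explain the observed product succession at all.

## The accounting model

Every compound is reduced to two integers derived from its molecular
formula:

* a **carbon factor**, the number of C atoms per molecule, and
* a **reductant factor**, the generalised *degree of reduction*
  γ = 4·n<sub>C</sub> + n<sub>H</sub> − 2·n<sub>O</sub> − 3·n<sub>N</sub>,
  the electron equivalents per molecule released on full oxidation to the
  CO₂ / H₂O / NH₃ reference state.

Organic acids are carried as their neutral (protonated) formulas so no
charge term is needed. For the compounds of a typical amino-sugar
fermentation experiment this gives the familiar carbon/reductant pairs
8/32 (N-acetylglucosamine), 2/8 (acetate), 1/2 (formate), 2/12 (ethanol),
3/14 (propionate), 1/8 (CH₄) and 1/0 (CO₂).

Net turnover over a time frame [t₀, t₁] is then computed per analyte as

```
Δ = (mean concentration at t₁) − (mean concentration at t₀)      # μM slurry
net = Δ(treatment) − Δ(matched control)                           # same BES status
carbon turnover    = net × carbon factor                          # μM C
reductant turnover = net × reductant factor                       # μM e⁻
```

and the **recovery (closure) ratio** of a frame is
100 · Σ(positive turnovers) / |Σ(negative turnovers)| on either basis;
100 % means the measured budget closes, values above 100 % are reported
as-is with a flag.

Closed-chamber fluxes use the ordinary least-squares slope of the chamber
mixing ratio (ppmv h⁻¹) converted through the ideal gas law,
F = b·PV/(RTA) in μmol m⁻² h⁻¹, plus CO₂:CH₄ ratio series and the unit
conversions used for slurry incubations (headspace vol% → mmol L⁻¹ slurry;
μM → μmol g⁻¹ dry weight).

Because raw incubation data of this kind are rarely deposited, the package
also ships an element- and electron-balanced kinetic simulator of the
anaerobic food chain — primary mixed-acid fermentation, syntrophic ethanol
oxidation, hydrogenotrophic and aceticlastic and methylotrophic
methanogenesis, hydrogenotrophic acetogenesis, with bromoethanesulfonate
(BES) inhibition of the methanogen-dependent steps — whose trajectories
conserve total carbon and electrons exactly, so every accounting stage can
be verified against known ground truth.

## Worked example

Simulate the standard amino-sugar experiment (500 μM N-acetylglucosamine
± 20 mM BES, triplicates, sampled over 10 days) and run the accounting:

```r
library(anoxbal)
library(dplyr)

model <- fermentation_model(noise_sd = 5)          # 5 μM measurement noise
exp   <- simulate_experiment(model, nag_design(), seed = 42)

nt <- net_turnover(exp$series, exp$design, "NAG")  # frames 0–4, 4–10, 0–10
recovery_ratio(nt)
#>   t_start t_end basis     consumed produced defined recovery_pct exceeds_100
#> 1       0     4 carbon       3997.    3999. TRUE           100.  TRUE
#> 2       0    10 carbon       4007.    4018. TRUE           100.  TRUE
#> 3       4    10 carbon        415.     424. TRUE           102.  TRUE
#> 4       0     4 reductant   15989.   15486. TRUE            96.8 FALSE
#> 5       0    10 reductant   16028.   16103. TRUE           100.  TRUE
#> 6       4    10 reductant    2065.    2643. TRUE           128.  TRUE
```

The 500 μM supplement carries 4 000 μM C and 16 000 μM e⁻; with all major
products measured the budget closes near 100 % on both bases (the 4–10 d
reductant frame exceeds 100 % because little is consumed in that frame and
measurement noise dominates — exactly the situation the `exceeds_100` flag
marks). Acetate dominates the recovered carbon in the fermentation stage:

```r
product_fraction(nt, "acetate", basis = "carbon")
#>   t_start t_end analyte basis  fraction_pct
#> 1       0     4 acetate carbon        68.8
```

A chamber series with a known true flux of 400 μmol m⁻² h⁻¹ is recovered by
the closed-chamber estimator:

```r
ser <- simulate_chamber(true_flux = 400, noise_sd = 5, seed = 42)
tidy(chamber_flux(ser, volume_m3 = 0.05, area_m2 = 0.25))
#>   plot  gas   slope_ppmv_h flux_umol_m2_h stderr r_squared n_points
#> 1 plot1 CO2           47.5           395.   17.8     0.996        4
```

`autoplot()` methods display simulated incubations and chamber fits;
`plot_turnover()` draws the per-frame carbon/reductant bar charts;
`run_pipeline()` drives the whole analysis from a YAML configuration and
writes provenance-stamped CSV reports.

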