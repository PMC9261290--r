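# apcahealth

Source apportionment of fine particles (PM2.5) by **absolute principal
component analysis** (APCA), projection of the apportionment onto
individual-level exposures, and **stratified Cox proportional-hazards**
models for source-specific mortality risks — with a synthetic generator
providing known ground truth for every stage.

## Who this is for

Environmental epidemiologists and exposure scientists who have (a) a
multi-pollutant monitoring campaign — per-site annual means of NO2, BC and
the PM2.5 elemental components Cu, Fe, K, Ni, S, Si, V, Zn plus PM2.5
mass — and (b) a cohort with modelled individual exposures to the same
pollutants and a survival endpoint, and who want health associations for
*source-specific* PM2.5 mass (traffic, residual-oil combustion, crustal
soil, biomass/agriculture, industry, ...) rather than for single tracers.

## The method

APCA proceeds in four steps:

1. z-score the pollutant matrix and run a correlation-matrix PCA;
2. rotate the retained components (Varimax, or Promax with power κ for
   correlated sources) and identify sources from tracer loadings;
3. convert component scores to **absolute** scores by subtracting the
   score of an artificial sample whose raw concentrations are all zero,
   so a zero-concentration record scores exactly zero:
   `APCS = (z - z0) W`, with regression-method weights `W = R⁻¹ P Φ`;
4. regress PM2.5 mass on the absolute scores:
   `PM2.5_i = b0 + Σ_p b_p · APCS_ip`, so `b_p · APCS_ip` is the mass
   contributed by source *p* at record *i* and `b0` is unapportioned mass.

Potassium enters the PCA soil-adjusted (`K_w = K − β̂·Si`, with β̂ the OLS
slope over the lowest decile of K/Si ratios); sulfur stays out of the PCA
and is apportioned afterwards by regression on the source contributions.
The fitted model projects onto cohort exposures with the campaign's stored
standardization, and hazards come from Cox models with age as the time
axis, subcohort × sex strata, and three nested confounder sets.  The joint
model's coefficients combine into a cumulative risk index
`CRI = exp(β̂' x)` at increments `x` (default: per-source IQRs).

## Worked example

```r
library(apcahealth)

prof  <- default_source_profiles()
camp  <- generate_monitoring_campaign(prof, campaign_config(seed = 42))
model <- fit_apca(camp$table)          # Promax, kappa = 1.6, 5 factors
print(model$solution)
```

```
5-factor promax solution (kappa = 1.6)
    traffic  oil  soil industry biomass_agriculture
NO2    0.98 0.03  0.00     0.02                0.00
BC     0.98 0.02 -0.01    -0.01                0.08
Cu     0.95 0.02  0.05     0.08               -0.01
Fe     0.80 0.05  0.34     0.11               -0.02
Kw     0.03 0.01  0.01     0.01                0.99
Ni     0.05 0.98  0.02     0.03               -0.01
Si     0.13 0.03  0.95     0.00                0.01
V      0.02 0.99  0.01     0.01                0.02
Zn     0.11 0.05  0.01     0.95                0.01
eigenvalue (after rotation): 3.72  1.99  1.15  1.02  1.01
cumulative variance: 41.3%  63.5%  76.3%  87.6%  98.8%
```

Each factor is labelled by its dominant tracer (NO2/BC/Cu/Fe → traffic,
Ni/V → residual oil, Si → soil, soil-adjusted K → biomass/agriculture,
Zn → industry).  All rotated eigenvalues exceed 1 and the five factors
explain 98.8% of the variance, so the retention rules are met.  The mass
regression stores slopes `b_p` (µg/m³ of PM2.5 per unit absolute score)
and the unapportioned intercept (5.21 µg/m³ here).

```r
coh  <- generate_cohort(prof, cohort_config(n_participants = 20000, seed = 7))
proj <- project_exposures(coh, model)
cohort <- cbind(coh, setNames(proj$contributions,
                              paste0("pm25_", names(proj$contributions))))
fit <- fit_cox(cohort, paste0("pm25_", model$source_labels), cox_model_spec(3))
print(fit)
cumulative_risk_index(fit)
```

```
multisource Cox fit (model 3): n = 20000, events = 2359, person-years = 209443
  pm25_traffic             HR/unit 1.016 (1.001-1.031)   HR/IQR(2.98) 1.049
  pm25_oil                 HR/unit 1.017 (0.916-1.129)   HR/IQR(0.39) 1.007
  pm25_soil                HR/unit 0.976 (0.940-1.013)   HR/IQR(1.23) 0.970
  pm25_industry            HR/unit 1.029 (0.997-1.062)   HR/IQR(1.21) 1.035
  pm25_biomass_agriculture HR/unit 1.012 (1.003-1.022)   HR/IQR(3.69) 1.047
Cumulative risk index: 1.110 (95% CI 1.029-1.198) at increments
  pm25_traffic=2.98, pm25_oil=0.39, pm25_soil=1.23, pm25_industry=1.21,
  pm25_biomass_agriculture=3.69
```

Hazard ratios are reported per 1 µg/m³ and per IQR of each projected
source exposure; the CRI of 1.110 summarizes the joint association of all
five sources at one IQR each.  (Estimates on *projected* exposures are
attenuated relative to the generating hazards by apportionment and
measurement error — see the vignette.)

`run_apportionment()` and `run_health_analysis()` orchestrate the same
steps from a `pipeline_config()`, including the stratified fivefold
robustness evaluation (`kfold_robustness()`), and stamp outputs with a
configuration hash and seed for byte-identical reruns.

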