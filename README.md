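# riceSiDyn

Whole-plant silicon dynamics in rice: a hydraulic-network simulation of Si
uptake, transport, and the diurnal regulation of root Si transporter
expression, with an investment-efficiency analysis and Bayesian calibration
of the root transport parameters.

## The scientific problem

Rice takes up large amounts of silicon through the root transporters
Lsi1/Lsi2, distributes it preferentially toward young tissue at the stem
nodes, and down-regulates transporter expression both diurnally and as Si
accumulates in the shoot. Why would a plant switch off transporters for a
nutrient with no known excess toxicity? This package implements a
whole-plant model to study that question for plant physiologists and crop
modelers:

* **Water**: xylem and phloem as coupled resistor networks over hydraulic
  nodes (electric-circuit analogy). Axial xylem flow follows water-potential
  differences, `J = -(Ψ_j - Ψ_i)/r`; phloem flow follows hydraulic pressure
  `P = Ψ_P - Π` with osmotic potential `Π = -R·T·C_S`; node-wise balance
  `ΣJ_W = 0` is solved as one linear system per time step.
* **Carbon**: leaf starch fed by photosynthesis, first-order conversion to
  sucrose (`k4`), phloem loading, upwind advection, first-order respiration
  (`k1`) — the engine behind the diurnal phloem-flow cycle.
* **Silicon**: a two-compartment root model across the Casparian bands
  (`J = α·tr·C − p_cm·ΔC`, with expression factor `α ∈ [0,1]`), advection
  with the transpiration stream, enrichment by factor `ρ` into the diffuse
  vascular bundle at each stem junction, and first-order unloading into
  tissue cells.
* **Signaling**: a shoot-borne substance generated under one of three
  hypotheses — leaf-Si *accumulation*, leaf-Si *shortage*, or *water stress*
  (transpiration) — transported down the phloem, decaying at rate `dec`, and
  mapped to `α` at the root (with a 5-h delay for water stress).
* **Investment efficiency**: `IE = ∫ J_unload(top leaf) dt / ∫ α dt` — Si
  delivered to the youngest leaf per unit of integrated transporter
  expression — compared across expression-control sensitivities.
* **Calibration**: adaptive Metropolis–Hastings estimation of
  `(tr_exo, tr_end, p_cm)` from xylem-sap Si time series, with a synthetic
  series generator for testing.

## Worked example

```r
library(riceSiDyn)

cfg <- default_config()
g   <- build_standard_plant(cfg)         # 1 root, 5 junctions+sheaths+leaves
f   <- generate_standard_forcing(days = 4, config = cfg)

traj <- run_simulation(g, f, control_config("constant"), cfg)
print(traj)
#> trajectory: 4 day(s), 1921 records, dt = 0.05 h, mode = constant
#>   alpha range: 1 1
#>   cumulative soil Si uptake: 50.304 umol

efficiency_experiment(g, f, cfg)
#>        setting         ie ie_change_vs_constant_pct night_day_ratio_pct
#> 1     constant 0.01223507                  0.000000            71.42857
#> 2          low 0.01288241                  5.290822            59.21525
#> 3 intermediate 0.01388299                 13.468785            43.41757
#> 4         high 0.01632186                 33.402261            14.77287
```

Reading the table: under constant expression the night/day investment ratio
is exactly 10/14 = 71.4% (forced by the 14-h/10-h photoperiod). As the
expression response to water stress sharpens (`dec = 0.2` with
`slp_J = 0.05 → 0.1 → 0.2`), nighttime expression is cut when the slow
nighttime xylem stream would waste it, the nighttime investment share falls
(59% → 15%), and the investment efficiency rises by 5.3%, 13.5%, and 33.4%
over the constant-expression run.

Calibration on a synthetic xylem-sap series:

```r
d    <- generate_synthetic_series(c(0.5, 1.0, 0.05), seed = 42)  # 5-min grid
post <- run_mcmc(d, n_iter = 60000, seed = 7)
credible_interval(post)     # wide along the tr_end / p_cm trade-off ridge
```

A thin command-line front end over the same functions lives at
`inst/cli/ricesidyn.R` (subcommands `simulate`, `efficiency`, `scan-carbon`,
`generate-forcing`, `calibrate`).

## Documentation

The methods vignette (`vignettes/silicon-dynamics.Rmd`) describes the model
equations, the unit conventions, the defaults that are package choices and
why, the numerical scheme, and known limitations.
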