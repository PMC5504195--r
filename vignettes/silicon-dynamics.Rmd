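---
title: "Whole-plant silicon dynamics: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plant silicon dynamics: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceSiDyn)
```

riceSiDyn simulates silicon (Si) transport through a whole rice plant and the
regulation of the root Si transporters (the Lsi1/Lsi2 family, aggregated into
two lumped transport capabilities). This vignette is the package's account of
the model itself: the governing equations, the parameters that matter and why
their defaults are what they are, what the synthetic inputs do and do not
emulate, and the numerical and design decisions a maintainer should know
about.

## The hydraulic circuit

The plant is discretized into *hydraulic nodes* — one root segment, a stem
junction per leaf, a sheath per leaf, and five leaf blades — connected by a
xylem resistor network and a phloem resistor network that are coupled
laterally at every node (`build_standard_plant()`). Water flow is treated by
the electric-circuit analogy:

* axial xylem flow between nodes $i,j$: $J_{W(i,j)X} = -(\Psi_{X(j)} -
  \Psi_{X(i)})/r_{X(i,j)}$;
* lateral flow at node $i$: $J_{W(i)Lat} = -(\Psi_{P(i)} -
  \Psi_{X(i)})/r_{Lat(i)}$;
* axial phloem flow follows the hydraulic pressure $P_P = \Psi_P - \Pi$,
  with osmotic potential $\Pi = -R\,T\,C_S$ (van 't Hoff; sucrose $C_S$ in
  mol m$^{-3}$ gives $\Pi$ in Pa, stored as MPa).

At every node the flows must balance ($\sum J_W = 0$). Because $\Pi$ is fixed
within a time step, the balance is *linear* in the potentials: the osmotic
terms move to the right-hand side and the coefficient matrix depends only on
the network. `water_system()` therefore factors the matrix once per
simulation and `solve_water()` reuses it every step — a quasi-static solve
with no water capacitance, which is the circuit analogy taken at face value.
The boundary condition is a fixed soil water potential behind a root radial
resistance plus prescribed transpiration sinks at the leaf xylem nodes.

Gravity is neglected (short plant), as is lateral sucrose flow.

## Carbon: starch, sucrose, and the dawn collapse

Per leaf, photosynthesis feeds a starch pool which converts to sucrose at
first-order rate `k4`; the sucrose loads into the leaf phloem, advects with
the phloem stream (first-order upwind on the network, sieve-tube volumes as
mixing volumes), and every node's pool respires at first-order rate `k1`.
This is the minimal source-sink carbon formulation compatible with the rest
of the framework — a leaf starch buffer, first-order conversion, loading,
advection, respiration — and it is the package's own.

The unit conventions for `k1` and `k4` are a package decision. We take `k4`
per hour: at `k4 = 0.1` the starch pool drains with a ~10-h time constant,
which is what produces the overnight starch rundown, the collapse of the
leaf-to-root phloem flow around dawn, and hence the diurnal phase structure
of the signal (below). We take `k1` per second (converted by 3600
internally), consistent with the boundary rates being quoted per second: at
`k1 = 8\times10^{-5}` s$^{-1}$ the whole-plant sucrose pool relaxes in a few
hours and the daily sucrose cycle becomes stationary by day 3 of a 4-day run
— the stable cyclic regime that `scan_carbon_stability()` classifies. Read
per hour instead, no value on the standard scan grid could reach a stable
cycle within 4 days (the relaxation time would exceed 10,000 h), so the
per-second reading is the only one that makes a stable cycle attainable at
all. `detect_cyclic_stability()` compares the last two daily cycles in
relative L$\infty$ (default tolerance 2%) and separates `cyclic_stable`,
`drifting`, and `decaying` regimes.

## Silicon

The root is a two-compartment model across the Casparian bands:
exodermal influx $J_{M(o:c)} = \alpha\,tr_{exo}\,C_{M:out} -
p_{cm}(C_{M:cor} - C_{M:out})$ and endodermal transfer $J_{M(c:s)} =
\alpha\,tr_{end}\,C_{M:cor} - p_{cm}(C_{M(nr)} - C_{M:cor})$, where $\alpha
\in [0,1]$ is the transporter expression factor applied identically to both
capabilities. In the xylem, Si moves only with positive
(rootward-to-shootward) water flow, $J_M = C_M J_{WX}$; reverse flow carries
none. At each stem junction the stream splits between the enlarged vascular
bundle (EVB, feeding that junction's leaf) and the diffuse vascular bundle
(DVB, feeding younger tissue above; for the highest junction, the top leaf).
The DVB branch is enriched by $\rho \ge 1$:

$$C_{EVB} = \frac{(J_{DVB} + J_{EVB})\,C_M}{\rho J_{DVB} + J_{EVB}}, \qquad
  C_{DVB} = \rho\,C_{EVB}.$$

An alternative form of this partition rule attaches $\rho$ to the EVB flow
in the denominator instead; that variant violates Si mass balance at the
junction whenever the two branch flows differ (its branch indices appear to
have been swapped somewhere in transmission), so the conservation-consistent
form above is the default and the alternative is available behind
`use_alt_partition_denominator` for comparison. Each node also unloads Si
into its tissue cells at $J_{unload} = k_{M:unload} C_M V_{con}$ — linear,
uncapped, a terminal sink (no silica polymerization kinetics).

Everything is advanced by a flux-based explicit Euler update: every edge flux
is removed from its donor and added to its receiver, so the whole-run Si
ledger (cumulative soil influx vs. change in total plant Si) closes to
machine precision, and the test suite checks it. The root stele's mixing
volume is its sieve-tube tissue volume by default
(`use_vst_for_root_stele`), with the conduit volume available as a switch.

## The signaling substance and expression control

A shoot-to-root signal of arbitrary units is generated in the leaves,
advected with the phloem stream (same upwind kernel as sucrose), and decays
at rate `dec`. Three generation hypotheses are implemented
(`generation_rate()`):

* **accumulation**: $GR = slp_c\,C_{M(cyt)}$ — the signal reports leaf Si
  excess; expression is repressed, $\alpha = \max(0, 1 - C_R(nr, t-\chi))$;
* **shortage**: $GR \propto slp_r\,(1 - C_{cyt}/C_{ref})$ — the signal
  reports leaf Si deficit; expression is activated, $\alpha = \min(1,
  C_R(nr, t-\chi))$;
* **water stress**: $GR = slp_J\,Trans$ — expression is repressed with a
  response delay $\chi = 5$ h (the other modes use $\chi = 0$).

Two scale choices here are ours, and they matter:

* The deficit $(1 - C_{cyt})$ only makes sense with $C_{cyt}$ on a unit
  scale; we divide by a reference concentration $C_{ref}$ (by default the
  end-of-run mean leaf-cell Si of a constant-expression reference run on the
  same forcing, computed automatically) and floor the rate at zero. The
  driver then multiplies the dimensionless deficit back by $C_{ref}$, which
  puts shortage generation on the same concentration scale as accumulation —
  so one `slp` magnitude serves both laws.
* The signal's units are arbitrary by construction, so the transpiration
  entering the water-stress law carries a configurable unit scale
  (`trans_signal_scale`, default 18 per ml h$^{-1}$). This constant, together
  with the unloading rate `k_m_unload = 0.6` h$^{-1}$, was fixed *once* so
  that the standard simulation operates in the regime where the three
  sensitivity settings of the efficiency experiment produce gains of the
  observed order; neither value is revisited per experiment.

The delay $\chi$ is realized by recording the root signal history and
linearly interpolating at $t - \chi$; pre-simulation history equals the
initial condition. Shortage control starts from $C_R = 1$ (expression fully
on); the repressive modes start from $C_R = 0$.

The diurnal phases emerge from the transport dynamics rather than being
imposed: overnight the starch rundown flattens the phloem pressure gradient,
delivery of signal to the root stalls, and the root signal decays — giving
dawn minima (shortage), dusk maxima (root signal under accumulation),
signal pooling in the leaf at dawn (top-leaf maxima), and night expression
troughs under water-stress control (dusk generation peak + transport lag +
5-h delay). The phase tests allow a tolerance of about the signal time
constant $1/dec = 5$ h around nominal dawn/dusk, because the morning phloem
recovery (starch rebuilding from lights-on) lags the photoperiod boundary by
design.

## Investment efficiency

Investment efficiency over a window is
$IE = \int J_{M(top)unload}\,dt \,/\, \int \alpha\,dt$ — Si delivered to the
top leaf per unit of integrated transporter expression — computed by
trapezoidal quadrature on the recorded grid. The expression integral is also
split into light- and dark-period investment; each inter-sample interval is
attributed to the day mask at its left endpoint, so with the default grid the
14 h/10 h photoperiod split is exact and a constant-$\alpha$ run yields a
night/day investment ratio of exactly $10/14 = 71.4\%$, independent of every
other parameter. `efficiency_experiment()` contrasts constant expression
with the low/intermediate/high water-stress sensitivities
(`dec = 0.2`, `slp_J = 0.05, 0.1, 0.2`) on identical forcing.

The mechanism behind the efficiency gain: at night transpiration is 10% of
standard, the xylem conveyor is slow, and Si pumped into the stele is mostly
unloaded into root tissue rather than reaching the top leaf. Expression that
switches off at night therefore saves investment with little cost to
top-leaf delivery.

## Boundary conditions

`generate_standard_forcing()` produces the artificial cycle: 14-h light,
10-h dark; transpiration and photosynthesis share a trapezoidal shape that
rises linearly from lights-on to a 2-h flat peak centered on midday and
falls to lights-off. The trapezoid is the package's chosen idealization of a
clear day (the shape function is internal and replaceable). Transpiration
peaks at the standard 0.4 ml cm$^{-2}$ day$^{-1}$ with a night floor of 10%
of standard; photosynthesis peaks at the standard 0.0015, treated as a
model-unit constant per leaf per hour rather than converted from a
per-area-per-second rate (taken literally such a rate would be implausible
as net assimilation); temperature is constant at 298.15 K.
`read_field_forcing()` converts eddy-covariance measurements instead:
transpiration from latent heat flux via the latent heat of vaporization,
photosynthesis from $-$NEE clipped at zero, linear interpolation across gaps
— assuming soil evaporation and heterotrophic respiration are negligible.

## Calibration of the root transporters

`forward_xylem_series()` predicts the xylem-sap Si concentration of a
seedling moved into 1.0 mM Si solution ($\alpha = 1$, cortex starting at
0.0 mM, stele turning over toward the shoot at a constant rate
`k_efflux = 0.2` h$^{-1}$ — a sealed stele could not produce the saturating
sap curves, and the choice of a constant turnover is ours). The
two-compartment system is linear, so it is solved exactly via the
eigendecomposition of its rate matrix (RK4 covers the degenerate corner).
The likelihood is independent Gaussian with the per-time standard deviations
of the data, using the standard normal-density normalization.

Real 5-min xylem-sap series are rarely redistributable, so
`generate_synthetic_series()` emulates one: forward trajectory plus
independent Gaussian noise (5% proportional with a 2%-of-peak floor by
default), with $\sigma_t$ stored alongside. All calibration tests run on
synthetic data; `read_calibration_csv()` accepts real measurements.

`run_mcmc()` is random-walk Metropolis under bounded uniform priors
(defaults span roughly two orders of magnitude around plausible values).
The three parameters trade off along a long, nearly flat likelihood ridge —
different $(tr_{exo}, tr_{end}, p_{cm})$ triplets produce near-identical sap
curves at realistic noise — so plain isotropic proposals mix far too slowly
to cover it. During burn-in (default 50%) the sampler therefore learns its
proposal covariance from the chain history (scaled $2.38^2/d$) while tuning
a global step factor toward 20–40% acceptance, and starts from the posterior
mode located by bounded optimization. With that, 95% credible intervals are
honestly wide along the ridge and cover the generating parameters at close
to nominal rate, which the test suite verifies on 20 replicate synthetic
fits.

## Numerical choices and degenerate inputs

* Explicit Euler, default `dt = 0.05` h; the test suite verifies that
  halving `dt` changes end-of-run state by well under 1%. Pools that
  undershoot zero by less than 1% of their prior value are clipped to zero
  (with a warning); larger overshoot aborts with advice to reduce `dt`.
* Junction partitioning with both branch flows zero returns the incoming
  concentration unchanged (with a warning) — no flow, no partition.
* A hydraulically isolated node makes the water system singular and is
  reported as a structural error; `validate_graph()` catches disconnected
  pathway subgraphs before a run starts.
* Expression clamps to $[0,1]$ on both sides even for degenerate signal
  histories.
* Problem sizes in the shipped tests: 1- to 4-day runs of the 16-node
  standard plant at `dt = 0.05` h; the carbon scan covers its full standard
  10 × 3 parameter grid; sampler checks use 20 replicate fits of 60,000
  iterations on 240-point series.

## What the synthetic inputs do not emulate

The artificial forcing is a clean trapezoid: real canopies have cloud
flecks, humidity transients, and day-to-day variation (the field reader
exists for exactly that reason). The plant is a single rice tiller with
fixed biomass: no growth, no tillering, no reproductive-stage stem
carbohydrate storage or remobilization, and one root segment rather than an
architecture. Si deposition is a linear, uncapped sink. Absolute water-flow
magnitudes are deliberately not calibrated to any particular plant — the
resistances and volumes here were chosen once to put potentials, phloem
flows, and sucrose concentrations in physiologically sensible ranges
(potentials of a few tenths of MPa to ~2 MPa, phloem flows of order
1 ml h$^{-1}$) and to place the efficiency experiment in its qualitative
regime. Passing tests therefore certify the model's internal structure —
conservation, phases, orderings, calibration machinery — not quantitative
agreement with any particular field plant.

## A short session

```{r example, eval = FALSE}
cfg <- default_config()
g <- build_standard_plant(cfg)
f <- generate_standard_forcing(days = 4, config = cfg)

traj <- run_simulation(g, f, control_config("water_stress",
                                            slp = 0.2, dec = 0.2), cfg)
investment_efficiency(traj)

efficiency_experiment(g, f, cfg)   # constant vs low/intermediate/high
```
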