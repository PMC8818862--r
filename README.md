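# pumpleak

Pump-leak modelling of monovalent ion and water homeostasis in animal cells.

Cell volume is not an independent variable: it follows from the balance of
Na⁺, K⁺ and Cl⁻ fluxes across the plasma membrane and from two constraints
that hold at every instant — macroscopic electroneutrality and osmotic
balance with the medium. `pumpleak` implements this whole-cell
electrochemical model for cells such as U937 lymphoid cells and uses it to
study how ionic homeostasis rearranges after a hyperosmolar challenge:
regulatory volume increase (RVI) in media supplemented with NaCl, and the
apoptotic-like volume decrease (AVD) in media supplemented with sucrose.
It is intended for cell physiologists who want to ask *which* changes in
channels or transporters can account for an observed volume response,
without invoking unmeasured signalling.

## The model

State: intracellular contents `q_Na, q_K, q_Cl` per unit of membrane-impermeant
osmolyte A (mean valence `z`), and cell water `V/A`. Constraints:

    [Na]i + [K]i − [Cl]i + z·(A/V)·1000 = 0                 (electroneutrality)
    [Na]i + [K]i + [Cl]i + (A/V)·1000 = [Na]o + [K]o + [Cl]o + [B]o   (osmotic)

Five transport pathways, each with a single rate coefficient:

* **Channels** (Goldman–Hodgkin–Katz electrodiffusion), e.g. for Na⁺
  `J = pNa·u·([Na]i·e^u − [Na]o)/g`, `g = 1 − e^u`, with `u = U/26.7` the
  dimensionless membrane potential at 37 °C;
* **Na/K pump**: Na⁺ efflux `−β[Na]i`, K⁺ influx `β[Na]i/γ` (γ = 1.5, the
  3Na:2K cycle);
* **Cotransporters** (SLC12 family, electroneutral):
  `J_NC = inc·([Na]o[Cl]o − [Na]i[Cl]i)`,
  `J_KC = ikc·([K]o[Cl]o − [K]i[Cl]i)`,
  `J_NKCC = inkcc·([Na]o[K]o[Cl]o² − [Na]i[K]i[Cl]i²)`.

The membrane potential is not a dynamical variable: at every instant `u` is
solved from the zero-net-charge-flux condition over channels plus pump
(cotransporters carry no charge), which preserves bulk electroneutrality
exactly along the motion. The three content ODEs are integrated in compiled
code with the water volume re-equilibrated from osmotic balance at each step.

The package's fitting function inverts the resting state: given measured
`[Na]i, [K]i, [Cl]i`, `V/A` and `β` plus an assigned cotransporter set, it
recovers `z` and the impermeant-osmolyte concentration in closed form and
solves the three linear steady-state equations for the channel
permeabilities `pNa, pK, pCl`.

## Worked example

```r
library(pumpleak)

# fit the model to U937-like cells resting in a normal 310 mOsm medium,
# with the full NC + KC + NKCC cotransporter set and resting U = -45 mV
mod <- fit_pump_leak(u937_measurement(), inc = 7e-5, ikc = 8e-5,
                     inkcc = 8e-9, U = -45.0)
mod
#> Pump-leak cell model (balanced-state fit)
#>   resting U -45.0 mV; z -1.75; [A] 80 mM; V/A 12.5 ml/mmol
#> Transport parameters:
#>   channels  pna 0.0017013, pk 0.011482, pcl 0.0110168 (min^-1)
#>   pump      beta 0.039 min^-1, gamma 1.5
#>   cotransport  inc 7e-05, ikc 8e-05 (ml/umol/min), inkcc 8e-09 (ml^3/umol^3/min)
```

The fit says: to hold 38/147/45 mM Na/K/Cl at −45 mV with this pump and
cotransport, the membrane must have Na, K and Cl permeabilities of about
0.0017, 0.0115 and 0.011 min⁻¹. The impermeant osmolytes (80 mM) carry a
mean charge of −1.75.

```r
run_scenario("nacl100")       # +100 mM NaCl, parameters unchanged, 4 h
#> Scenario nacl100 (240 min, 510 mOsm): weak RVI
#>   V/A 7.78 ml/mmol (post-jump 7.6, ratio 1.024); U -48.9 mV
#>   [Na]i 90.8, [K]i 212, [Cl]i 78.3 mM

run_scenario("sucrose180_incx10")  # +180 mM sucrose with NC x10 at the jump
#> Scenario sucrose180_incx10 (240 min, 490 mOsm): RVI
#>   V/A 8.62 ml/mmol (post-jump 7.91, ratio 1.090); U -47.8 mV
#>   [Na]i 109, [K]i 180, [Cl]i 85.5 mM
```

After the +100 mM NaCl jump the cell shrinks osmotically to V/A 7.60 and
then partially re-swells to 7.78 (a weak RVI) by taking up Na⁺ and Cl⁻
while losing some K⁺. In sucrose the same membrane produces an AVD instead;
only an increased NC cotransport rate converts it into an RVI. Flux
decompositions per pathway (the `flux_table()` below), unidirectional
influx/efflux splits, electrochemical driving forces and full trajectories
(`simulate()`, `plot()`) are available throughout:

```r
flux_table(mod$state, mod$params, mod$medium)
#> Flux decomposition at U = -45.0 mV (u = -1.6854)
#>  ion pathway influx  efflux     net
#>    k channel 0.1378 -0.6473 -0.5095
#>    k    pump 0.9880  0.0000  0.9880
#>    ...
#> Total net: Na -0.0000, K 0.0000, Cl -0.0000; OSOR 3.54
#> mu (mV): Na -79.8, K 41.3, Cl 19.7 | NC -60.1, KC 61.0, NKCC 0.9
```

A thin command-line interface covers the same operations
(`inst/exec/pumpleak simulate|steady-state|fit-params|scenario|fluxes`),
driven by flat YAML configurations using the model's symbol names
(see `inst/extdata/table2_full_set.yaml`).

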