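# biobattery

Zero-dimensional mechanistic simulation of a **phenazine-producing
*Escherichia coli* anolyte coupled to a redox-flow-battery half-cell** — a
"bio-battery" in which an engineered microbe synthesises (and regenerates)
the soluble redox mediator that carries charge to the anode.

The package is aimed at bioelectrochemistry and systems-biology researchers
who want to screen microbial anolyte designs *in silico*: how do mediator
production strength, inoculum size, phenazine toxicity and mediator
stability jointly constrain current density, cumulative charge and
cycle-to-cycle capacity?

## The model

A well-mixed anolyte with state `X` (biomass, gDW L⁻¹), `S` (substrate,
mmol L⁻¹) and the two phenazine pools `P_red`, `P_ox` (mmol L⁻¹), with
`P_tot = P_red + P_ox`:

- **Monod uptake** `q_S = q_S,max · S/(K_S + S)` and base growth
  `μ_base = Y_X/S · q_S`;
- **Hill-type toxicity** scaling growth by
  `f_tox = 1 / (1 + (P_tot/K_inh)^n_inh)` — phenazines such as pyocyanin
  inhibit their producers at micromolar concentrations, so
  `μ = μ_base · f_tox`;
- **Luedeking-Piret production** `r_prod = (α_P μ + β_P) X`, primarily
  growth-associated (`β_P = 0` by default);
- **first-order mediator degradation** `k_deg` acting on both pools;
- **electrode oxidation** `v_elec = k_elec · P_red`, converted to a current
  density `j = n F v_elec / (A · 1000 · 3600)` (A m⁻²);
- **Nernstian anode potential**
  `E_an = E°_an + (RT/nF) ln(P_ox/P_red)`, an ideal cathode at fixed
  `E_cath`, and a lumped area-specific ohmic loss:
  `V_cell = (E_cath − E_an) − j·R_ohm`.

Balances: `dX/dt = μX`, `dS/dt = −q_S X`,
`dP_red/dt = r_prod − v_elec − k_deg P_red`,
`dP_ox/dt = v_elec − k_deg P_ox`. The system is integrated with the
explicit Euler scheme (`Δt = 0.01` h by default). Charge–discharge cycling
imposes a constant recharge current density with a discharge voltage
cut-off; design sweeps, sensitivity curves and redox-speciation analyses
are built on top. The microbial subsystem (including a cumulative-capacity
variable) can be exported as **SBML Level 2 Version 4** and cross-simulated
with a bundled generic rate-rule integrator.

## Worked example

```r
library(biobattery)
mp <- microbial_params()      # Monod / Luedeking-Piret / Hill baseline
ep <- electro_params()        # half-cell constants
traj <- simulate_batch(anolyte_state(X = 0.05, S = 20), mp, ep,
                       termination_spec(t_max = 200))
print(traj)
#> bb_trajectory: 20001 states over 200.00 h (dt = 0.01 h, mode = discharge)
#>   terminated by: max_time
#>   peak j = 0.0002804 mA/cm^2, avg j = 5.789e-06 mA/cm^2, charge = 0.01158 A h/m^2
```

The batch run peaks at `0.28 × 10⁻³ mA cm⁻²` shortly after inoculation and
declines through the `0.25 × 10⁻³` range as substrate depletion, mediator
degradation and toxicity set in — a low-power but self-sustained operating
regime. Cycling the same design shows capacity rising over early cycles and
then plateauing at the recharge-limited value:

```r
cycles <- run_cycling(anolyte_state(X = 0.05, S = 20), mp, ep,
                      cycling_params(n_cycles = 10))
round(cycles$Q_k_Ah_m2, 5)
#>  [1] 0.00106 0.00313 0.00565 0.00707 0.00674 0.00525 0.00449 0.00449 0.00449
#> [10] 0.00449
```

SBML export and validation:

```r
doc <- export_sbml(sbml_model_spec(mp, ep, anolyte_state()))
validate_sbml(doc)
#> $errors     character(0)
#> $warnings   character(0)
```

A command line mirrors these operations
(`batch | cycle | sweep | sensitivity | export-sbml`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","biobattery.R",package="biobattery"))')" \
    batch --config my_run.yaml --out results/
```

Configuration is one YAML file with nested blocks (`microbial`, `electro`,
`initial`, `termination`, `cycling`, `sweep`, `sensitivity`); unknown keys
are rejected, every output carries a JSON metadata sidecar with the fully
resolved parameter set, and identical configurations produce bit-identical
outputs (the model is deterministic).

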