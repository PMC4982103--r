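# chelapower

Quantitative analysis of the catalytic power of **magnesium chelatase**, the
three-subunit (ChlI/ChlD/ChlH) AAA+ motor enzyme that inserts Mg²⁺ into a
porphyrin ring — the first committed step of chlorophyll biosynthesis. The
package is aimed at enzymologists and systems biologists who want to
reproduce, perturb or extend the chain of reasoning that turns a handful of
measured constants into headline statements about an ATP-coupled enzyme:
how much it accelerates its reaction, how tightly it must bind the
transition state, and how far from equilibrium it can hold its product.

## The quantities at the core

The uncoupled chelation reaction Mg²⁺ + D_IX ⇌ MgD_IX is strongly
unfavorable (association constant K_eq ≈ 10⁻⁶ M⁻¹). From the first-order
dechelation constant k_dechel, fitted through the origin from initial rates
(k = Σcᵢrᵢ/Σcᵢ²), microscopic reversibility gives the uncatalyzed
second-order chelation constant and from it everything else:

| quantity | definition | units |
|---|---|---|
| uncatalyzed constant | k_uncat = K_eq·k_dechel | M⁻¹s⁻¹ |
| rate enhancement | k_cat / k_uncat | M |
| catalytic proficiency | (k_cat/(K_m^DIX·K_0.5^Mg)) / k_uncat | M⁻¹ |
| transition-state K_TX | 1 / proficiency | M |
| uncatalyzed half-time | ln 2 / (k_uncat·[Mg²⁺]) | s |
| displacement factor | ([MgD]/([D][Mg²⁺]))_ss / K_eq | — |
| displacement ΔG | RT·ln(displacement factor) | kJ·mol⁻¹ |

The steady-state ratio comes from a saturation-kinetics ODE model of the
assay (product formation balanced against uncatalyzed dechelation, with
nucleotide depletion and a PEP/pyruvate-kinase ATP-regeneration system), and
the 15:1 ATP:product stoichiometry is interpreted through a stochastic
model in which each hydrolysis cycle succeeds in inserting a magnesium with
probability 1/15 (geometric waiting times). See the methods vignette
(`vignettes/catalytic-power.Rmd`) for the model, its assumptions and the
design decisions.

## Worked example

```r
library(chelapower)

rep <- power_report(chela_params(), thermo_context(),
                    cond = chela_conditions(D_total_M = 2.5e-6, ATP0_M = 5e-3))
print(rep)
#> Catalytic power report (rendered at 1 sig. fig.)
#>   k_uncat           3e-11 M^-1 s^-1
#>   rate enhancement  4e+08 M
#>   proficiency       3e+16 M^-1
#>   K_TX              3e-17 M
#>   t1/2 (at 0.001 M Mg) 7e+05 yr
#>   dG standard       40 kJ/mol
#>   displacement      1e+09 fold, 50 kJ/mol
```

Reading the report: the uncatalyzed chelation constant is ~3×10⁻¹¹ M⁻¹s⁻¹,
so at 1 mM Mg²⁺ uncatalyzed insertion would take ~0.7 million years
(half-time); the enzyme accelerates the reaction 4×10⁸-fold (in M) with a
catalytic proficiency of 3×10¹⁶ M⁻¹, i.e. an attomolar transition-state
dissociation constant (3×10⁻¹⁷ M); and at 2.5 µM total porphyrin the
ATP-clamped steady state sits ~10⁹-fold (~50 kJ·mol⁻¹) above the chemical
equilibrium. Values are stored at full precision; the printed rendering
rounds to one significant figure by default (`sig_figs` to change).

Other entry points:

```r
# fit the dechelation constant from a synthetic initial-rate experiment
ex  <- generate_dechelation_experiment(seed = 42)
fit_first_order_constant(ex$rates)
#> First-order dechelation fit (n = 6)
#>   k_dechel = 3.131e-05 +/- 2.8e-07 s^-1

# simulate the regenerated assay and measure plateau maintenance
pre <- chela_preset("fig2b")
pc  <- simulate_progress(pre$params, pre$conditions, pre$t_end_s, pre$n_out)
steady_state_maintenance_time(pc)$duration_s / 3600   # 7.42 h

# probabilistic ATP coupling
simulate_coupled_cycles(stoichiometry_to_probability(15), 1e5, seed = 1)
#> Coupled-cycle simulation: p = 0.06667, 100000 products, 1498585 cycles
#>   ATP per product: 14.986 +/- 14.457 (mean +/- SD)
```

A thin command-line front end over the same functions is installed at
`inst/scripts/chelapower.R` (subcommands `simulate`, `steady-state`,
`fit-dechel`, `initial-rate`, `power`, `coupling`, `synth`, `run`).

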