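# lfcrtemp

Temperature-response analysis for hybrid linear flow channel reactors
(LFCRs) — channel bioreactors in which sulphate-reducing bacteria (SRB) in
an anoxic bulk convert sulphate to sulphide, and sulphide-oxidising
bacteria at the quiescent surface deposit elemental sulphur into a
harvestable floating sulphur biofilm (FSB). The package is aimed at
bioprocess researchers studying how such semi-passive mine-water treatment
systems respond to cooling: it turns per-port reactor time series, biofilm
harvest records and amplicon (ASV) count tables into per-stage rates,
stoichiometric flux partitions, Arrhenius activation energies with a
critical temperature, sulphur mass balances and community-shift summaries
— and it ships a mechanistic simulator so the whole chain is testable
without any external data.

## The analysis in brief

At pseudo-steady state in a well-mixed reactor with hydraulic residence
time HRT and feed sulphate C_feed, the conversion X = (C_feed − C_res)/C_feed
gives the volumetric sulphate reduction rate

    VSRR = X · C_feed / HRT        (mmol/L·h)

and the shortfall of measured dissolved sulphide HS against the expected
1:1 sulphide yield gives the volumetric sulphide oxidation rate
VSOR = (X·C_feed − HS)/HRT. Temperature dependence is modelled by the
Arrhenius law

    ln k = ln A − (Ea/R) · (1/T)

fitted by least squares in one or two segments; with two segments the
critical temperature T_crit is the intersection of the warm (adapted) and
cold (stress) lines, and Ea = −slope·R. Lactate flux is partitioned using
the reactions 3 lactate → acetate + 2 propionate (fermentation, propionate
as marker) and 2 lactate + SO₄²⁻ → HS⁻ + 2 acetate (incomplete oxidation),
flagging acetate produced beyond what stoichiometry allows (yeast-extract
contribution). Sulphur converted from sulphate is balanced across the
harvested biofilm (FSB-S), the aqueous effluent and a closure-defined
unaccounted ("gap") pool. Community tables get Shannon/Simpson indices,
Bray–Curtis dissimilarities and rank-aggregated abundance shifts.

## Worked example

Run the bundled 2 L lactate-fed scenario — a 48 h HRT reactor cooled from
30 to 10 °C in 5 °C stages of 6 residence times each, sampled daily at four
ports and the effluent with 5 % assay noise:

```r
library(lfcrtemp)
library(dplyr)

res <- run_scenario(scenario_config("lactate_2L", seed = 1))

res$summaries |>
  filter(compartment == "bulk") |>
  select(temp_C, conversion, vsrr_mmol_L_h, lactate_util_mmol_L_h)
#>   temp_C conversion vsrr_mmol_L_h lactate_util_mmol_L_h
#> 1     30      0.643        0.140                  0.227
#> 2     25      0.567        0.123                  0.227
#> 3     20      0.489        0.106                  0.227
#> 4     15      0.449        0.0974                 0.225
#> 5     10      0.272        0.0591                 0.139
```

Conversion falls from 64 % to 27 % and the VSRR from 0.140 to
0.059 mmol/L·h as the reactor cools; lactate utilisation sits at the supply
limit (0.228 mmol/L·h) until the cold stage. The two-regime Arrhenius fit
locates the critical temperature:

```r
glance(res$arrhenius)
#>   mode  t_crit_K t_crit_C Ea_warm_kJ_mol Ea_cold_kJ_mol pooled_rss
#> 1 fixed     288.     14.8           17.8           67.9   0.000948
```

The warm range behaves like an adapted mesophilic community
(Ea ≈ 18 kJ/mol); below T_crit ≈ 14.8 °C the response steepens nearly
four-fold (Ea ≈ 68 kJ/mol) — the thermal-stress signature. The sulphur
ledger shows where the converted sulphur went:

```r
res$ledgers |> select(temp_C, converted_S_g, fsb_S_g, recovery_pct, gap_pct)
#>   temp_C converted_S_g fsb_S_g recovery_pct gap_pct
#> 1     30          2.58   0.772         30.0    69.2
#> 2     25          2.27   0.682         30.0    69.2
#> 3     20          1.96   0.601         30.7    68.6
#> 4     15          1.80   0.526         29.2    70.0
#> 5     10          1.09   0.326         29.9    69.5
```

About 30 % of converted sulphur is recovered in the harvested biofilm; the
~70 % gap is colloidal sulphur and washed-out film fragments, not gaseous
loss. `autoplot(res$arrhenius)`, `plot_stage_rates()` and
`plot_sulphur_ledger()` draw the standard diagnostic figures, and
`diversity_table()` / `shift_table()` summarise the accompanying synthetic
ASV tables.

A thin command-line front end with `run`, `simulate`, `summarise`,
`partition`, `arrhenius`, `balance`, `diversity` and `validate`
subcommands is installed at `inst/scripts/lfcrtemp`; configurations are
YAML files (see `scenario_config()` / `write_run_config()`).

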