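# thzhdx

Per-residue analysis of protein hydrogen–deuterium exchange (HDX) under a
transient perturbation — sub-terahertz irradiation or mild heating —
monitored by NMR peak intensities.

When a protein is dissolved in D2O, backbone amide protons exchange for
deuterons and their ¹H-¹⁵N peak intensities decay. Exchange proceeds
through transient structural opening,

    NH(closed) ⇌ NH(open) → exchanged,        k_ex = K_op · k_ch  (EX2 limit)

where `K_op` is the opening equilibrium constant and `k_ch` the intrinsic
chemical rate of the exposed amide (base-catalysed: ×10 per pH unit;
Arrhenius in temperature). A perturbation applied for t = 3, 6 or 12 min
inside a fixed 14-min room-temperature window changes `K_op` and/or `k_ch`
while it is on; comparing the perturbed sample to a matched unperturbed
control gives, per residue, after normalisation by 37 non-exchangeable
methyl internal standards,

    R_t = I_pert,t / I_GC,t
    Error(R_t) = R_t · sqrt(SNR_pert⁻² + SNR_GC⁻²)
    ΔR  = R_t − R_3min            (t = 6, 12)

and the one-sigma decision rule: ΔR + Error(ΔR) < 0 ⇒ **accelerated**
exchange, ΔR − Error(ΔR) > 0 ⇒ **decelerated**, otherwise unchanged, with
an onset tier (call at both 6 and 12 min, or only at 12 min).

The package provides, as pipe-friendly functions over tidy data frames:

* the two-state exchange-kinetics engine (general and EX2/EX1-limit rates,
  pH and Arrhenius scaling, piecewise exposure protocols);
* a seeded synthetic-experiment generator reproducing the measurement's
  statistical structure (concentration jitter, methyl standards,
  three-spectrum summation, SNR-based noise, the 14-min protocol) with
  perturbation scenarios for direct sub-THz action vs. pure heating;
* the ratio statistics, SNR error propagation, residue selection
  (fast-exchanger / SNR < 33.3 / overlap exclusions) and classification;
* exponential HDX-rate fitting with `tidy()`/`glance()` methods;
* beam dosimetry (reflection loss, Beer–Lambert absorption, delivered
  dose) and structure annotation (per-residue calls written into the PDB
  temperature-factor column);
* a config-driven pipeline `run_thz_hdx()` plus a thin CLI
  (`inst/scripts/thz-hdx-cli.R`) with `simulate`, `analyze`, `report` and
  `dose` subcommands.

It is intended for spectroscopists analysing perturbation-HDX intensity
tables and for method developers who need a controlled synthetic testbed
for the decision rule's statistical power.

## Worked example

```r
library(thzhdx)

fx <- default_ubiquitin_fixture()          # 15 residues, 3 hydropathy classes
peaks <- simulate_run(fx, thz_scenario(), "THz_low",
                      nominal_snr = 500, seed = 1)
cls <- classify_residues(compute_ratios(peaks))
summary_table(cls, fx)
#> # A tibble: 4 × 4
#>   hydropathy_class    label       onset           n
#>   <chr>               <chr>       <chr>       <int>
#> 1 hydrophilic_surface decelerated at_6_and_12     2
#> 2 hydrophilic_surface decelerated only_12         1
#> 3 hydrophobic_surface accelerated at_6_and_12    10
#> 4 interior_helix      accelerated at_6_and_12     2
```

Under the direct sub-THz scenario all twelve hydrophobic/interior residues
classify as accelerated (their opening equilibrium is raised while the
beam is on) and the three hydrophilic surface residues as decelerated
(their open-state chemistry is slowed); `heat_scenario()` inverts both
directions. Per-residue detail, e.g. residue 70: `R_12 = 0.933`,
`ΔR_12 = −0.0498 ± 0.0023` — the 12-min ratio sits 5% below the control,
far outside its propagated error, a strong accelerated call
(`at_6_and_12`). `autoplot(cls)` draws the ΔR profile with error bars.

Dosimetry for the two power densities used (values in J/cm²):

```r
beam_summary(c(18, 90), 12)
#>   power_density duration_min transmitted_fraction absorbed_fraction ...
#> 1            18           12                  0.6             0.961
#> 2            90           12                  0.6             0.961
```

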