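# gbas

Modelling and signal decoding for **glucometer-based allosteric
biosensors** — sensors that detect a therapeutic drug by letting it
modulate enzymatic glucose oxidation.

## The problem

Glucometers are cheap, robust and everywhere, but they measure one thing.
A glucometer-based allosteric sensor (GBAS) repurposes that
infrastructure: the ligand-binding domain (LBD) of estrogen receptor
alpha is inserted into PQQ-dependent glucose dehydrogenase (GDH), so that
binding of 4-hydroxytamoxifen (4-HT, the active metabolite of the breast
cancer drug tamoxifen) allosterically represses glucose turnover. The drug
signal then rides on every glucose-derived observable: colorimetric assay
slopes, electrode currents, fuel-cell power, and the drain current of an
organic electrochemical transistor (OECT).

`gbas` is for protein engineers and bioelectrochemists building or
analysing such sensors. It provides, as tested and seeded R code:

* **kinetics** — allosteric Michaelis–Menten rate law
  `v = f·Vmax·S/(Km+S)` with `f = d·(1 − α·w·h(c))` acting on Vmax only,
  a DCPIP dye-decay forward model, slope-based activity estimation, and
  Levenberg–Marquardt Michaelis–Menten fitting;
* **amperometry** — staircase i–t traces under injection schedules,
  steady-state extraction, background correction, whole-blood response;
* **decoder** — the ratiometric dual-electrode algorithm: ratio
  `r = i_5E+/i_wt` with first-order error propagation, a strict >0.4 mM
  glucose gate, and a binary call against the references 6.37 ± 0.1
  (blank) and 4.85 ± 0.1 (4-HT) with midpoint boundary 5.61 and a
  z-score refusal band;
* **efc_oect** — Nernstian open-circuit potential
  `OCP = K + (RT/2F)·ln(C_glc/C_lactone)`, its decay under zero-order
  fuel consumption, polarization/power curves with ohmic + concentration
  losses, and the OECT drain-current derivative statistic (reduced and
  exact variants);
* **screening** — two-round insertion-library analysis (fold-threshold
  permissive calling, triplicate t-test allosteric calling),
  secondary-structure enrichment, and coupon-collector library coverage
  by inclusion–exclusion;
* **synthetic_data** — generators reproducing the study's statistical
  structure (454-position library with 232/71 truth labels, assay CVs of
  11%/7.6%, blood glucose N(5.6, 1.0) mM), plus CSV/YAML fixture writers
  with a checksummed manifest.

## Worked example

```r
library(gbas)

## allosteric kinetics: 1 nM 4-HT attenuates the engineered enzyme by 18%
e5 <- gdh_5e_plus()
catalytic_rate(e5, 80, ligand_dose("none", 0, 0.01))   # 112.0 a.u./s
catalytic_rate(e5, 80, ligand_dose("4-HT", 1e-9, 0.01)) #  91.8 a.u./s

## decode one blood sample with the dual-electrode ratio
s <- blood_sample(glucose_mM = 5.6, dose = ligand_dose("4-HT", 1e-6, 0.01),
                  volume_uL = 200, electrolyte_mL = 2)
m <- simulate_dual_measurement(s, seed = 42)
decode_measurement(m)
#> <decision> POSITIVE_4HT  (ratio 5.114 +/- 0.106; z_blank -8.64, z_pos 1.81)

## screen a synthetic 454-position insertion library
tab  <- generate_screen_table(sim_config(seed = 17))
profile_summary(classify_screen(tab))
#> <profile_summary> 454 positions: 232 permissive (51.1%), 63 allosteric (13.9%)

## was picking 7392 colonies enough to see every variant?
coverage_probability(7392, 454)$p_full_coverage  # 0.999962
```

The decoded ratio 5.11 falls below the midpoint boundary 5.61 and within
the refusal band of neither reference, so the sample is called 4-HT
positive. The classified library recovers the 232 permissive truth sites
exactly and 63 of the 71 allosteric ones — the triplicate t test at 11%
CV has power ≈0.85, so a handful of weak allosteric effects stay below
the significance threshold.

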