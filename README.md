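# comdiss

Quantitative analysis of calcium oxalate monohydrate (COM, whewellite)
dissolution and its inhibition by adsorbing additives.

COM is the dominant mineral phase of kidney stones, and candidate stone
modulators are screened by seeded constant-composition dissolution
experiments: titrant additions hold the solution composition fixed, so the
titrant addition rate measures the dissolution rate at a known, constant
undersaturation. `comdiss` turns the raw experiment tables of such a study
into the standard derived quantities:

* **Speciation** — free-ion concentrations of the Ca/oxalate/Na/Cl system
  from mass balance and electroneutrality, with Davies activity
  corrections (`solve_speciation()`), feeding the free-ion product
  √([Ca²⁺][C₂O₄²⁻]).
* **Relative undersaturation** — σ = (H₀^½ − H^½)/H₀^½, the normalized
  driving force for dissolution (`relative_undersaturation()`,
  `com_sigma()`).
* **Power rate law** — R = k·s·σⁿ with s ≡ 1, fitted by OLS in log–log
  space; the slope is the apparent order n (n ≈ 2 indicates
  surface-controlled dissolution) and k = 10^intercept
  (`fit_rate_law()`).
* **Langmuir adsorption** — inhibitors block a fraction
  θ = K·C/(1 + K·C) of active sites so Rᵢ = R₀(1 − θ). Two
  linearizations give two estimates of the adsorption constant:
  R₀/(R₀−Rᵢ) = 1 + 1/(K_L·C) (kinetic, `langmuir_kinetic_fit()`) and
  C/θ = C + 1/K_ads (equilibrium, `langmuir_isotherm_fit()`), plus
  ΔG_ads = −RT·ln(55.5·K_ads) (`gibbs_adsorption()`).
* **Adsorption-energy arithmetic** — E_a = E_complex − (E_A + E_B) and
  HOMO–LUMO gap bookkeeping for electronic-structure results
  (`adsorption_energy()`, `energy_gap()`, `gap_widening()`).
* **Synthetic data** — generators with known ground truth for every
  measurement type (`synthetic_config()`, `generate_rate_table()`,
  `generate_inhibition_table()`, `generate_titration_series()`), so the
  whole pipeline is testable without any external data.

The reference experiment tables (dissolution series, inhibition series,
DFT energies) ship as plain-text fixtures with accessors
`com_dissolution_table()`, `com_inhibition_table()`, `com_energy_table()`.

## Worked example

```r
library(comdiss)

report <- run_com_analysis(
  runs       = com_dissolution_table(),   # control + additive series
  inhibition = com_inhibition_table(),    # rate vs inhibitor concentration
  energies   = com_energy_table()         # DFT totals and gaps
)
print(report)
#> COM dissolution-inhibition analysis report
#>   rate law [additive]: n = 1.753 (-> 2), k = 4.625e-05, r^2 = 0.9985
#>   rate law [control]: n = 1.689 (-> 2), k = 4.981e-05, r^2 = 0.9879
#>   adsorption: K_L = 2.265e+04, K_ads = 2.286e+04 dm^3 mol^-1, dG = -36.238 kJ/mol
#>   max inhibition: 18.533 % at C = 1e-05 mol dm^-3
#>   energetics: E_ads = -0.273 eV (physisorption), gap 4.656 -> 5.278 eV (+0.622)
```

Reading the numbers: both dissolution series follow the power law with an
apparent order rounding to 2 (surface-controlled mechanism). The two
independent Langmuir routes agree — an affinity constant K_L ≈ 2.27×10⁴
and equilibrium constant K_ads ≈ 2.29×10⁴ dm³ mol⁻¹ — and the Gibbs
energy of adsorption of about −36 kJ/mol indicates strong, favorable
adsorption of the additive on the crystal surface. The additive reduces
the dissolution rate by up to ~18.5 % over the 2–10 µM range, and the
−0.273 eV adsorption energy with a widened HOMO–LUMO gap classifies the
additive–crystal interaction as physisorption (hydrogen bonding / van der
Waals), consistent with the kinetic picture of reversible site blocking.

`write_com_report(report, "report.json")` serializes the full report
(deterministically — identical inputs give byte-identical JSON). A thin
command-line wrapper with `analyze`, `simulate` and `speciate`
subcommands is installed at `inst/scripts/comdiss`.

## Method details

See the methods vignette (`vignettes/com-dissolution-methods.Rmd`) for
the models, their assumptions, the numerical design of the speciation
solver, the two σ and ΔG conventions, and the measured limits of the
linearized Langmuir estimators at low surface coverage.
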