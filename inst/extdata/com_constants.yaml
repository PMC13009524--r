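# Thermodynamic constants for Ca / oxalate / Na / Cl speciation at 37 C.
# Association constants are thermodynamic (activity-scale, I = 0); sources
# are the NIST critical stability-constant compilation (Smith & Martell)
# and standard aqueous-chemistry references. Every value is overridable:
# copy this file, edit, and pass it to com_constants(file = ...).
species:
  - {name: Ca, charge: 2}
  - {name: Ox, charge: -2}   # oxalate C2O4^2-
  - {name: Na, charge: 1}
  - {name: Cl, charge: -1}
  - {name: H,  charge: 1}    # activity fixed by pH
reactions:
  - product: OH
    charge: -1
    reactants: {H: -1}
    logK: -13.62
    source: water autoionization, pKw at 310 K (Bandura & Lvov 2006)
  - product: HOx
    charge: -1
    reactants: {H: 1, Ox: 1}
    logK: 4.266
    source: oxalate pKa2 (Smith & Martell)
  - product: H2Ox
    charge: 0
    reactants: {H: 2, Ox: 1}
    logK: 5.518
    source: cumulative, pKa1 = 1.252 + pKa2 = 4.266 (Smith & Martell)
  - product: CaOx
    charge: 0
    reactants: {Ca: 1, Ox: 1}
    logK: 3.19
    source: CaC2O4(aq) ion pair (Smith & Martell)
  - product: CaHOx
    charge: 1
    reactants: {Ca: 1, H: 1, Ox: 1}
    logK: 5.37
    source: cumulative, Ca + HOx logK ~ 1.1 plus oxalate pKa2
  - product: CaOH
    charge: 1
    reactants: {Ca: 1, H: -1}
    logK: -12.70
    source: first hydrolysis constant of Ca2+ (Baes & Mesmer)
  - product: NaOx
    charge: -1
    reactants: {Na: 1, Ox: 1}
    logK: 1.00
    source: NaC2O4- ion pair (Daniele et al.); disabled by default because
      Na+/Cl- are treated as fully dissociated background electrolyte
    enabled: false
physical:
  debye_huckel_A: 0.5215   # Debye-Huckel A for water at 310.15 K, kg^1/2 mol^-1/2
  water_molarity: 55.5     # mol dm^-3, standard state for adsorption from solution
  gas_constant: 8.314      # J mol^-1 K^-1
  h0_sqrt: 1.994e-4        # mol dm^-3, COM solubility (H0^1/2) at I = 0.15
  ssa_m2_per_g: 3.73       # BET specific surface area of the seed crystals
  temperature_K: 310.15
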