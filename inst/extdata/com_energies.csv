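# DFT total energies (eV) for the caffeine / calcium-oxalate system in
# water, and HOMO-LUMO gaps where published. Orbital energies behind the
# gaps were not published, so gaps are carried as pre-computed values.
label,e_total_ev,e_homo_ev,e_lumo_ev,e_gap_ev
caffeine,-15305.276,NA,NA,4.656
caox,-28704.271,NA,NA,NA
complex,-44009.820,NA,NA,5.278
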