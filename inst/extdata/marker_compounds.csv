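name,formula,adduct,measured_mz,reported_theoretical_mz,mass_derivable
Dihydrobiopterin,C9H13N5O3,[M+K]+,278.0655,278.0650,TRUE
PGB2,C20H30O4,[M+H-2H2O]+,299.2022,299.2017,FALSE
Argininosuccinate,C10H18N4O6,[M+NH4]+,308.1571,308.1565,TRUE
Carboxy-LTB4,C20H30O6,[M+Na]+,389.1942,389.1935,TRUE
CMPF,C12H16O5,[M+Na]+,263.0885,263.0890,TRUE
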