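# Default water radiolysis reaction network (25 C, low LET, oxygenated water).
# Columns: label, reactants -> products, k, unit, provenance note.
# Provenance tags: "core" = the six published hydroxyl/superoxide/peroxide
# reactions with their printed rate constants; "literature" = standard
# aqueous radiolysis set (Buxton et al. 1988 / Elliot 1994 compilations);
# "equilibrium" = acid-base / autoionization partners chosen to reproduce
# pKa(HO2) = 4.8, pKa(H2O2) = 11.7 and Kw = 1e-14 at 25 C.
# Solvent water written explicitly for balance; kinetic order is set by the
# unit tag (see parse_reaction_table).
1a, OH + OH -> H2O2, 5.50e9, M-1s-1, core
1b, OH + O2- -> O2 + OH-, 1.07e10, M-1s-1, core
2a, H3O+ + O2- -> HO2 + H2O, 4.78e10, M-1s-1, core
2b, HO2 + O2- -> HO2- + O2, 9.70e7, M-1s-1, core
2c, H3O+ + HO2- -> H2O2 + H2O, 5.00e10, M-1s-1, core
2d, HO2- + H2O -> H2O2 + OH-, 1.36e6, M-1s-1, core
E1, eaq + eaq + 2 H2O -> H2 + 2 OH-, 5.5e9, M-1s-1, literature
E2, eaq + OH -> OH-, 3.0e10, M-1s-1, literature
E3, eaq + H + H2O -> H2 + OH-, 2.5e10, M-1s-1, literature
E4, eaq + H2O2 -> OH + OH-, 1.1e10, M-1s-1, literature
E5, eaq + O2 -> O2-, 1.9e10, M-1s-1, literature
E6, eaq + H3O+ -> H + H2O, 2.3e10, M-1s-1, literature
E7, eaq + HO2 -> HO2-, 2.0e10, M-1s-1, literature
H1, H + H -> H2, 7.8e9, M-1s-1, literature
H2a, H + OH -> H2O, 7.0e9, M-1s-1, literature
H3a, H + H2O2 -> OH + H2O, 9.0e7, M-1s-1, literature
H4, H + O2 -> HO2, 2.1e10, M-1s-1, literature
H5, H + HO2 -> H2O2, 1.8e10, M-1s-1, literature
H6, H + O2- -> HO2-, 1.8e10, M-1s-1, literature
H7, H + OH- -> eaq + H2O, 2.2e7, M-1s-1, literature
O1, OH + H2 -> H + H2O, 4.2e7, M-1s-1, literature
O2a, OH + H2O2 -> HO2 + H2O, 2.7e7, M-1s-1, literature
O3, OH + HO2 -> O2 + H2O, 6.0e9, M-1s-1, literature
O4, OH + HO2- -> HO2 + OH-, 7.5e9, M-1s-1, literature
P1, HO2 + HO2 -> H2O2 + O2, 8.3e5, M-1s-1, literature
A1, HO2 + H2O -> O2- + H3O+, 1.37e4, M-1s-1, equilibrium
A2, H2O2 + H2O -> HO2- + H3O+, 1.8e-3, M-1s-1, equilibrium
W1, H3O+ + OH- -> H2O + H2O, 1.43e11, M-1s-1, literature
W2, H2O + H2O -> H3O+ + OH-, 4.68e-7, M-1s-1, equilibrium
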