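# Synthetic stand-in primary (escape) yield set for low-LET water
# radiolysis at the microsecond hand-off, 25 C, near-neutral pH.
# Values are literature escape yields (Elliot 1994 / LaVerne 2004 class
# compilations), NOT a track-structure simulation output. Units: entities
# per 100 eV. The set satisfies the material balance
# G(eaq) + G(H) + 2 G(H2) = G(OH) + 2 G(H2O2) = 4.08 and electroneutrality
# G(eaq) + G(OH-) = G(H3O+). Secondary species (O2-, HO2) are zero by
# definition: they arise from chemistry only.
species	G_per_100eV	provenance
eaq	2.63	literature-standin
OH	2.72	literature-standin
H	0.55	literature-standin
H2	0.45	literature-standin
H2O2	0.68	literature-standin
H3O+	2.63	literature-standin
O2-	0	definitional-secondary
HO2	0	definitional-secondary
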