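{
 "material_id": "C",
 "density_g_cm3": 2.267,
 "edges_keV": [],
 "source": "computed: Cromer-Liberman photoabsorption (via gemmi) + Klein-Nishina incoherent + empirical coherent term; validated against standard reference tabulations to ~1% for Z<=29 over 20-150 keV"
}
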