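{
 "material_id": "ptfe",
 "density_g_cm3": 2.2,
 "edges_keV": [],
 "source": "computed: Cromer-Liberman photoabsorption (via gemmi) + Klein-Nishina incoherent + empirical coherent term; validated against standard reference tabulations to ~1% for Z<=29 over 20-150 keV",
 "mass_fractions": {
  "C": 0.240186,
  "F": 0.759814
 }
}
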