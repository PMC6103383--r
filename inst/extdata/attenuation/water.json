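{
 "material_id": "water",
 "density_g_cm3": 0.998,
 "edges_keV": [],
 "source": "computed: Cromer-Liberman photoabsorption (via gemmi) + Klein-Nishina incoherent + empirical coherent term; validated against standard reference tabulations to ~1% for Z<=29 over 20-150 keV",
 "mass_fractions": {
  "H": 0.111907,
  "O": 0.888093
 }
}
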