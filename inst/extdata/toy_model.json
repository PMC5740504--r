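{
  "schema": "metdriver-model-v1",
  "id": "toy-chain",
  "metabolites": [
    {"id": "A", "compartment": "c"},
    {"id": "B", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_A", "stoichiometry": {"A": -1}, "lb": -10, "ub": 0,
     "gpr": ""},
    {"id": "R1", "stoichiometry": {"A": -1, "B": 1}, "lb": 0, "ub": 1000,
     "gpr": "g1 and g2"},
    {"id": "BIOMASS", "stoichiometry": {"B": -1}, "lb": 0, "ub": 1000,
     "gpr": ""}
  ],
  "objective": "BIOMASS",
  "exchanges": ["EX_A"]
}
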