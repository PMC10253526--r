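{
  "comment": [
    "Default water-radiolysis reaction network: ten tracked species plus",
    "continuum dissolved O2. Diffusion coefficients in nm^2/ns (numerically",
    "equal to 1e-9 m^2/s); bimolecular rate constants in 1/M/s, unimolecular",
    "in 1/s. Values are standard diffusion-controlled literature constants",
    "for pure water at 25 C, pH 7. Same-species reactions (A+A->P) use the",
    "convention d[A]/dt = -2*k*[A]^2: each event consumes two A.",
    "Water appearing as implicit reactant/product is omitted; the validator",
    "balances H and O by allowing integer implied-H2O on either side."
  ],
  "species": [
    {"name": "OH",    "D_nm2_per_ns": 2.8,  "category": "i",   "charge": 0},
    {"name": "H3O+",  "D_nm2_per_ns": 9.0,  "category": "i",   "charge": 1},
    {"name": "H",     "D_nm2_per_ns": 7.0,  "category": "i",   "charge": 0},
    {"name": "eaq-",  "D_nm2_per_ns": 4.9,  "category": "i",   "charge": -1},
    {"name": "H2",    "D_nm2_per_ns": 4.8,  "category": "ii",  "charge": 0},
    {"name": "H2O2",  "D_nm2_per_ns": 2.3,  "category": "ii",  "charge": 0},
    {"name": "OH-",   "D_nm2_per_ns": 5.0,  "category": "ii",  "charge": -1},
    {"name": "HO2",   "D_nm2_per_ns": 2.0,  "category": "iii", "charge": 0},
    {"name": "O2-",   "D_nm2_per_ns": 1.75, "category": "iii", "charge": -1},
    {"name": "HO2-",  "D_nm2_per_ns": 1.4,  "category": "iii", "charge": -1}
  ],
  "continuum": {
    "O2": {"henry_M_per_atm": 1.3e-3}
  },
  "reactions": [
    {"id": "R01", "reactants": ["eaq-", "eaq-"], "products": ["H2", "OH-", "OH-"], "k_per_M_per_s": 5.5e9},
    {"id": "R02", "reactants": ["eaq-", "OH"],   "products": ["OH-"],              "k_per_M_per_s": 3.0e10},
    {"id": "R03", "reactants": ["eaq-", "H"],    "products": ["H2", "OH-"],        "k_per_M_per_s": 2.5e10},
    {"id": "R04", "reactants": ["eaq-", "H3O+"], "products": ["H"],                "k_per_M_per_s": 2.3e10},
    {"id": "R05", "reactants": ["eaq-", "H2O2"], "products": ["OH", "OH-"],        "k_per_M_per_s": 1.1e10},
    {"id": "R06", "reactants": ["OH", "OH"],     "products": ["H2O2"],             "k_per_M_per_s": 5.5e9},
    {"id": "R07", "reactants": ["OH", "H"],      "products": [],                   "k_per_M_per_s": 7.0e9},
    {"id": "R08", "reactants": ["OH", "H2"],     "products": ["H"],                "k_per_M_per_s": 4.2e7},
    {"id": "R09", "reactants": ["H", "H"],       "products": ["H2"],               "k_per_M_per_s": 7.8e9},
    {"id": "R10", "reactants": ["H", "H2O2"],    "products": ["OH"],               "k_per_M_per_s": 9.0e7},
    {"id": "R11", "reactants": ["H", "OH-"],     "products": ["eaq-"],             "k_per_M_per_s": 2.2e7},
    {"id": "R12", "reactants": ["H3O+", "OH-"],  "products": [],                   "k_per_M_per_s": 1.43e11},
    {"id": "R13", "reactants": ["eaq-", "O2"],   "products": ["O2-"],              "k_per_M_per_s": 1.9e10},
    {"id": "R14", "reactants": ["H", "O2"],      "products": ["HO2"],              "k_per_M_per_s": 2.1e10},
    {"id": "R15", "reactants": ["eaq-", "HO2"],  "products": ["HO2-"],             "k_per_M_per_s": 1.28e10},
    {"id": "R16", "reactants": ["eaq-", "O2-"],  "products": ["HO2-", "OH-"],      "k_per_M_per_s": 1.3e10},
    {"id": "R17", "reactants": ["H", "HO2"],     "products": ["H2O2"],             "k_per_M_per_s": 1.0e10},
    {"id": "R18", "reactants": ["OH", "HO2"],    "products": ["O2"],               "k_per_M_per_s": 7.9e9},
    {"id": "R19", "reactants": ["OH", "O2-"],    "products": ["OH-", "O2"],        "k_per_M_per_s": 1.0e10},
    {"id": "R20", "reactants": ["HO2", "HO2"],   "products": ["H2O2", "O2"],       "k_per_M_per_s": 8.3e5},
    {"id": "R21", "reactants": ["HO2", "O2-"],   "products": ["HO2-", "O2"],       "k_per_M_per_s": 9.7e7},
    {"id": "R22", "reactants": ["H3O+", "O2-"],  "products": ["HO2"],              "k_per_M_per_s": 4.78e10},
    {"id": "R23", "reactants": ["H3O+", "HO2-"], "products": ["H2O2"],             "k_per_M_per_s": 5.0e10},
    {"id": "R24", "reactants": ["HO2"],          "products": ["O2-", "H3O+"],      "k_per_s": 8.0e5}
  ]
}
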