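{
  "id": "toy5",
  "compartments": {
    "c": "cytoplasm",
    "e": "extracellular"
  },
  "extracellular": "e",
  "metabolites": [
    {
      "id": "bm_c",
      "name": "bm_c",
      "compartment": "c"
    },
    {
      "id": "glc_c",
      "name": "glc_c",
      "compartment": "c",
      "formula": "C6H12O6",
      "charge": 0
    },
    {
      "id": "glc_e",
      "name": "glc_e",
      "compartment": "e",
      "formula": "C6H12O6",
      "charge": 0
    },
    {
      "id": "pyr_c",
      "name": "pyr_c",
      "compartment": "c",
      "formula": "C3H3O3",
      "charge": -1
    }
  ],
  "reactions": [
    {
      "id": "BIOMASS",
      "name": "BIOMASS",
      "metabolites": {
        "bm_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": null,
      "kind": "biomass",
      "objective_coefficient": 1
    },
    {
      "id": "EX_glc",
      "name": "EX_glc",
      "metabolites": {
        "glc_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": null,
      "kind": "exchange",
      "objective_coefficient": 0
    },
    {
      "id": "GLCt",
      "name": "GLCt",
      "metabolites": {
        "glc_e": -1,
        "glc_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b1 or b2",
      "subsystem": "transport",
      "kind": "transport",
      "objective_coefficient": 0
    },
    {
      "id": "GLY",
      "name": "GLY",
      "metabolites": {
        "glc_c": -1,
        "pyr_c": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b3 and b4",
      "subsystem": "glycolysis",
      "kind": "internal",
      "objective_coefficient": 0
    },
    {
      "id": "PYR2BM",
      "name": "PYR2BM",
      "metabolites": {
        "pyr_c": -1,
        "bm_c": 0.25
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "central",
      "kind": "internal",
      "objective_coefficient": 0
    }
  ],
  "genes": [
    {
      "id": "b1"
    },
    {
      "id": "b2"
    },
    {
      "id": "b3"
    },
    {
      "id": "b4"
    }
  ]
}
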