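{
  "id": "toy_3path_seed1",
  "metabolites": [
    {
      "id": "cof_ox",
      "name": "cofactor (oxidised)",
      "compartment": "c"
    },
    {
      "id": "cof_red",
      "name": "cofactor (reduced)",
      "compartment": "c"
    },
    {
      "id": "A1",
      "name": "A1",
      "compartment": "c"
    },
    {
      "id": "B1",
      "name": "B1",
      "compartment": "c",
      "annotation": {
        "hmdb": "HMDB00101"
      }
    },
    {
      "id": "C1",
      "name": "C1",
      "compartment": "c"
    },
    {
      "id": "A2",
      "name": "A2",
      "compartment": "c"
    },
    {
      "id": "B2",
      "name": "B2",
      "compartment": "c",
      "annotation": {
        "hmdb": "HMDB00102"
      }
    },
    {
      "id": "A3",
      "name": "A3",
      "compartment": "c"
    },
    {
      "id": "B3",
      "name": "B3",
      "compartment": "c",
      "annotation": {
        "hmdb": "HMDB00103"
      }
    }
  ],
  "reactions": [
    {
      "id": "EX_upt_1",
      "name": "uptake exchange, pathway 1",
      "metabolites": {
        "A1": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_1",
      "name": "conversion, pathway 1",
      "metabolites": {
        "cof_ox": -1,
        "cof_red": 1,
        "A1": -1,
        "B1": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Fatty acid oxidation",
      "gene_reaction_rule": "(g1a and g1b) or g1c",
      "objective_coefficient": 0
    },
    {
      "id": "EX_sec_1",
      "name": "secretion exchange, pathway 1",
      "metabolites": {
        "B1": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    },
    {
      "id": "BR1_1",
      "name": "branch step 1, pathway 1",
      "metabolites": {
        "A1": -1,
        "C1": 1
      },
      "lower_bound": 0,
      "upper_bound": 5,
      "subsystem": "Fatty acid oxidation",
      "gene_reaction_rule": "g1d",
      "objective_coefficient": 0
    },
    {
      "id": "BR2_1",
      "name": "branch step 2, pathway 1",
      "metabolites": {
        "B1": 1,
        "C1": -1
      },
      "lower_bound": 0,
      "upper_bound": 5,
      "subsystem": "Fatty acid oxidation",
      "gene_reaction_rule": "g1d",
      "objective_coefficient": 0
    },
    {
      "id": "EX_upt_2",
      "name": "uptake exchange, pathway 2",
      "metabolites": {
        "A2": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_2",
      "name": "conversion, pathway 2",
      "metabolites": {
        "cof_ox": -1,
        "cof_red": 1,
        "A2": -1,
        "B2": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Bile acid synthesis",
      "gene_reaction_rule": "(g2a and g2b) or g2c",
      "objective_coefficient": 0
    },
    {
      "id": "EX_sec_2",
      "name": "secretion exchange, pathway 2",
      "metabolites": {
        "B2": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_upt_3",
      "name": "uptake exchange, pathway 3",
      "metabolites": {
        "A3": -1
      },
      "lower_bound": -10,
      "upper_bound": 0,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "CONV_3",
      "name": "conversion, pathway 3",
      "metabolites": {
        "cof_ox": -1,
        "cof_red": 1,
        "A3": -1,
        "B3": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Amino acid metabolism",
      "gene_reaction_rule": "(g3a and g3b) or g3c",
      "objective_coefficient": 0
    },
    {
      "id": "EX_sec_3",
      "name": "secretion exchange, pathway 3",
      "metabolites": {
        "B3": -1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "subsystem": "Transport, extracellular",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "COF_REGEN",
      "name": "cofactor regeneration",
      "metabolites": {
        "cof_ox": 1,
        "cof_red": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "subsystem": "Miscellaneous",
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    }
  ]
}
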