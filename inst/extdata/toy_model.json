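{
  "metabolites": [
    {
      "id": "A_c",
      "name": "A_c",
      "compartment": "c"
    },
    {
      "id": "B_c",
      "name": "B_c",
      "compartment": "c"
    },
    {
      "id": "C_c",
      "name": "C_c",
      "compartment": "c"
    },
    {
      "id": "D_c",
      "name": "D_c",
      "compartment": "c"
    },
    {
      "id": "E_c",
      "name": "E_c",
      "compartment": "c"
    },
    {
      "id": "atp_c",
      "name": "atp_c",
      "compartment": "c"
    },
    {
      "id": "adp_c",
      "name": "adp_c",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_A",
      "name": "EX_A",
      "metabolites": {
        "A_c": -1
      },
      "lower_bound": -1,
      "upper_bound": -1,
      "gene_reaction_rule": "",
      "subsystem": "Toy"
    },
    {
      "id": "R1",
      "name": "R1",
      "metabolites": {
        "A_c": -1,
        "B_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g1",
      "subsystem": "Toy"
    },
    {
      "id": "R5",
      "name": "R5",
      "metabolites": {
        "A_c": -1,
        "B_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g7",
      "subsystem": "Toy"
    },
    {
      "id": "R2",
      "name": "R2",
      "metabolites": {
        "B_c": -1,
        "C_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g2 or g3",
      "subsystem": "Toy"
    },
    {
      "id": "R3",
      "name": "R3",
      "metabolites": {
        "C_c": -1,
        "D_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g4",
      "subsystem": "Toy"
    },
    {
      "id": "EX_D",
      "name": "EX_D",
      "metabolites": {
        "D_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Toy"
    },
    {
      "id": "R4",
      "name": "R4",
      "metabolites": {
        "B_c": -1,
        "atp_c": -1,
        "E_c": 1,
        "adp_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g5",
      "subsystem": "Energy"
    },
    {
      "id": "ADK",
      "name": "ADK",
      "metabolites": {
        "adp_c": -1,
        "atp_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "g6",
      "subsystem": "Energy"
    },
    {
      "id": "EX_E",
      "name": "EX_E",
      "metabolites": {
        "E_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Toy"
    }
  ],
  "genes": [
    {
      "id": "g1",
      "name": "g1"
    },
    {
      "id": "g2",
      "name": "g2"
    },
    {
      "id": "g3",
      "name": "g3"
    },
    {
      "id": "g4",
      "name": "g4"
    },
    {
      "id": "g5",
      "name": "g5"
    },
    {
      "id": "g6",
      "name": "g6"
    },
    {
      "id": "g7",
      "name": "g7"
    }
  ],
  "id": "fluxpath_model"
}
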