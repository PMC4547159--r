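{
  "id": "erk1_activation_synthetic",
  "name": "ERK1 activation (synthetic reconstruction)",
  "entities": [
    {
      "id": "ERK1",
      "name": "ERK1",
      "kind": "protein",
      "components": [],
      "description": "Extracellular signal-regulated kinase 1"
    },
    {
      "id": "ERK1_pMEK1",
      "name": "ERK1:p-S218,222-MEK1",
      "kind": "complex",
      "components": [
        "ERK1",
        "p-S218_222-MEK1"
      ],
      "description": "Complex of ERK1 and activated MEK1"
    },
    {
      "id": "MEK1",
      "name": "MEK1",
      "kind": "protein",
      "components": [],
      "description": "Dual specificity mitogen-activated protein kinase kinase 1"
    },
    {
      "id": "p-ERK1",
      "name": "p-ERK1",
      "kind": "protein",
      "components": [],
      "description": "Doubly phosphorylated ERK1"
    },
    {
      "id": "p-MEK1",
      "name": "p-MEK1",
      "kind": "protein",
      "components": [],
      "description": "Singly phosphorylated MEK1"
    },
    {
      "id": "p-S218_222-MEK1",
      "name": "p-S218,222-MEK1",
      "kind": "protein",
      "components": [],
      "description": "MEK1 phosphorylated at S218 and S222"
    },
    {
      "id": "pERK1_dimer",
      "name": "p-ERK1 dimer",
      "kind": "complex",
      "components": [
        "p-ERK1"
      ],
      "description": "Dimer of phosphorylated ERK1"
    },
    {
      "id": "pERK1_dimer_nuc",
      "name": "nuclear p-ERK1 dimer",
      "kind": "complex",
      "components": [
        "p-ERK1"
      ],
      "description": "Nuclear phospho-ERK1 dimer"
    },
    {
      "id": "pERK1_pMEK1",
      "name": "p-ERK1:p-S218,222-MEK1",
      "kind": "complex",
      "components": [
        "p-ERK1",
        "p-S218_222-MEK1"
      ],
      "description": "Complex of phospho-ERK1 and activated MEK1"
    }
  ],
  "reactions": [
    {
      "id": "RX1",
      "name": "MEK1 binds ERK-1",
      "description": "Activated MEK1 binds ERK1 to form the ERK1:p-S218,222-MEK1 complex",
      "inputs": [
        "ERK1",
        "p-S218_222-MEK1"
      ],
      "outputs": [
        "ERK1_pMEK1"
      ]
    },
    {
      "id": "RX2",
      "name": "MEK1 phosphorylates ERK-1",
      "description": "MEK1 phosphorylates ERK1 within the complex",
      "inputs": [
        "ERK1_pMEK1"
      ],
      "outputs": [
        "pERK1_pMEK1"
      ]
    },
    {
      "id": "RX3",
      "name": "Dissociation of phospho-ERK-1:MEK1",
      "description": "Dissociation of the phospho-ERK1:MEK1 complex releases p-ERK1 and p-S218,222-MEK1",
      "inputs": [
        "pERK1_pMEK1"
      ],
      "outputs": [
        "p-ERK1",
        "p-S218_222-MEK1"
      ]
    },
    {
      "id": "RX4",
      "name": "Dimerisation of p-ERK1",
      "description": "Phosphorylated ERK1 dimerizes",
      "inputs": [
        "p-ERK1"
      ],
      "outputs": [
        "pERK1_dimer"
      ]
    },
    {
      "id": "RX5",
      "name": "Translocation of the ERK1 dimer",
      "description": "The phospho-ERK1 dimer translocates to the nucleus",
      "inputs": [
        "pERK1_dimer"
      ],
      "outputs": [
        "pERK1_dimer_nuc"
      ]
    },
    {
      "id": "RX6",
      "name": "Phosphorylation of MEK1",
      "description": "MEK1 is phosphorylated",
      "inputs": [
        "MEK1"
      ],
      "outputs": [
        "p-MEK1"
      ]
    }
  ],
  "controls": []
}
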