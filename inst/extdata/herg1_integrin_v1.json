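{
  "species": [
    {
      "name": "F",
      "role": "free fibronectin binding sites",
      "initial": 0
    },
    {
      "name": "B",
      "role": "inactive beta1 integrin",
      "initial": 17090000
    },
    {
      "name": "Bs",
      "role": "active (fibronectin-bound) beta1 integrin",
      "initial": 0
    },
    {
      "name": "M",
      "role": "herg1 mRNA",
      "initial": 0
    },
    {
      "name": "R",
      "role": "ER core-glycosylated channel (135 kD band)",
      "initial": 0
    },
    {
      "name": "G",
      "role": "Golgi fully-glycosylated channel",
      "initial": 0
    },
    {
      "name": "Sc",
      "role": "surface free closed channel",
      "initial": 0
    },
    {
      "name": "So",
      "role": "surface free open channel",
      "initial": 0
    },
    {
      "name": "X",
      "role": "hERG1/beta1-integrin complex",
      "initial": 0
    },
    {
      "name": "E",
      "role": "endosomal channel (Rab5-positive)",
      "initial": 1000
    },
    {
      "name": "A",
      "role": "activator, inactive",
      "initial": 1500
    },
    {
      "name": "As",
      "role": "activator, active (girdin-Gai3-PI3K-Akt axis)",
      "initial": 0
    },
    {
      "name": "I",
      "role": "inhibitor, inactive",
      "initial": 1500
    },
    {
      "name": "Is",
      "role": "inhibitor, active",
      "initial": 0
    },
    {
      "name": "N",
      "role": "internalisation module, inactive",
      "initial": 1000
    },
    {
      "name": "Ns",
      "role": "internalisation module, active",
      "initial": 0
    }
  ],
  "reactions": [
    {
      "id": "integrin_activation",
      "reactants": {
        "B": 1,
        "F": 1
      },
      "products": {
        "Bs": 1
      },
      "rate_constant": "kf0"
    },
    {
      "id": "integrin_deactivation",
      "reactants": {
        "Bs": 1
      },
      "products": {
        "B": 1,
        "F": 1
      },
      "rate_constant": "k_mf"
    },
    {
      "id": "transcription_free_integrin",
      "products": {
        "M": 1
      },
      "modifiers": {
        "Bs": 1
      },
      "rate_constant": "k_ie"
    },
    {
      "id": "transcription_complexed_integrin",
      "products": {
        "M": 1
      },
      "modifiers": {
        "X": 1
      },
      "rate_constant": "k_ie"
    },
    {
      "id": "mrna_decay",
      "reactants": {
        "M": 1
      },
      "rate_constant": "k_dm"
    },
    {
      "id": "translation",
      "products": {
        "R": 1
      },
      "modifiers": {
        "M": 1
      },
      "rate_constant": "k_c"
    },
    {
      "id": "translation_boost",
      "products": {
        "R": 1
      },
      "modifiers": {
        "M": 1,
        "As": 1
      },
      "rate_constant": "k_cp"
    },
    {
      "id": "er_to_golgi",
      "reactants": {
        "R": 1
      },
      "products": {
        "G": 1
      },
      "rate_constant": "k_g"
    },
    {
      "id": "er_to_golgi_boost",
      "reactants": {
        "R": 1
      },
      "products": {
        "G": 1
      },
      "modifiers": {
        "As": 1
      },
      "rate_constant": "k_gp"
    },
    {
      "id": "golgi_to_membrane",
      "reactants": {
        "G": 1
      },
      "products": {
        "Sc": 1
      },
      "rate_constant": "k_tg"
    },
    {
      "id": "golgi_to_membrane_boost",
      "reactants": {
        "G": 1
      },
      "products": {
        "Sc": 1
      },
      "modifiers": {
        "As": 1
      },
      "rate_constant": "k_tgp"
    },
    {
      "id": "channel_opening",
      "reactants": {
        "Sc": 1
      },
      "products": {
        "So": 1
      },
      "rate_constant": "k_o"
    },
    {
      "id": "channel_closing",
      "reactants": {
        "So": 1
      },
      "products": {
        "Sc": 1
      },
      "rate_constant": "k_om"
    },
    {
      "id": "complex_formation",
      "reactants": {
        "Sc": 1,
        "Bs": 1
      },
      "products": {
        "X": 1
      },
      "rate_constant": "k_on"
    },
    {
      "id": "complex_dissociation",
      "reactants": {
        "X": 1
      },
      "products": {
        "Sc": 1,
        "Bs": 1
      },
      "rate_constant": "k_off"
    },
    {
      "id": "internalization",
      "reactants": {
        "Sc": 1
      },
      "products": {
        "E": 1
      },
      "modifiers": {
        "Ns": 1
      },
      "rate_constant": "k_e"
    },
    {
      "id": "recycling",
      "reactants": {
        "E": 1
      },
      "products": {
        "Sc": 1
      },
      "rate_constant": "k_te"
    },
    {
      "id": "endosomal_degradation",
      "reactants": {
        "E": 1
      },
      "rate_constant": "k_de"
    },
    {
      "id": "activator_activation",
      "reactants": {
        "A": 1
      },
      "products": {
        "As": 1
      },
      "modifiers": {
        "X": 1
      },
      "rate_constant": "k_a"
    },
    {
      "id": "activator_inactivation",
      "reactants": {
        "As": 1
      },
      "products": {
        "A": 1
      },
      "modifiers": {
        "Is": 2
      },
      "rate_constant": "k_am"
    },
    {
      "id": "inhibitor_activation",
      "reactants": {
        "I": 1
      },
      "products": {
        "Is": 1
      },
      "modifiers": {
        "X": 1
      },
      "rate_constant": "k_i"
    },
    {
      "id": "inhibitor_relaxation",
      "reactants": {
        "Is": 1
      },
      "products": {
        "I": 1
      },
      "rate_constant": "k_iep"
    },
    {
      "id": "internalization_module_activation",
      "reactants": {
        "N": 1
      },
      "products": {
        "Ns": 1
      },
      "rate_constant": "k_np"
    },
    {
      "id": "internalization_module_relaxation",
      "reactants": {
        "Ns": 1
      },
      "products": {
        "N": 1
      },
      "rate_constant": "k_mn"
    },
    {
      "id": "internalization_module_inhibition",
      "reactants": {
        "Ns": 1
      },
      "products": {
        "N": 1
      },
      "modifiers": {
        "As": 1
      },
      "rate_constant": "k_n"
    }
  ]
}
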