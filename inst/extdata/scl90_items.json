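{
  "n_items": 55,
  "likert": {
    "min": 1,
    "max": 5
  },
  "dimensions": [
    {
      "code": "int",
      "label": "Interpersonal sensitivity",
      "n_items": 9,
      "items": ["item_01", "item_02", "item_03", "item_04", "item_05", "item_06", "item_07", "item_08", "item_09"]
    },
    {
      "code": "dep",
      "label": "Depression",
      "n_items": 13,
      "items": ["item_10", "item_11", "item_12", "item_13", "item_14", "item_15", "item_16", "item_17", "item_18", "item_19", "item_20", "item_21", "item_22"]
    },
    {
      "code": "anx",
      "label": "Anxiety",
      "n_items": 10,
      "items": ["item_23", "item_24", "item_25", "item_26", "item_27", "item_28", "item_29", "item_30", "item_31", "item_32"]
    },
    {
      "code": "hos",
      "label": "Hostility",
      "n_items": 6,
      "items": ["item_33", "item_34", "item_35", "item_36", "item_37", "item_38"]
    },
    {
      "code": "pho",
      "label": "Phobic anxiety",
      "n_items": 7,
      "items": ["item_39", "item_40", "item_41", "item_42", "item_43", "item_44", "item_45"]
    },
    {
      "code": "psy",
      "label": "Psychoticism",
      "n_items": 10,
      "items": ["item_46", "item_47", "item_48", "item_49", "item_50", "item_51", "item_52", "item_53", "item_54", "item_55"]
    }
  ]
}
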