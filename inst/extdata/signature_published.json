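[
  {"id": "RP11-383H13.1", "class": "mesenchymal", "weight": 0.16},
  {"id": "MIR4435-1HG", "class": "mesenchymal", "weight": 0.15},
  {"id": "AC005932.1", "class": "mesenchymal", "weight": 0.05},
  {"id": "AC108463.1", "class": "mesenchymal", "weight": 0.15},
  {"id": "AP000695.4", "class": "mesenchymal", "weight": 0.18},
  {"id": "LINC00294", "class": "mesenchymal", "weight": 0.14},
  {"id": "LINC00152", "class": "mesenchymal", "weight": 0.13},
  {"id": "RP11-404O13.1", "class": "mesenchymal", "weight": 0.09},
  {"id": "RP11-483P21.2", "class": "mesenchymal", "weight": 0.12},
  {"id": "AC144450.2", "class": "mesenchymal", "weight": 0.04},
  {"id": "RP11-731D1.4", "class": "mesenchymal", "weight": 0.06},
  {"id": "RP11-610P16.1", "class": "mesenchymal", "weight": 0.06},
  {"id": "RP11-44F14.8", "class": "mesenchymal", "weight": 0.05},
  {"id": "RP11-44F14.2", "class": "mesenchymal", "weight": 0.05},
  {"id": "RP4-568C11.4", "class": "epithelial", "weight": -0.048}
]
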