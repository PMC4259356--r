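{
  "start": ["mmGene0003", "mmGene0018", "mmGene0020", "mmGene0041", "mmGene0045", "mmGene0053", "mmGene0058", "mmGene0067", "mmGene0070", "mmGene0084", "mmGene0085", "mmGene0099", "mmGene0103", "mmGene0104"],
  "stages": {
    "inflammatory": {
      "category": "inflammatory",
      "signatures": "inflammatory_wound_desmoplastic",
      "removed": "mmGene0067",
      "n_removed": 1,
      "n_remaining": 13
    },
    "non-osteotropic": {
      "category": "non-osteotropic",
      "signatures": "non_osteotropic_cancer_stroma",
      "removed": "mmGene0020",
      "n_removed": 1,
      "n_remaining": 12
    },
    "osteotropic": {
      "category": "osteotropic",
      "signatures": "osteotropic_primary_stroma",
      "removed": "mmGene0045",
      "n_removed": 1,
      "n_remaining": 11
    }
  },
  "components": {
    "inflammatory-shared": "mmGene0067",
    "universal": "mmGene0020",
    "osteotropic": "mmGene0045",
    "core": ["mmGene0003", "mmGene0018", "mmGene0041", "mmGene0053", "mmGene0058", "mmGene0070", "mmGene0084", "mmGene0085", "mmGene0099", "mmGene0103", "mmGene0104"]
  },
  "fractions": {
    "inflammatory-shared": 0.071428571429,
    "universal": 0.071428571429,
    "osteotropic": 0.071428571429,
    "core": 0.78571428571
  }
}
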