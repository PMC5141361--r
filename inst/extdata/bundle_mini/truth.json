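{
  "plantedPathNodes": {
    "pw1": ["g0001", "g0002", "g0003"],
    "pw2": [],
    "pw3": []
  },
  "plantedPairs": [
    {
      "mirna_id": "mir001",
      "gene_id": "g0005",
      "rho": -0.8
    },
    {
      "mirna_id": "mir002",
      "gene_id": "g0015",
      "rho": -0.8
    },
    {
      "mirna_id": "mir003",
      "gene_id": "g0025",
      "rho": -0.8
    },
    {
      "mirna_id": "mir004",
      "gene_id": "g0006",
      "rho": -0.8
    }
  ],
  "plantedCircuits": [
    {
      "topology": "tf_master",
      "tf_id": "g0039",
      "mirna_id": "mir005",
      "gene_id": "g0037",
      "coherence": "coherent"
    },
    {
      "topology": "mirna_master",
      "tf_id": "g0040",
      "mirna_id": "mir006",
      "gene_id": "g0038",
      "coherence": "coherent"
    }
  ],
  "config": {
    "nPerClass": [8, 8, 8],
    "nGenes": 40,
    "nMirnas": 12,
    "nPathways": 3,
    "pathwaySize": 10,
    "pathLength": 3,
    "delta": 1.5,
    "rho": -0.8,
    "nPairs": 4,
    "nCircuits": 1,
    "sigma": 1,
    "nDecoyPredictions": 40,
    "seed": 17
  }
}
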