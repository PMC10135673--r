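{
  "n_sites": 88,
  "n_incomplete": 8,
  "env": {
    "velocity": {
      "dist": "truncnorm",
      "mean": 0.3,
      "sd": 0.29,
      "min": 0,
      "max": 1.5
    },
    "turbidity": {
      "dist": "trunclnorm",
      "meanlog": 0.693147180559945,
      "sdlog": 1.2,
      "min": 0.02,
      "max": 34.7
    },
    "elevation": {
      "dist": "trunclnorm",
      "meanlog": 4.45434729625351,
      "sdlog": 1.15,
      "min": 2,
      "max": 1075
    }
  },
  "responses": {
    "scraper": {
      "predictor": "turbidity",
      "form": "broken",
      "a": 2,
      "b1": 0.35,
      "b2": -0.45,
      "psi": 5,
      "k": 2
    },
    "deposit_feeder": {
      "predictor": "turbidity",
      "form": "linear",
      "a": 2.2,
      "b1": -0.08,
      "k": 2
    },
    "filter_feeder": {
      "predictor": "velocity",
      "form": "linear",
      "a": 1.2,
      "b1": 1.6,
      "k": 2
    },
    "predator": {
      "predictor": "velocity",
      "form": "linear",
      "a": 2,
      "b1": 0.8,
      "k": 2
    },
    "shredder": {
      "predictor": "elevation",
      "form": "quadratic",
      "a": 1,
      "b1": 0.006,
      "b2": -5.5e-06,
      "k": 2
    },
    "piercer": {
      "predictor": "turbidity",
      "form": "flat",
      "a": 1,
      "k": 2
    },
    "parasite": {
      "predictor": "elevation",
      "form": "flat",
      "a": 0.6,
      "k": 2
    },
    "absorber": {
      "predictor": "velocity",
      "form": "flat",
      "a": -1.2,
      "k": 2
    }
  },
  "generative_feature": "feeding",
  "mixed_fraction": 0.25,
  "affinity": {
    "taxa": ["Chironomidae", "Simuliidae", "Ancylidae", "Tipulidae", "Libellulidae", "Corixidae", "Glossiphoniidae", "Naididae", "Baetidae", "Hydropsychidae", "Caenidae", "Leptophlebiidae", "Elmidae", "Physidae", "Leptohyphidae", "Hydroptilidae", "Philopotamidae", "Ceratopogonidae", "Psephenidae", "Dytiscidae", "Gyrinidae", "Hydrophilidae", "Naucoridae", "Veliidae", "Gerridae", "Gomphidae", "Coenagrionidae", "Calopterygidae", "Planorbidae", "Palaemonidae"],
    "traits": ["absorber", "deposit_feeder", "filter_feeder", "parasite", "piercer", "predator", "scraper", "shredder", "gill", "plastron", "spiracle", "tegument", "burrower", "crawler", "flier", "full_water_swimmer", "interstitial", "surface_swimmer", "temp_attached", "clutches_cemented", "clutches_free", "clutches_terrestrial", "clutches_vegetation", "eggs_cemented", "eggs_free", "ovoviviparity", "size_le_0.25", "size_0.25_0.5", "size_0.5_1", "size_1_2", "size_2_4", "size_4_8", "size_gt_8"],
    "feature": ["feeding", "feeding", "feeding", "feeding", "feeding", "feeding", "feeding", "feeding", "respiration", "respiration", "respiration", "respiration", "locomotion", "locomotion", "locomotion", "locomotion", "locomotion", "locomotion", "locomotion", "reproduction", "reproduction", "reproduction", "reproduction", "reproduction", "reproduction", "reproduction", "size", "size", "size", "size", "size", "size", "size"],
    "scores": [
      [0, 5, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0],
      [0, 0, 5, 0, 0, 0, 0, 0, 4, 0, 2, 0, 0, 2, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 2, 0],
      [0, 0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 5, 2, 0, 4, 0, 0, 4, 0, 2, 0, 0, 0, 0, 0, 4, 0, 0, 2, 0, 2, 0, 0, 4, 0, 0, 0],
      [0, 0, 0, 0, 0, 5, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4],
      [0, 0, 0, 0, 5, 0, 0, 0, 4, 0, 2, 0, 4, 0, 0, 0, 0, 2, 0, 2, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0],
      [0, 0, 0, 5, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0],
      [5, 0, 0, 0, 0, 0, 0, 0, 2, 0, 4, 0, 2, 0, 0, 0, 0, 0, 4, 4, 0, 2, 0, 0, 0, 0, 0, 4, 0, 0, 2, 0, 0],
      [0, 1, 0, 0, 0, 0, 3, 0, 0, 4, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0],
      [0, 0, 4, 0, 0, 1, 0, 0, 4, 0, 2, 0, 0, 0, 2, 0, 0, 4, 0, 0, 0, 0, 0, 2, 0, 4, 4, 0, 0, 0, 0, 0, 2],
      [0, 3, 0, 0, 0, 0, 1, 0, 0, 0, 0, 4, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0],
      [0, 2, 0, 0, 0, 0, 2, 0, 2, 0, 4, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 2, 0, 2, 0, 0, 0, 0, 4],
      [0, 0, 0, 0, 0, 0, 3, 1, 0, 4, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0],
      [0, 1, 0, 0, 0, 0, 3, 0, 4, 0, 2, 0, 0, 0, 0, 4, 0, 0, 2, 0, 2, 0, 0, 4, 0, 0, 0, 0, 0, 2, 0, 4, 0],
      [0, 4, 0, 0, 0, 0, 1, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 3, 0, 1, 0, 2, 0, 4, 0, 0, 2, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 2, 0],
      [0, 0, 5, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0],
      [0, 1, 0, 0, 0, 3, 0, 0, 4, 0, 2, 0, 0, 4, 0, 2, 0, 0, 0, 0, 0, 4, 0, 0, 2, 0, 2, 0, 0, 4, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 4, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4],
      [0, 0, 0, 0, 0, 5, 0, 0, 2, 0, 4, 0, 4, 0, 0, 0, 0, 2, 0, 2, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 4, 0, 1, 0, 4, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0],
      [0, 0, 0, 0, 0, 2, 0, 2, 4, 0, 2, 0, 2, 0, 0, 0, 0, 0, 4, 4, 0, 2, 0, 0, 0, 0, 0, 4, 0, 0, 2, 0, 0],
      [0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0, 4, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0],
      [0, 0, 0, 0, 0, 5, 0, 0, 2, 0, 4, 0, 0, 0, 2, 0, 0, 4, 0, 0, 0, 0, 0, 2, 0, 4, 4, 0, 0, 0, 0, 0, 2],
      [0, 0, 0, 0, 0, 5, 0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0],
      [0, 0, 0, 0, 0, 5, 0, 0, 4, 0, 2, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 2, 0, 2, 0, 0, 0, 0, 4],
      [0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 5, 0, 0, 2, 0, 4, 0, 0, 0, 0, 4, 0, 0, 2, 0, 2, 0, 0, 4, 0, 0, 0, 0, 0, 2, 0, 4, 0],
      [0, 1, 0, 0, 0, 0, 4, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 1, 0, 1, 4, 0, 2, 0, 0, 2, 4, 0, 0, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0, 0, 0, 0, 4, 2, 0]
    ],
    "coded_features": ["feeding", "respiration", "locomotion", "reproduction", "size"],
    "coded": [
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [true, true, true, true, true],
      [false, true, true, true, true]
    ]
  }
}
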