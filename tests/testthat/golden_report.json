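{
  "provenance": {
    "package_version": "0.1.0",
    "config_hash": "14b7eeb2",
    "seed": 1
  },
  "intervals": {
    "per_sample": [
      {
        "sample": "S1",
        "n_h3k27ac": 214,
        "n_h3k4me1": 180
      },
      {
        "sample": "S2",
        "n_h3k27ac": 214,
        "n_h3k4me1": 180
      },
      {
        "sample": "S3",
        "n_h3k27ac": 214,
        "n_h3k4me1": 180
      }
    ]
  },
  "enhancers": {
    "mode": "double_positive_union",
    "counts": {
      "sample": ["S1", "S2", "S3"],
      "n_enhancers": [120, 120, 120],
      "n_common_overlap": [120, 120, 120],
      "fraction_common": [1, 1, 1]
    },
    "n_common": 120
  },
  "super_enhancers": {
    "per_sample": [
      {
        "sample": "S1",
        "n_super_enhancers": 27
      },
      {
        "sample": "S2",
        "n_super_enhancers": 32
      },
      {
        "sample": "S3",
        "n_super_enhancers": 25
      }
    ],
    "n_common": 18
  },
  "loops": {
    "n_loops": 5
  },
  "association": {
    "bin_counts": {
      "inactive": 30,
      "low": 30,
      "mid": 30,
      "high": 30
    },
    "enhancer_fractions": {
      "bin": ["inactive", "low", "mid", "high"],
      "n_enhancers_linked": [114, 113, 110, 111],
      "fraction": [0.95, 0.9416666667, 0.9166666667, 0.925]
    },
    "super_enhancer_fractions": {
      "bin": ["inactive", "low", "mid", "high"],
      "n_enhancers_linked": [12, 12, 12, 10],
      "fraction": [0.6666666667, 0.6666666667, 0.6666666667, 0.5555555556]
    }
  },
  "colocalization": {
    "enhancers": {
      "category": "enhancer",
      "n_regions": 120,
      "n_colocalized": 24,
      "percent": 20
    },
    "super_enhancers": {
      "category": "super_enhancer",
      "n_regions": 18,
      "n_colocalized": 14,
      "percent": 77.8
    },
    "contrast": {
      "percent_difference": 57.8,
      "odds_ratio": 14,
      "undefined_or": false,
      "fisher_p": 2.509326761e-06
    }
  },
  "activity": {
    "target_gene": "TARGETG",
    "r": 0.3849086383,
    "n": 43,
    "p_value": 0.01081325337,
    "n_up_used": 50,
    "n_down_used": 50
  },
  "perturb": {
    "class_fractions": {
      "none": 0.16,
      "singlet": 0.57875,
      "multiplet": 0.26125
    },
    "n_singlet_cells": 463,
    "calls": {
      "grna": ["PLCL2-1", "PLCL2-2", "PLCL2-3", "PLCL2-4", "PLCL2-5", "PLCL2-6", "PLCL2-7", "PLCL2-8"],
      "gene": ["PLCL2", "PLCL2", "PLCL2", "PLCL2", "PLCL2", "PLCL2", "PLCL2", "PLCL2"],
      "fold_change": [1.637320412, 0.8801939162, 1.771775, 1.116884474, 2.746528695, 1.356430302, 1.990559682, 1.908889167],
      "activated": [true, false, true, false, true, false, true, true],
      "n_perturbed": [62, 55, 54, 50, 48, 45, 52, 51],
      "n_control": [46, 46, 46, 46, 46, 46, 46, 46]
    }
  }
}
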