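{
  "annotate": {
    "n_ucnes": 5,
    "n_open": 4,
    "n_high_confidence": 1,
    "n_marked": 2,
    "n_marked_activating": 2,
    "n_active_enhancer": 1,
    "n_sustained_adult": 1,
    "active_mark_cooccurrence": 1
  },
  "targets": {
    "n_active": 4,
    "n_edges": 6,
    "n_target_genes": 3,
    "n_expressed_edges": 4,
    "n_expressed_genes": 2,
    "n_missing_expression": 0,
    "n_tad_consistent_genes": 2,
    "tad_consistent_fraction_genes": 1,
    "concordant_fraction": 0.5,
    "peak2gene_agreement": 0.25,
    "n_disease_genes": 1,
    "n_disease_ucnes": 2,
    "genes_per_ucne": {
      "1": 2,
      "2": 2
    },
    "tss_distance_bins": {
      "0-5kb": 1,
      "5-50kb": 5,
      "50-500kb": 0,
      ">500kb": 0
    }
  },
  "variants": {
    "n_variants": 8,
    "bin_counts": {
      "ultrarare": 4,
      "very_rare": 1,
      "rare": 2,
      "low_frequency": 0,
      "common": 1
    },
    "n_rare": 6,
    "n_hits": 5,
    "n_ultrarare_hits": 4,
    "n_ultrarare_disease_hits": 3,
    "n_sv_hits": 1,
    "search_space": {
      "n_variants": 3,
      "n_ucnes": 1,
      "n_genes": 1,
      "n_variants_unsolved": 1,
      "n_ucnes_unsolved": 1
    }
  },
  "constraint": {
    "n_roi_ucnes": 2,
    "H": 2149,
    "p": 0,
    "medians": {
      "UCNE": -1,
      "Flanking": -0.5,
      "Random": 0.3
    },
    "z_ucne_random": -46.332157383892,
    "p_adj_ucne_random": 0,
    "pairwise": [
      {
        "group_i": "UCNE",
        "group_j": "Flanking",
        "z": -23.4913170194573,
        "p": 5.00364925854233e-122,
        "p_adjusted": 1.5010947775627e-121
      },
      {
        "group_i": "UCNE",
        "group_j": "Random",
        "z": -46.332157383892,
        "p": 0,
        "p_adjusted": 0
      },
      {
        "group_i": "Flanking",
        "group_j": "Random",
        "z": -24.7948414690197,
        "p": 1.01903776384745e-135,
        "p_adjusted": 3.05711329154236e-135
      }
    ],
    "spectrum_roi": {
      "ultrarare": 0.75,
      "very_rare": 0,
      "rare": 0.25,
      "low_frequency": 0,
      "common": 0
    },
    "spectrum_background": {
      "ultrarare": null,
      "very_rare": null,
      "rare": null,
      "low_frequency": null,
      "common": null
    },
    "common_density_ratio": null,
    "suitability_p": 0.438578026081
  },
  "vista": {
    "active_ucnes": {
      "overlapped": 1,
      "positive": 1,
      "proportion": 1,
      "defined": true
    },
    "all_ucnes": {
      "overlapped": 2,
      "positive": 1,
      "proportion": 0.5,
      "defined": true
    }
  },
  "provenance": {
    "seed": 1,
    "config_hash": "3558a007"
  }
}
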