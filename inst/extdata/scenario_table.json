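{
  "version": 1,
  "comment": "Qualitative drug-response scenario table for the synthetic spheroid phantom. Radii are [slow, depth, lateral] in micrometres. dead_fraction is the fraction of viable-shell voxels rendered static (collapsed dynamics). Values encode orderings (growth/shrinkage, dynamics decline), not absolute image values.",
  "defaults": {
    "shell": { "m": 0.8, "tau_c": 600, "reflectivity": 1.0 },
    "core": { "m": 0.0, "tau_c": 3000, "reflectivity": 0.6 },
    "boundary_perturbation": 0.08,
    "plate_reflectivity": 10,
    "noise_floor": 0.001,
    "spot": { "radius_um": 20, "m": 0.0, "tau_c": 3000, "reflectivity": 0.9 },
    "domain": { "radius_um": 35, "m": 0.0, "tau_c": 3500, "reflectivity": 0.95 },
    "peripheral": { "m": 0.0, "tau_c": 3000, "reflectivity": 0.9 },
    "ring": { "m": 0.0, "tau_c": 3000, "reflectivity": 0.9 },
    "replicate_radius_jitter": 0.03
  },
  "scenarios": [
    {
      "drug": "control", "concentration_uM": 0,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.0 },
        "3": { "radii_um": [190, 170, 190], "core_fraction": 0.4, "dead_fraction": 0.02 },
        "6": { "radii_um": [230, 205, 230], "core_fraction": 0.5, "dead_fraction": 0.05 }
      }
    },
    {
      "drug": "TAM", "concentration_uM": 0.1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.0 },
        "3": { "radii_um": [190, 170, 190], "core_fraction": 0.4, "dead_fraction": 0.02 },
        "6": { "radii_um": [230, 205, 230], "core_fraction": 0.5, "dead_fraction": 0.05 }
      }
    },
    {
      "drug": "TAM", "concentration_uM": 1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.02 },
        "3": { "radii_um": [190, 170, 190], "core_fraction": 0.4, "dead_fraction": 0.06 },
        "6": { "radii_um": [230, 205, 230], "core_fraction": 0.5, "dead_fraction": 0.12 }
      }
    },
    {
      "drug": "TAM", "concentration_uM": 10,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.1,
               "shell_m": 0.7, "shell_tau_c": 800, "boundary_perturbation": 0.12 },
        "3": { "radii_um": [165, 150, 165], "core_fraction": 0.4, "dead_fraction": 0.35,
               "shell_m": 0.45, "shell_tau_c": 2000, "boundary_perturbation": 0.22 },
        "6": { "radii_um": [125, 115, 125], "core_fraction": 0.5, "dead_fraction": 0.6,
               "shell_m": 0.25, "shell_tau_c": 3500, "boundary_perturbation": 0.3 }
      }
    },
    {
      "drug": "PTX", "concentration_uM": 0.1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.05, "n_spots": 3 },
        "3": { "radii_um": [155, 140, 155], "core_fraction": 0.35, "dead_fraction": 0.15, "n_spots": 6 },
        "6": { "radii_um": [158, 142, 158], "core_fraction": 0.42, "dead_fraction": 0.3, "n_spots": 10 }
      }
    },
    {
      "drug": "PTX", "concentration_uM": 1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.08,
               "n_spots": 4, "n_domains": 1 },
        "3": { "radii_um": [135, 122, 135], "core_fraction": 0.35, "dead_fraction": 0.3,
               "n_spots": 8, "n_domains": 1 },
        "6": { "radii_um": [115, 104, 115], "core_fraction": 0.45, "dead_fraction": 0.5,
               "n_spots": 14, "n_domains": 1 }
      }
    },
    {
      "drug": "PTX", "concentration_uM": 10,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.12,
               "n_spots": 5, "n_domains": 2, "domain_radius_um": 45 },
        "3": { "radii_um": [128, 116, 128], "core_fraction": 0.35, "dead_fraction": 0.4,
               "n_spots": 10, "n_domains": 2, "domain_radius_um": 45 },
        "6": { "radii_um": [105, 95, 105], "core_fraction": 0.45, "dead_fraction": 0.6,
               "n_spots": 16, "n_domains": 2, "domain_radius_um": 45 }
      }
    },
    {
      "drug": "DOX", "concentration_uM": 0.1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.05 },
        "3": { "radii_um": [158, 142, 158], "core_fraction": 0.38, "dead_fraction": 0.2 },
        "6": { "radii_um": [166, 150, 166], "core_fraction": 0.45, "dead_fraction": 0.35 }
      }
    },
    {
      "drug": "DOX", "concentration_uM": 1,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.08,
               "peripheral_thickness_um": 20 },
        "3": { "radii_um": [130, 117, 130], "core_fraction": 0.38, "dead_fraction": 0.3,
               "peripheral_thickness_um": 20 },
        "6": { "radii_um": [110, 99, 110], "core_fraction": 0.48, "dead_fraction": 0.55,
               "peripheral_thickness_um": 20 }
      }
    },
    {
      "drug": "DOX", "concentration_uM": 10,
      "days": {
        "1": { "radii_um": [150, 135, 150], "core_fraction": 0.25, "dead_fraction": 0.1,
               "ring": [0.55, 0.75] },
        "3": { "radii_um": [185, 167, 185], "core_fraction": 0.38, "dead_fraction": 0.35,
               "ring": [0.55, 0.75] },
        "6": { "radii_um": [222, 200, 222], "core_fraction": 0.48, "dead_fraction": 0.6,
               "ring": [0.55, 0.75] }
      }
    }
  ]
}
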