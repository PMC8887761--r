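{
  "params_version": "1.0",
  "comment": "Default generator parameters, calibrated to the bundled reference cohort statistics (rabbit cavotricuspid isthmus, n = 52). Placement priors for ramification positions are coarse and qualitative.",
  "n_specimens": 52,
  "weight_kg": { "meanlog": 1.2237754, "sdlog": 0.40 },
  "cti_area_mm2": { "meanlog": 4.7673716, "sdlog": 0.3318, "spearman_with_weight": 0.49 },
  "isthmus_mm": {
    "ili_mean": 13.09, "ili_sd": 2.14, "ili_min": 6.0,
    "ci_ili_ratio_mean": 0.7537, "ci_ili_ratio_sd": 0.1119,
    "psi_ci_ratio_mean": 0.4947, "psi_ci_ratio_sd": 0.1723
  },
  "tc_diameter_mm": { "mean": 1.19, "sd": 0.27, "min": 0.4 },
  "vb_diameter_mm": { "mean": 1.30, "sd": 0.46, "min": 0.4 },
  "corner_jitter_frac": 0.03,
  "level_counts": {
    "c": { "median": 4, "iqr": 2, "min": 0, "max": 8 },
    "p": { "median": 3, "iqr": 2, "min": 0, "max": 5 },
    "x": { "median": 1, "iqr": 2, "min": 0, "max": 7 },
    "y": { "median": 0, "iqr": 0, "min": 0, "max": 2 },
    "a": { "median": 3, "iqr": 2, "min": 1, "max": 7 },
    "v": { "median": 4, "iqr": 2, "min": 2, "max": 8 }
  },
  "total_count": { "median": 16, "iqr": 6 },
  "level_m": { "c": 0.85, "p": 0.75, "x": 0.55, "y": 0.45, "a": 0.30, "v": 0.15 },
  "level_m_sd": 0.03,
  "efferent_probs": {
    "c": [0.85, 0.12, 0.03],
    "p": [0.35, 0.55, 0.10],
    "x": [0.55, 0.35, 0.10],
    "y": [0.75, 0.25, 0.00],
    "a": [0.88, 0.10, 0.02]
  },
  "target_level_probs": {
    "c": { "p": 0.490, "x": 0.016, "y": 0.004, "a": 0.329, "v": 0.161 },
    "p": { "x": 0.331, "y": 0.022, "a": 0.626, "v": 0.022 },
    "x": { "y": 0.148, "a": 0.836, "v": 0.016 },
    "y": { "a": 1.0 },
    "a": { "v": 1.0 }
  },
  "ii_edges_max": 2,
  "ii_edge_prob": 0.25,
  "virtual_anchor_prob": 0.15,
  "tortuosity_sd": 0.08,
  "segment_diameter_mm": {
    "cp": { "median": 0.6, "mad": 0.2 },
    "cv": { "median": 0.8, "mad": 0.3 },
    "ca": { "median": 0.5, "mad": 0.2 },
    "cx": { "median": 0.3, "mad": 0.1 },
    "cy": { "median": 0.6, "mad": 0.15 },
    "pa": { "median": 0.5, "mad": 0.2 },
    "px": { "median": 0.4, "mad": 0.2 },
    "py": { "median": 0.5, "mad": 0.1 },
    "xa": { "median": 0.5, "mad": 0.2 },
    "xy": { "median": 0.4, "mad": 0.1 },
    "ya": { "median": 0.6, "mad": 0.3 },
    "pv": { "median": 0.7, "mad": 0.1 },
    "xv": { "median": 0.5, "mad": 0.1 },
    "yv": { "median": 0.5, "mad": 0.15 },
    "av": { "median": 0.9, "mad": 0.3 },
    "ii": { "median": 0.4, "mad": 0.2 }
  },
  "min_segment_diameter_mm": 0.12,
  "paraseptal_class_weights": {
    "Plain": 2, "Simple": 13, "SimpleCrossoverILPS": 16,
    "SimpleCrossoverPSIL": 7, "ComplexNoCrossover": 2, "ComplexCrossover": 12
  },
  "species_probs": { "NZ": 0.21, "Dom": 0.79 },
  "sex_probs": { "m": 0.44, "f": 0.40, "unknown": 0.16 },
  "resolution_um_per_px": [6.1, 27.8]
}
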