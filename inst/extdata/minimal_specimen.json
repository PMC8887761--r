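{
  "format_version": "1.0",
  "units": "mm",
  "specimen": {
    "id": "MINIMAL",
    "species": "unknown",
    "sex": "unknown",
    "body_weight_kg": 3.4,
    "resolution_um_per_px": 10
  },
  "boundary": {
    "corners": {
      "ilV": [0, 0], "cV": [5, 0], "psV": [10, 0],
      "ilC": [0, 10], "cC": [5, 10], "psC": [10, 10]
    },
    "tc_contour": [[0, 10], [5, 10], [10, 10], [10, 9], [5, 9], [0, 9]],
    "vb_contour": [[0, 0], [5, 0], [10, 0], [10, 1], [5, 1], [0, 1]],
    "ili_line": [[0, 0], [0, 10]],
    "ci_line": [[5, 0], [5, 10]],
    "psi_line": [[10, 0], [10, 10]],
    "cti_boundary": [[0, 0], [5, 0], [10, 0], [10, 10], [5, 10], [0, 10]]
  },
  "ramifications": [
    { "id": "c1", "level": "c", "index": 1, "pos": [2.5, 8.5], "virtual": false },
    { "id": "v1", "level": "v", "index": 1, "pos": [2.5, 1.5], "virtual": false }
  ],
  "segments": [
    {
      "id": "P.c1.v1", "start": "c1", "end": "v1",
      "contour": [[2.2, 1.5], [2.8, 1.5], [2.8, 8.5], [2.2, 8.5]],
      "endocardial": true, "orthogonal_epicardial": false
    }
  ]
}
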