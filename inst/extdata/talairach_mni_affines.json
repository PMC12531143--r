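{
  "comment": "Named 4x4 affines for Talairach <-> MNI conversion. Matrices are stored in the MNI->Talairach direction (row-major); tal_to_mni() applies the inverse. 'lancaster' is the pooled-average icbm(spm)->tal matrix of Lancaster et al.; 'identity' passes coordinates through unchanged.",
  "mni_to_tal": {
    "identity": [
      [1.0, 0.0, 0.0, 0.0],
      [0.0, 1.0, 0.0, 0.0],
      [0.0, 0.0, 1.0, 0.0],
      [0.0, 0.0, 0.0, 1.0]
    ],
    "lancaster": [
      [0.9254, 0.0024, -0.0118, -1.0207],
      [-0.0048, 0.9316, -0.0871, -1.7667],
      [0.0152, 0.0883, 0.8924, 4.0926],
      [0.0, 0.0, 0.0, 1.0]
    ]
  }
}
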