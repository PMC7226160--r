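{
  "reference_id": "TrmFO_Tth_synthetic",
  "catalytic_positions": [51, 223],
  "folate_triad_positions": [308, 309, 310],
  "flavin_stack_position": 343,
  "fad_motif_pattern": "GAGx[A/S]GxE[A/V]",
  "note": "Synthetic stand-in for T. thermophilus TrmFO (PDB 3G5S); the annotated coordinates are the published ones, the sequence background is random."
}
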