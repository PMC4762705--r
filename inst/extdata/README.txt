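Planned-vs-postoperative accuracy measurements for a published
ten-patient bimaxillary-surgery cohort (maxilla and distal mandibular
segment). Columns are the six clinical movement components: translations
in mm (d_ap anterior+, d_lr patient-right+, d_ud cranial+) and rotations
in degrees (pitch, roll, yaw; anti-clockwise positive in the standard
cephalometric views). One maxillary value intentionally retains a
decimal comma ("0,26") as found in the source table; readers normalize
it with a warning.
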