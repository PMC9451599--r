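# Lung adenocarcinoma driver-stratification rules: recurrent hotspot
# substitutions plus EGFR indels in exons 18-21 (protein-residue window
# fallback when the MAF lacks exon numbers). Same content as
# default_driver_rules().
KRAS:
  sites: [G12, G13, Q61, A146]
BRAF:
  sites: [V600, N581, G464, G466, G469, G596, D594]
EGFR:
  sites: [L858, S768, L861, G719, T790]
  indel_exons: [18, 21]
  indel_residue_window: [688, 875]
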