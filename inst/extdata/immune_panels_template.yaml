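# PARTIAL template of curated immune gene panels for epithelial-immune
# interactions, organized by functional process. The genes listed here are
# only the symbols recoverable from published summary tables and figures;
# the underlying curated lists are several hundred genes, so users should
# supply their own complete panels in this format. The chemokine-signaling
# category is omitted because no member genes are recoverable from the
# published tables.
Antigen Processing:
  - ERAP1
  - ERAP2
  - TAP1
  - HLA-F
  - CIITA
  - CD1A
  - CD1B
  - CD1E
  - B2M
Immune Modulating Proteins:
  - PVR
  - PVRL1
  - PVRL2
  - MICA
  - CD86
  - CD274
  - CTLA4
  - RAET1E
  - ULBP2
Innate Immune Receptor Signaling:
  - IRF3
  - CIITA
  - NLRC3
  - DHX58
  - TLR4
  - BTK
  - TBK1
  - IKBKE
  - NLRP3
  - NLRP4
  - NLRP5
  - NLRP7
  - NLRP8
  - NLRP10
  - NLRP12
  - NLRP13
  - NLRP14
Interferon Signaling:
  - IRF2BP1
  - SOCS6
  - IRF5
  - IRF3
  - SIRT1
  - SIRT3
  - SMARCA4
  - DOCK2
  - IFNAR1
  - IFNAR2
  - IFNGR1
  - IFNGR2
  - JAK1
  - TYK2
Cytokine Signaling:
  - IL1R1
  - IL1RAP
  - IL1RAPL1
  - IL17RB
  - IL17RD
  - IL18
  - IL18RAP
  - IL1B
  - IL6ST
  - IL7R
  - TNFRSF10A
  - TNFRSF1A
  - TGFB3
  - TGFBI
  - LTBP1
  - LTBP2
  - LTBP3
Complement:
  - C4A
  - C4B
  - C6
  - C7
  - CFH
  - CFHR4
  - CFHR5
  - CSMD1
  - CSMD2
  - CSMD3
  - ITGAX
  - MBL2
  - FCN2
  - MASP1
  - COLEC11
Programmed Cell Death:
  - TNFRSF10A
  - CASP8AP2
  - SERPINB4
  - BIRC7
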