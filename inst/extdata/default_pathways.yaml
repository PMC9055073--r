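# Minimal cancer hallmark pathway gene sets bundled as a working default for
# rollup_pathway_status(); supply your own YAML for real analyses.
cell_cycle:
  genes:
    RB1: tumor_suppressor
    CCND1: oncogene
    CCNE1: oncogene
    CDK4: oncogene
    CDK6: oncogene
    CDKN2A: tumor_suppressor
tgf_beta:
  genes:
    SMAD2: tumor_suppressor
    SMAD3: tumor_suppressor
    SMAD4: tumor_suppressor
    TGFBR1: tumor_suppressor
    TGFBR2: tumor_suppressor
    ACVR2A: tumor_suppressor
pi3k:
  genes:
    PIK3CA: oncogene
    PIK3R1: tumor_suppressor
    PTEN: tumor_suppressor
    AKT1: oncogene
    MTOR: oncogene
rtk_ras:
  genes:
    KRAS: oncogene
    NRAS: oncogene
    BRAF: oncogene
    ERBB2: oncogene
    EGFR: oncogene
    NF1: tumor_suppressor
wnt:
  genes:
    APC: tumor_suppressor
    CTNNB1: oncogene
    RNF43: tumor_suppressor
    AXIN2: tumor_suppressor
tp53:
  genes:
    TP53: tumor_suppressor
    MDM2: oncogene
    ATM: tumor_suppressor
myc:
  genes:
    MYC: oncogene
    MYCN: oncogene
    MXD1: tumor_suppressor
notch:
  genes:
    NOTCH1: unknown
    NOTCH4: unknown
    FBXW7: tumor_suppressor
hippo:
  genes:
    YAP1: oncogene
    LATS1: tumor_suppressor
    LATS2: tumor_suppressor
nrf2:
  genes:
    NFE2L2: oncogene
    KEAP1: tumor_suppressor
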