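trinuc	ratio
ACA	1.437
ACC	0.74
ACG	1.6172
ACT	1.0233
CCA	1.5544
CCC	0.8474
CCG	1.3251
CCT	1.233
GCA	1.4309
GCC	0.8951
GCG	1.7856
GCT	1.1766
TCA	1.1922
TCC	1.5597
TCG	1.6647
TCT	1.5532
ATA	1.4003
ATC	0.7965
ATG	1.0838
ATT	1.2146
CTA	1.4626
CTC	0.9001
CTG	1.7107
CTT	0.9889
GTA	1.5273
GTC	1.5276
GTG	1.6756
GTT	1.6413
TTA	0.7773
TTC	1.5698
TTG	1.365
TTT	1.5771
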