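snp_id	nonrisk_genotypes	risk_genotypes
rs4731426_LEP	GC	GG+CC
rs1800006_UCP3	AG	GG+AA
rs1052700_PLIN1	TT	AA+TA
rs1042713_ADRB2	AA+AG	GG
rs11605924_CRY2	CC	AA+AC
rs1800592_UCP1	CC+TT	CT
rs2734827_UCP3	GG	AA+AG
rs1440581_PPM1K	CC	TT+TC
rs7799039_LEP	GA	GG+AA
rs12255372_TCF7L2	TT	GG+GT
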