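# Simulation config for `aggcall simulate`
coverage_per_allele: 40
p_sub: 0.002
p_ins: 0.002
p_del: 0.002
allelic_bias: 1.0
samples:
  - sample_id: female1
    alleles: ["(CGG)9(AGG)1(CGG)12", "(CGG)69"]
  - sample_id: female2
    alleles: ["(CGG)9(AGG)1(CGG)9(AGG)1(CGG)45", "(CGG)9(AGG)1(CGG)7(AGG)1(CGG)55"]
  - sample_id: female3
    alleles: ["(CGG)9(AGG)1(CGG)9(AGG)1(CGG)13", "(CGG)9(AGG)1(CGG)9(AGG)1(CGG)49"]
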