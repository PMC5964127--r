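# Pipeline configuration (all keys optional; defaults shown)
flank5: TCAGGCGCTCAGCTCCGTTTCGGT
flank3: CTGGGCCTCGAGCGCCCGCAGCCC
max_anchor_mismatches: 2
min_canonical_fraction: 0.9
known_interruptions: [CTG, TGG]
min_reads_per_allele: 10
min_length_separation: 2
max_barcode_mismatches: 1
# risk_table: path/to/custom_risk.tsv   # default: shipped anchor table
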