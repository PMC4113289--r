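# Default ITS2 anchor model: conserved flanks delimiting the ITS2.
# motifs_5p mark the 3' end of the 5.8S gene; motifs_3p the 5' start of
# the LSU. IUPAC ambiguity codes are allowed. Treated as data: replace
# this file (or pass your own model) for other primer systems.
motifs_5p:
  - AACTTTCAACAACGGATCTCTTGG
motifs_3p:
  - TTGACCTCAAATCAGGTAGGACTA
max_mismatches: 1
search_window_5p: 80
search_window_3p: 80
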