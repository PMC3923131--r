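>casq1 synthetic overlap region (ORF-1 frame 0, ends at ORF-1 stop; ORF-2 in +1 frame)
GAUGAUGAUGGCGAUGAUGAUGGCGAUGAUGAUGGAUAA
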