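# Inter-protein cross-linked lysine pairs (catalytic-domain phosphatase vs
# inhibitor), full-length numbering. 'a/b' = sites indistinguishable from
# the fragmentation spectra; comma-separated partners expand to one record
# each.
ppz1	hal3
356/359	39
358	29, 41, 315
378	113, 197, 315, 316
381	210, 483
396	236
433	210
453	280
468	201
496/502	315
584	90, 113, 323
589	90
664	113, 210, 483
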