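# drug: lecanemab
# outcome: any-ARIA-E
genotype,arm,events,non_events
e4e4,active,46,95
e4e4,placebo,5,128
non-e4e4,active,67,690
non-e4e4,placebo,10,754
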