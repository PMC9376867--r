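Bin Id	Marker lineage	Completeness	Contamination	Strain heterogeneity
bin_7	g__Prochlorococcus	85.3	1.2	0
bin_9	g__Prochlorococcus	100.0	0.5	0
bin_12	g__Prochlorococcus	42.7	8.9	25
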