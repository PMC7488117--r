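Sample	Sex	Excluded chromosomes	Pct discordant
sample_001	male	MT,X,Y	0.3317
sample_002	female	MT	0.8448
sample_003	male	MT,X,Y	0.7392
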