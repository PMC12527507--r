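# pre-defined route hierarchy for measure IRR (highest priority first)
# edit freely: one route id per line, blank lines and # comments ignored
rates
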