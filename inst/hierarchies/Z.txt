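# pre-defined route hierarchy for measure Z (highest priority first)
# edit freely: one route id per line, blank lines and # comments ignored
r_n
means_sd
change_scores
means_se
means_ci
ancova_means
t
f
p
eta
med_iqr
med_iqr_range
med_range
2x2
props
or_ci
logor_se
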