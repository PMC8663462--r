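p value
p-value
p
mean difference
mean difference (95% ci)
difference (95% ci)
odds ratio
odds ratio (95% ci)
relative risk
risk ratio
hazard ratio
effect size
95% ci
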