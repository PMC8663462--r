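control
experimental
treatment
intervention
comparator
control group
treatment group
intervention group
experimental group
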