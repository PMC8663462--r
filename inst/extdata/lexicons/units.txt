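years
kg
cm
kg/m2
mmhg
bpm
g/dl
mmol/l
ml
days
hours
points
score
%
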