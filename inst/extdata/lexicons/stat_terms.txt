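mean
sd
standard deviation
median
iqr
n
no.
%
percent
count
min
max
range
mean (sd)
n (%)
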