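placebo
aspirin
metformin
dexamethasone
high flow nasal cannula
cognitive behavioral therapy
standard care
usual care
normal saline
physical therapy
mindfulness based stress reduction
transcranial magnetic stimulation
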