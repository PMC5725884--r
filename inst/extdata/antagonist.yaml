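# H3 antagonist parameterisation: 60% of autoreceptors unavailable.
b0: 4
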