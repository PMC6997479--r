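,normal,borderline,accumulation
normal,32,2,1
borderline,7,18,5
accumulation,1,9,13
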