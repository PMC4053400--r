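inhibitor	ddG_bind
8CA	2.04
F8A	1.45
I4A	2.18
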