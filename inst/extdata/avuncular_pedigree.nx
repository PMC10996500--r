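G1 U
G2 U
G1 P
G2 P
P C
S C
S H
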