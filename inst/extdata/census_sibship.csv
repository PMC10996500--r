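generation,mean,sd
1850,3.31,2.13
1880,3.02,1.95
1910,2.72,1.85
1940,2.35,1.70
1970,2.30,1.43
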