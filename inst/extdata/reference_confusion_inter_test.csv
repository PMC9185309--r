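"",N,S,V,F,Q
N,40629,1832,645,989,90
S,321,1427,83,1,3
V,224,156,2788,29,20
F,53,4,50,264,17
Q,2,0,3,0,2
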