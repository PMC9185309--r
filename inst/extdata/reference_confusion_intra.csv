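"",N,S,V,F,Q
N,89820,117,34,4,1
S,122,2636,16,0,0
V,59,13,6895,35,0
F,32,3,39,728,0
Q,1,0,4,1,9
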