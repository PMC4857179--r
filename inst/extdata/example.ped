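f1 gf 0 0 1 0
f1 gm 0 0 2 0
f1 s1 gf gm 1 1
f1 s2 gf gm 1 1
f1 w1 0 0 2 1
f1 w2 0 0 2 1
f1 c11 s1 w1 1 1
f1 c12 s1 w1 2 1
f1 c21 s2 w2 1 1
f1 c22 s2 w2 2 1
f2 a 0 0 1 1
f2 b 0 0 2 1
f2 d a b 2 1
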