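t1 0 d01 2
t1 0 d02 0
t1 0 d03 1
t1 0 d04 0
t1 0 d05 1
t1 0 d06 0
t1 0 d07 2
t1 0 d08 0
t1 0 d09 0
t1 0 d10 1
t1 0 d11 2
t1 0 d12 0
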