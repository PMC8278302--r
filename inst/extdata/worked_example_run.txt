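t1 Q0 d01 1 12.0 worked
t1 Q0 d02 2 11.0 worked
t1 Q0 d03 3 10.0 worked
t1 Q0 d04 4 9.0 worked
t1 Q0 d05 5 8.0 worked
t1 Q0 d06 6 7.0 worked
t1 Q0 d07 7 6.0 worked
t1 Q0 d08 8 5.0 worked
t1 Q0 d09 9 4.0 worked
t1 Q0 d10 10 3.0 worked
t1 Q0 d11 11 2.0 worked
t1 Q0 d12 12 1.0 worked
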